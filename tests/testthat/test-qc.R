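# Quality control, normalization and HVG selection.

# a screen_matrix built by hand with fully controlled QC quantities
toy_matrix <- function(umis, genes_detected, pct_mito,
                       n_genes = 6000) {
  n <- length(umis)
  counts <- matrix(0L, n, n_genes,
                   dimnames = list(sprintf("cell%02d", seq_len(n)),
                                   c(sprintf("mt-%02d", 1:10),
                                     sprintf("g%04d", seq_len(n_genes - 10)))))
  for (i in seq_len(n)) {
    mito_umis <- round(umis[i] * pct_mito[i] / 100)
    nuc_umis <- umis[i] - mito_umis
    k <- genes_detected[i] - (mito_umis > 0)
    cols <- 10 + seq_len(k)
    base <- nuc_umis %/% k
    cnt <- rep(base, k)
    cnt[seq_len(nuc_umis - base * k)] <- base + 1
    counts[i, cols] <- as.integer(cnt)
    if (mito_umis > 0) counts[i, 1] <- as.integer(mito_umis)
  }
  screen_matrix(counts)
}

test_that("screen-profile cell filtering applies the published strict bounds", {
  mat <- toy_matrix(
    umis = c(3999, 4000, 12000, 20000, 20001, 12000, 12000, 12000),
    genes_detected = c(1700, 1600, 1599, 1700, 1700, 5000, 5001, 1700),
    pct_mito = c(0, 5, 0, 0, 0, 0, 0, 6)
  )
  out <- filter_cells(mat, qc_profile("screen"))
  kept <- out$cell_meta$barcode
  # 3999 UMIs (below), 1599 genes (below), 20001 UMIs (above),
  # 5001 genes (above) and 6% mito are removed; boundary cells survive
  expect_setequal(kept, c("cell02", "cell04", "cell06"))
  rep <- attr(out, "qc_report")
  expect_equal(rep$n_in, 8)
  expect_equal(rep$n_out, 3)
})

test_that("pilot and screen profiles carry the published thresholds", {
  s <- qc_profile("screen")
  expect_equal(c(s$min_umis, s$min_genes, s$max_umis, s$max_genes,
                 s$max_pct_mito), c(4000, 1600, 20000, 5000, 5))
  p <- qc_profile("pilot")
  expect_equal(c(p$min_umis, p$min_genes, p$max_umis, p$max_genes,
                 p$max_pct_mito), c(15000, 4000, 40000, 6500, 5))
  expect_error(qc_profile("custom", min_umis = 10, max_umis = 5), "below")
})

test_that("cell filtering is idempotent and order-invariant", {
  cfg <- simulation_config(n_target_genes = 10, sgrnas_per_target = 2,
                           n_nontargeting = 5, cells_per_sgrna = 30,
                           n_genes = 300, n_signature_genes = 30,
                           n_variable_genes = 40, seed = 31)
  mat <- generate_cells(cfg, generate_library(cfg))$matrix
  prof <- qc_profile_for_config(cfg)
  once <- filter_cells(mat, prof)
  twice <- filter_cells(once, prof)
  expect_identical(once$counts, twice$counts)
  perm <- sample(nrow(mat$counts))
  mat_p <- screen_matrix(mat$counts[perm, ], mat$repeat_counts[perm, ],
                         mat$cell_meta[perm, ], mat$gene_meta)
  out_p <- filter_cells(mat_p, prof)
  expect_setequal(out_p$cell_meta$barcode, once$cell_meta$barcode)
})

test_that("QC removes exactly the planted low-quality cells", {
  cfg <- simulation_config(n_target_genes = 15, sgrnas_per_target = 2,
                           n_nontargeting = 5, cells_per_sgrna = 60,
                           n_genes = 400, n_signature_genes = 40,
                           n_variable_genes = 60, low_quality_frac = 0.04,
                           seed = 17)
  sim <- generate_cells(cfg, generate_library(cfg))
  out <- filter_cells(sim$matrix, qc_profile_for_config(cfg))
  removed <- setdiff(sim$matrix$cell_meta$barcode, out$cell_meta$barcode)
  planted <- sim$truth$cells$barcode[sim$truth$cells$low_quality != "none"]
  expect_setequal(removed, planted)
})

test_that("gene filtering keeps genes detected in at least min_cells cells", {
  counts <- matrix(0L, 12, 3,
                   dimnames = list(NULL, c("g9", "g10", "gzero")))
  counts[1:9, 1] <- 1L
  counts[1:10, 2] <- 1L
  mat <- screen_matrix(counts)
  out <- filter_genes(mat, min_cells = 10)
  expect_equal(out$gene_meta$gene_id, "g10")
  expect_error(filter_genes(screen_matrix(matrix(0L, 5, 2)), 1), "survive")
})

test_that("normalization is ln(1 + count/total * 10000)", {
  counts <- matrix(0L, 2, 3)
  counts[1, ] <- c(1L, 9999L, 0L)
  counts[2, ] <- c(2L, 19998L, 0L)   # cell 2 = doubled cell 1
  mat <- screen_matrix(counts)
  norm <- normalize_log(mat)
  expect_equal(norm$values[1, 1], log(2))
  expect_equal(norm$values[1, 3], 0)
  # library-size scale invariance: doubling all counts changes nothing
  expect_equal(norm$values[1, ], norm$values[2, ])
  # back-transformed adjusted counts sum to the scale factor per cell
  expect_equal(unname(rowSums(expm1(norm$values))), c(1e4, 1e4))
  # zero-total cells are refused
  expect_error(normalize_log(screen_matrix(matrix(0L, 2, 2))), "zero")
})

test_that("HVG selection reproduces an independent binned-dispersion oracle", {
  cfg <- simulation_config(n_target_genes = 15, sgrnas_per_target = 2,
                           n_nontargeting = 5, cells_per_sgrna = 80,
                           n_genes = 400, n_signature_genes = 40,
                           n_variable_genes = 60, seed = 13)
  sim <- generate_cells(cfg, generate_library(cfg))
  mat <- filter_genes(filter_cells(sim$matrix, qc_profile_for_config(cfg)), 10)
  norm <- normalize_log(mat)
  avg <- 1e4 / ncol(norm$values)
  norm <- select_hvg(norm, min_mean = avg / 50, max_mean = 10 * avg)
  # independent reimplementation of the pinned formula
  x <- expm1(norm$values)
  mu <- apply(x, 2, mean)
  disp <- ifelse(mu > 0, apply(x, 2, var) / mu, 0)
  qs <- unique(quantile(mu, probs = seq(0, 1, length.out = 21)))
  bin <- cut(mu, qs, include.lowest = TRUE)
  z <- rep(0, length(mu))
  for (b in levels(bin)) {
    i <- which(bin == b)
    s <- sd(disp[i])
    if (length(i) > 1 && s > 0) z[i] <- (disp[i] - mean(disp[i])) / s
  }
  want <- mu > avg / 50 & mu < 10 * avg & z > 0.5
  expect_equal(norm$hvg_mask, unname(want))
  # planted bimodal signature genes are selected
  sig <- norm$gene_meta$is_signature
  expect_gt(mean(norm$hvg_mask[sig]), 0.8)
  # constant-in-expectation unexpressed-variance genes: a constant nonzero
  # gene has zero dispersion and is excluded
  vals <- norm$values
  vals[, 1] <- 1
  norm2 <- norm; norm2$values <- vals
  norm2 <- select_hvg(norm2, min_mean = 0.01, max_mean = 1e6)
  expect_false(norm2$hvg_mask[1])
})

test_that("HVG mean bounds exclude genes outside (min_mean, max_mean)", {
  set.seed(4)
  n <- 200
  vals <- cbind(lowg = abs(rnorm(n, 0.005, 0.002)),
                okg = abs(rnorm(n, 1, 0.8)),
                highg = abs(rnorm(n, 8, 3)))
  norm <- structure(list(values = log1p(vals), scale_factor = 1e4,
                         cell_meta = NULL,
                         gene_meta = data.frame(gene_id = colnames(vals)),
                         hvg_mask = NULL),
                    class = "normalized_matrix")
  out <- select_hvg(norm, min_mean = 0.01, max_mean = 5, min_disp = -10,
                    n_bins = 2)
  expect_false(out$hvg_mask[1])  # mean 0.005 < 0.01
  expect_true(out$hvg_mask[2])
  expect_false(out$hvg_mask[3])  # mean 8 > 5
})
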