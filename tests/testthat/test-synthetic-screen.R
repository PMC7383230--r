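# The synthetic-screen generator: library construction, planted counts,
# amplicon and repeat reads.

small_cfg <- function(...) {
  defaults <- list(n_target_genes = 15, sgrnas_per_target = 2,
                   n_nontargeting = 5, cells_per_sgrna = 25,
                   n_genes = 200, n_signature_genes = 30,
                   n_mito_genes = 5, n_variable_genes = 40,
                   n_true_hits = 4, seed = 42)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

test_that("library arithmetic matches the published design", {
  cfg <- simulation_config(n_target_genes = 230, sgrnas_per_target = 2,
                           n_nontargeting = 15, seed = 1)
  lib <- generate_library(cfg)
  expect_equal(nrow(lib), 475)
  expect_equal(sum(lib$is_targeting), 460)
  expect_equal(sum(!lib$is_targeting), 15)
  expect_equal(length(unique(lib$protospacer)), 475)
  expect_true(all(nchar(lib$protospacer) == 20))
})

test_that("a single-guide library is trivially valid", {
  cfg <- simulation_config(n_target_genes = 1, sgrnas_per_target = 1,
                           n_nontargeting = 0, n_genes = 200,
                           n_signature_genes = 20, n_true_hits = 0,
                           seed = 3)
  lib <- generate_library(cfg)
  expect_equal(nrow(lib), 1)
  expect_true(validate_library(lib)$valid)
})

test_that("generated protospacers keep pairwise Levenshtein distance >= 4", {
  lib <- generate_library(small_cfg())
  # brute-force DP over all pairs, independent of utils::adist
  n <- nrow(lib)
  dmin <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dmin <- min(dmin, brute_levenshtein(lib$protospacer[i],
                                          lib$protospacer[j]))
    }
  }
  expect_gte(dmin, 4)
  expect_equal(validate_library(lib)$min_distance, dmin)
})

test_that("an infeasible distance constraint raises", {
  cfg <- simulation_config(n_target_genes = 100, sgrnas_per_target = 2,
                           n_nontargeting = 15, n_genes = 500,
                           n_signature_genes = 50, seed = 1)
  expect_error(generate_library(cfg, protospacer_length = 4),
               "cannot satisfy")
})

test_that("identical configurations give bit-identical datasets", {
  a <- generate_cells(small_cfg(), generate_library(small_cfg()))
  b <- generate_cells(small_cfg(), generate_library(small_cfg()))
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(a$matrix$repeat_counts, b$matrix$repeat_counts)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("empirical per-gene means match the configured baseline means", {
  cfg <- simulation_config(n_target_genes = 1, sgrnas_per_target = 1,
                           n_nontargeting = 30, cells_per_sgrna = 400,
                           n_genes = 300, n_signature_genes = 40,
                           n_variable_genes = 0, n_true_hits = 0,
                           low_quality_frac = 0, seed = 5)
  sim <- generate_cells(cfg, generate_library(cfg))
  tr <- sim$truth
  base <- startsWith(tr$cells$guide1, "NT") & tr$cells$state == 0
  expect_gt(sum(base), 10000)
  emp <- colMeans(sim$matrix$counts[base, ])
  expct <- tr$per_gene_base_mean
  sel <- expct >= 1  # keep Monte-Carlo error well below the 5% band
  expect_true(all(abs(emp[sel] - expct[sel]) / expct[sel] < 0.05))
})

test_that("hit-sgRNA cells enter the ZGA-like state at the configured rate", {
  cfg <- simulation_config(n_target_genes = 15, sgrnas_per_target = 2,
                           n_nontargeting = 5, cells_per_sgrna = 300,
                           n_genes = 200, n_signature_genes = 30,
                           n_variable_genes = 0, n_true_hits = 10,
                           seed = 9)
  sim <- generate_cells(cfg, generate_library(cfg))
  tr <- sim$truth
  hit_cells <- tr$cells$guide1 %in% tr$true_hit_sgrnas
  n <- sum(hit_cells)
  phat <- mean(tr$cells$state[hit_cells])
  se <- sqrt(0.0856 * (1 - 0.0856) / n)
  expect_lt(abs(phat - 0.0856), 3.5 * se)
  base_cells <- !hit_cells
  expect_lt(abs(mean(tr$cells$state[base_cells]) - 0.02),
            3.5 * sqrt(0.02 * 0.98 / sum(base_cells)))
})

test_that("raising hit_state_prob raises signature expression in hit cells", {
  mean_sig <- function(p) {
    cfg <- small_cfg(hit_state_prob = p)
    sim <- generate_cells(cfg, generate_library(cfg))
    hit <- sim$truth$cells$guide1 %in% sim$truth$true_hit_sgrnas
    sig <- sim$matrix$gene_meta$is_signature
    mean(sim$matrix$counts[hit, sig])
  }
  expect_gt(mean_sig(0.5), mean_sig(0.02))
})

test_that("noiseless amplicon reads carry the exact protospacer at 24-43", {
  cfg <- small_cfg(base_error_rate = 0, contamination_rate = 0,
                   doublet_rate = 0)
  lib <- generate_library(cfg)
  sim <- generate_cells(cfg, lib)
  reads <- generate_amplicon_reads(cfg, sim$truth, lib)
  expect_true(all(nchar(reads$sequence) == 66))
  proto <- substr(reads$sequence, 24, 43)
  truth_proto <- lib$protospacer[match(
    sim$truth$cells$guide1[match(reads$cell_barcode,
                                 sim$truth$cells$barcode)],
    lib$guide_id)]
  expect_identical(proto, truth_proto)
})

test_that("the observed per-base mismatch rate matches base_error_rate", {
  cfg <- small_cfg(base_error_rate = 0.005, contamination_rate = 0,
                   doublet_rate = 0, cells_per_sgrna = 60,
                   amplicon_reads_per_cell = 30)
  lib <- generate_library(cfg)
  sim <- generate_cells(cfg, lib)
  reads <- generate_amplicon_reads(cfg, sim$truth, lib)
  tmpl <- paste0(attr(lib, "upstream_context"),
                 lib$protospacer[match(reads$true_guide, lib$guide_id)],
                 attr(lib, "downstream_context"))
  n_bases <- 66 * nrow(reads)
  expect_gt(n_bases, 1e5)
  mm <- sum(mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
                   reads$sequence, tmpl))
  rate <- mm / n_bases
  se <- sqrt(0.005 * 0.995 / n_bases)
  expect_lt(abs(rate - 0.005), 4 * se)
})

test_that("doublet cells emit reads from two guides at the configured rate", {
  cfg <- small_cfg(doublet_rate = 0.1, cells_per_sgrna = 120)
  lib <- generate_library(cfg)
  sim <- generate_cells(cfg, lib)
  frac <- mean(!is.na(sim$truth$cells$guide2))
  n <- nrow(sim$truth$cells)
  expect_lt(abs(frac - 0.1), 4 * sqrt(0.1 * 0.9 / n))
  # doublets' reads really come from both guides
  reads <- generate_amplicon_reads(
    small_cfg(doublet_rate = 0.1, cells_per_sgrna = 120,
              contamination_rate = 0, amplicon_reads_per_cell = 40),
    sim$truth, lib)
  dbl <- sim$truth$cells[!is.na(sim$truth$cells$guide2), ][1, ]
  src <- unique(reads$true_guide[reads$cell_barcode == dbl$barcode])
  expect_setequal(src, c(dbl$guide1, dbl$guide2))
})

test_that("repeat reads map back to their source family and state raises MERVL", {
  cfg <- small_cfg(cells_per_sgrna = 40, hit_state_prob = 0.5)
  lib <- generate_library(cfg)
  sim <- generate_cells(cfg, lib)
  ref <- synthetic_repeat_reference(seed = 7)
  reads <- generate_repeat_reads(cfg, sim$truth, ref)
  sub <- reads[sample.int(nrow(reads), 300), ]
  expect_identical(map_read_to_family(sub, ref), sub$true_family)
  # planted MERVL molecules are elevated in ZGA-state cells
  tr <- sim$truth
  mervl <- tr$repeat_molecules[, "MERVL"]
  expect_gt(mean(mervl[tr$cells$state == 1]),
            mean(mervl[tr$cells$state == 0]))
})

test_that("without ZGA cells MERVL counts are indistinguishable across sgRNAs", {
  cfg <- small_cfg(baseline_state_prob = 0, hit_state_prob = 0,
                   cells_per_sgrna = 150)
  sim <- generate_cells(cfg, generate_library(cfg))
  tr <- sim$truth
  hit <- tr$cells$guide1 %in% tr$true_hit_sgrnas
  m <- tr$repeat_molecules[, "MERVL"]
  p <- wilcox.test(m[hit], m[!hit])$p.value
  expect_gt(p, 0.01)
})

test_that("reads round-trip through FASTQ in both barcode dialects", {
  cfg <- small_cfg(cells_per_sgrna = 3)
  lib <- generate_library(cfg)
  sim <- generate_cells(cfg, lib)
  reads <- generate_amplicon_reads(cfg, sim$truth, lib)[1:50, ]
  fq <- tempfile(fileext = ".fastq")
  bq <- tempfile(fileext = ".fastq")
  write_reads_fastq(reads, fq, barcode_path = bq)
  back <- read_reads_fastq(fq)
  expect_equal(back$cell_barcode, reads$cell_barcode)
  expect_equal(back$umi, reads$umi)
  expect_equal(back$sequence, reads$sequence)
  back2 <- read_reads_fastq(fq, barcode_path = bq)
  expect_equal(back2$cell_barcode, reads$cell_barcode)
  expect_equal(back2$umi, reads$umi)
  unlink(c(fq, bq))
})

test_that("configurations validate and round-trip through YAML", {
  expect_error(simulation_config(contamination_rate = 1.5), "probability")
  expect_error(simulation_config(n_genes = -5), "non-negative")
  expect_error(simulation_config(n_genes = 100, n_signature_genes = 150,
                                 n_variable_genes = 0),
               "accommodate")
  cfg <- small_cfg()
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(unclass(back), unclass(cfg))
  unlink(path)
})
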