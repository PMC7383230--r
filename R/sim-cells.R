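# Synthetic screen cells: UMI counts, repeat-family counts and ground truth.

# The twelve repeat families tracked by the simulator, with baseline mean
# UMIs per cell. Four families are given near-zero detection so the
# min-total-reads family filter has realistic casualties.
REPEAT_FAMILY_MEANS <- c(
  "LINE-1" = 3, "LINE-2" = 2e-4, "ERV1" = 0.5, "ERVK" = 2.5,
  "MERVL" = 0.3, "Major satellites" = 0.15, "Minor satellites" = 1e-4,
  "rRNA" = 3e-4, "SINE Alu B1" = 0.2, "SINE B2" = 1, "SINE B4" = 0.25,
  "Telomeric repeats" = 2e-4
)

sim_gene_ids <- function(config) {
  n_mito <- config$n_mito_genes
  c(sprintf("mt-%02d", seq_len(n_mito)),
    sprintf("g%04d", seq_len(config$n_genes - n_mito)))
}

#' Simulate screen cells with planted ground truth
#'
#' Draws a cells-by-genes UMI count matrix and a cells-by-repeat-family UMI
#' count matrix under a negative-binomial model
#' (variance = mu + phi * mu^2) with log-normal per-cell library sizes and a
#' Beta-distributed mitochondrial fraction. A binary latent ZGA-like state
#' (probability `hit_state_prob` under planted hit sgRNAs, otherwise
#' `baseline_state_prob`) up-scales the signature genes and the MERVL repeat
#' family by a continuous per-cell intensity; each targeting sgRNA up-scales
#' its own target gene by `2^activation_log2fc` (the CRISPRa effect). A
#' small labelled fraction of cells is planted as low quality.
#'
#' @param config A [simulation_config()].
#' @param library The matching [generate_library()] output.
#' @return A list with components `matrix` (a `screen_matrix`: `counts`,
#'   `repeat_counts`, `cell_meta`, `gene_meta`) and `truth` (a
#'   `ground_truth`: per-cell table, planted hit sgRNAs, signature genes,
#'   per-gene baseline means, planted repeat molecule table).
#' @export
generate_cells <- function(config, library) {
  stop_if_not(inherits(config, "sim_config"), "config must be a sim_config")
  stop_if_not(inherits(library, "guide_library"), "library must be a guide_library")
  n_cells <- config$cells_per_sgrna * config$n_sgrnas
  stop_if_not(n_cells > 0, "zero cells requested")
  stop_if_not(config$n_genes > 0, "zero genes requested")
  set.seed(config$seed + 1L)

  genes <- sim_gene_ids(config)
  n_mito <- config$n_mito_genes
  is_mito <- startsWith(genes, "mt-")
  non_mito_ids <- genes[!is_mito]
  target_genes <- sprintf("g%04d", seq_len(config$n_target_genes))
  sig_genes <- sprintf("g%04d",
                       config$n_target_genes + seq_len(config$n_signature_genes))
  is_sig <- genes %in% sig_genes
  var_genes <- sprintf("g%04d", config$n_target_genes +
                         config$n_signature_genes +
                         seq_len(config$n_variable_genes))
  is_var <- genes %in% var_genes

  # relative expression profiles (log-normal), separate budgets for the
  # mitochondrial and nuclear gene sets
  w_non <- stats::rlnorm(length(non_mito_ids), 0, 1.2)
  w_non <- w_non / sum(w_non)
  w_mito <- if (n_mito > 0) {
    w <- stats::rlnorm(n_mito, 0, 0.8)
    w / sum(w)
  } else numeric(0)
  base_w <- numeric(config$n_genes)
  base_w[!is_mito] <- w_non
  base_w[is_mito] <- w_mito

  # per-cell identity: sgRNA, doublet partner, latent state, quality label
  guide1 <- rep(library$guide_id, each = config$cells_per_sgrna)
  n <- length(guide1)
  is_doublet <- runif(n) < config$doublet_rate
  guide2 <- rep(NA_character_, n)
  if (any(is_doublet)) {
    idx <- which(is_doublet)
    pick <- sample.int(nrow(library) - 1L, length(idx), replace = TRUE)
    g1pos <- match(guide1[idx], library$guide_id)
    pick <- ifelse(pick >= g1pos, pick + 1L, pick)
    guide2[idx] <- library$guide_id[pick]
  }

  targeting <- library$guide_id[library$is_targeting]
  n_hit_genes <- ceiling(config$n_true_hits / config$sgrnas_per_target)
  hit_genes <- sample(target_genes, n_hit_genes)
  hit_pool <- library$guide_id[!is.na(library$target_gene) &
                                 library$target_gene %in% hit_genes]
  true_hits <- sort(hit_pool)[seq_len(config$n_true_hits)]

  carries_hit <- guide1 %in% true_hits |
    (!is.na(guide2) & guide2 %in% true_hits)
  p_state <- ifelse(carries_hit, config$hit_state_prob,
                    config$baseline_state_prob)
  state <- rbinom(n, 1L, p_state)
  factor_value <- state * exp(rnorm(n, 0, 0.25))

  low_quality <- rep("none", n)
  n_lowq <- floor(config$low_quality_frac * n)
  if (n_lowq > 0) {
    lq <- sample.int(n, n_lowq)
    half <- floor(n_lowq / 2)
    low_quality[lq[seq_len(half)]] <- "low_umi"
    if (n_lowq > half) low_quality[lq[(half + 1):n_lowq]] <- "high_mito"
  }

  libsize <- config$mean_libsize *
    exp(rnorm(n, 0, config$libsize_lognormal_sigma) -
          config$libsize_lognormal_sigma^2 / 2)
  libsize[low_quality == "low_umi"] <- libsize[low_quality == "low_umi"] * 0.08
  mito_frac <- rbeta(n, config$mito_beta_shape1, config$mito_beta_shape2)
  hm <- low_quality == "high_mito"
  mito_frac[hm] <- rbeta(sum(hm), 30, 70)
  if (n_mito == 0) mito_frac[] <- 0

  barcodes <- random_dna_unique(n, 16)
  target_col <- match(library$target_gene[match(guide1, library$guide_id)], genes)
  target_col2 <- match(library$target_gene[match(guide2, library$guide_id)], genes)
  sig_cols <- which(is_sig)
  var_cols <- which(is_var)
  var_tau <- runif(length(var_cols), 0.3, config$variable_gene_sigma)
  mito_cols <- which(is_mito)
  nm_cols <- which(!is_mito)

  counts <- matrix(0L, n, config$n_genes, dimnames = list(barcodes, genes))
  qc_total <- numeric(n)
  qc_detect <- numeric(n)
  qc_mito <- numeric(n)
  phi <- config$nb_dispersion
  block_size <- max(1L, floor(8e6 / config$n_genes))
  starts <- seq(1L, n, by = block_size)
  for (s in starts) {
    rows <- s:min(s + block_size - 1L, n)
    nb <- length(rows)
    W <- matrix(base_w, nb, config$n_genes, byrow = TRUE)
    boost <- 2^(config$signature_log2fc * factor_value[rows])
    W[, sig_cols] <- W[, sig_cols] * boost
    if (length(var_cols)) {
      # mean-preserving log-normal overdispersion, independent per cell
      # and gene: other variable programs of real data, uncorrelated so
      # they add no latent structure of their own; per-gene sigma spans a
      # continuum as in real dispersion profiles
      tau <- var_tau
      W[, var_cols] <- W[, var_cols] *
        exp(sweep(matrix(rnorm(nb * length(var_cols), 0, 1), nb), 2, tau, "*") -
              matrix(tau^2 / 2, nb, length(var_cols), byrow = TRUE))
    }
    t1 <- target_col[rows]
    has_t1 <- which(!is.na(t1))
    if (length(has_t1)) {
      ij <- cbind(has_t1, t1[has_t1])
      W[ij] <- W[ij] * 2^config$activation_log2fc
    }
    t2 <- target_col2[rows]
    has_t2 <- which(!is.na(t2))
    if (length(has_t2)) {
      ij <- cbind(has_t2, t2[has_t2])
      W[ij] <- W[ij] * 2^config$activation_log2fc
    }
    f <- mito_frac[rows]
    # normalize nuclear weights to (1 - f) and mito weights to f without
    # copying the large nuclear submatrix: scale everything by the nuclear
    # factor, then correct the (few) mito columns
    rs_mito <- if (length(mito_cols))
      rowSums(W[, mito_cols, drop = FALSE]) else numeric(nb)
    rs_non <- rowSums(W) - rs_mito
    scale_non <- (1 - f) / rs_non
    W <- W * (libsize[rows] * scale_non)
    if (length(mito_cols)) {
      W[, mito_cols] <- W[, mito_cols, drop = FALSE] *
        ((f / pmax(rs_mito, 1e-300)) / scale_non)
    }
    cb <- matrix(as.integer(rnbinom(length(W), mu = W, size = 1 / phi)), nb)
    counts[rows, ] <- cb
    qc_total[rows] <- rowSums(cb)
    qc_detect[rows] <- rowSums(cb > 0L)
    if (length(mito_cols)) {
      qc_mito[rows] <- rowSums(cb[, mito_cols, drop = FALSE])
    }
  }

  # repeat-family molecules: MERVL responds to the ZGA-like state
  fam_means <- REPEAT_FAMILY_MEANS
  rep_mu <- outer(libsize / config$mean_libsize, fam_means)
  rep_mu[, "MERVL"] <- rep_mu[, "MERVL"] *
    2^(config$mervl_log2fc * factor_value)
  repeat_counts <- matrix(
    as.integer(rnbinom(length(rep_mu), mu = rep_mu, size = 1 / phi)),
    n, length(fam_means), dimnames = list(barcodes, names(fam_means))
  )

  total_umis <- qc_total
  mean_f <- config$mito_beta_shape1 /
    (config$mito_beta_shape1 + config$mito_beta_shape2)
  per_gene_base_mean <- setNames(numeric(config$n_genes), genes)
  per_gene_base_mean[!is_mito] <- config$mean_libsize * (1 - mean_f) * w_non
  if (n_mito > 0) {
    per_gene_base_mean[is_mito] <- config$mean_libsize * mean_f * w_mito
  }

  cell_meta <- data.frame(
    barcode = barcodes,
    total_umis = total_umis,
    n_genes_detected = qc_detect,
    pct_mito = if (n_mito > 0) 100 * qc_mito / pmax(total_umis, 1)
    else rep(0, n),
    assigned_guide = NA_character_,
    stringsAsFactors = FALSE
  )
  gene_meta <- data.frame(
    gene_id = genes, is_mito = is_mito, is_signature = is_sig,
    is_variable = is_var,
    stringsAsFactors = FALSE
  )
  mat <- screen_matrix(counts, repeat_counts, cell_meta, gene_meta)

  truth <- structure(list(
    cells = data.frame(
      barcode = barcodes, guide1 = guide1, guide2 = guide2,
      is_doublet = is_doublet, state = state, factor_value = factor_value,
      low_quality = low_quality, libsize = libsize, mito_frac = mito_frac,
      stringsAsFactors = FALSE
    ),
    true_hit_sgrnas = true_hits,
    hit_genes = sort(unique(library$target_gene[match(true_hits, library$guide_id)])),
    signature_genes = sig_genes,
    per_gene_base_mean = per_gene_base_mean,
    repeat_molecules = repeat_counts
  ), class = "ground_truth")

  list(matrix = mat, truth = truth)
}

#' Construct a screen matrix container
#'
#' @param counts Cells-by-genes non-negative integer matrix.
#' @param repeat_counts Cells-by-repeat-family non-negative integer matrix
#'   (may be `NULL`).
#' @param cell_meta,gene_meta Per-cell and per-gene metadata data.frames.
#' @return A `screen_matrix`.
#' @export
screen_matrix <- function(counts, repeat_counts = NULL, cell_meta = NULL,
                          gene_meta = NULL) {
  stop_if_not(is.matrix(counts) || inherits(counts, "Matrix"),
              "counts must be a matrix")
  stop_if_not(min(counts) >= 0, "counts must be non-negative")
  if (is.null(gene_meta)) {
    ids <- colnames(counts) %||% sprintf("g%04d", seq_len(ncol(counts)))
    gene_meta <- data.frame(gene_id = ids,
                            is_mito = startsWith(ids, "mt-"),
                            is_signature = FALSE, stringsAsFactors = FALSE)
  }
  if (is.null(cell_meta)) {
    total <- rowSums(counts)
    cell_meta <- data.frame(
      barcode = rownames(counts) %||% sprintf("cell%05d", seq_len(nrow(counts))),
      total_umis = total,
      n_genes_detected = rowSums(counts > 0),
      pct_mito = if (any(gene_meta$is_mito)) {
        100 * rowSums(counts[, gene_meta$is_mito, drop = FALSE]) /
          pmax(total, 1)
      } else 0,
      assigned_guide = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  structure(list(counts = counts, repeat_counts = repeat_counts,
                 cell_meta = cell_meta, gene_meta = gene_meta),
            class = "screen_matrix")
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat(sprintf("screen_matrix: %d cells x %d genes", nrow(x$counts),
              ncol(x$counts)))
  if (!is.null(x$repeat_counts)) {
    cat(sprintf(" (+ %d repeat families)", ncol(x$repeat_counts)))
  }
  cat("\n")
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d cells, %d planted hit sgRNAs, %d signature genes\n",
              nrow(x$cells), length(x$true_hit_sgrnas),
              length(x$signature_genes)))
  invisible(x)
}
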