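# Cell/gene quality control, library-size normalization and HVG selection.

#' Quality-control profiles
#'
#' Named presets reproduce the published thresholds: the `screen` profile
#' removes cells with fewer than 4,000 UMIs or fewer than 1,600 detected
#' genes, more than 20,000 UMIs or more than 5,000 genes, or more than 5%
#' mitochondrial UMIs; the `pilot` profile uses 15,000 / 4,000 lower and
#' 40,000 / 6,500 upper bounds with the same mitochondrial cut. The `desk`
#' profile scales the same structure to the synthetic desk-scale data
#' (2,000 genes, ~8,000 UMIs per cell). All comparisons are strict in the
#' printed direction ("less than" / "more than"), so boundary cells
#' survive.
#'
#' @param name Profile name, or `"custom"` with explicit bounds.
#' @param min_umis,min_genes,max_umis,max_genes,max_pct_mito,min_cells_per_gene
#'   Explicit bounds overriding the preset.
#' @return A `qc_profile` list.
#' @export
qc_profile <- function(name = c("screen", "pilot", "desk", "custom"),
                       min_umis = NULL, min_genes = NULL, max_umis = NULL,
                       max_genes = NULL, max_pct_mito = NULL,
                       min_cells_per_gene = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    screen = list(min_umis = 4000, min_genes = 1600, max_umis = 20000,
                  max_genes = 5000, max_pct_mito = 5, min_cells_per_gene = 10),
    pilot = list(min_umis = 15000, min_genes = 4000, max_umis = 40000,
                 max_genes = 6500, max_pct_mito = 5, min_cells_per_gene = 10),
    desk = list(min_umis = 2000, min_genes = 400, max_umis = 40000,
                max_genes = 1e6, max_pct_mito = 5, min_cells_per_gene = 10),
    custom = list(min_umis = 0, min_genes = 0, max_umis = Inf,
                  max_genes = Inf, max_pct_mito = 100, min_cells_per_gene = 0)
  )
  for (f in names(preset)) {
    v <- get(f)
    if (!is.null(v)) preset[[f]] <- v
  }
  stop_if_not(preset$min_umis < preset$max_umis &&
                preset$min_genes < preset$max_genes,
              "lower bounds must be below upper bounds")
  preset$name <- name
  class(preset) <- "qc_profile"
  preset
}

# Recompute the QC quantities from the counts, keeping cell_meta in sync.
# A spot check on a handful of cells decides whether the stored metadata is
# already consistent, so repeated filtering does not rescan large matrices.
refresh_cell_meta <- function(mat) {
  counts <- mat$counts
  n <- nrow(counts)
  meta <- mat$cell_meta
  if (n > 0 && all(c("total_umis", "n_genes_detected", "pct_mito") %in%
                     names(meta))) {
    probe <- unique(round(seq(1, n, length.out = min(n, 25L))))
    pc <- counts[probe, , drop = FALSE]
    mito <- mat$gene_meta$is_mito
    probe_mito <- if (any(mito)) {
      100 * rowSums(pc[, mito, drop = FALSE]) / pmax(rowSums(pc), 1)
    } else rep(0, length(probe))
    if (isTRUE(all.equal(unname(meta$total_umis[probe]),
                         unname(rowSums(pc)))) &&
        isTRUE(all.equal(unname(meta$n_genes_detected[probe]),
                         unname(rowSums(pc > 0)))) &&
        isTRUE(all.equal(unname(meta$pct_mito[probe]),
                         unname(probe_mito)))) {
      return(mat)
    }
  }
  total <- rowSums(counts)
  mito <- mat$gene_meta$is_mito
  meta$total_umis <- total
  meta$n_genes_detected <- rowSums(counts > 0)
  meta$pct_mito <- if (any(mito)) {
    100 * rowSums(counts[, mito, drop = FALSE]) / pmax(total, 1)
  } else 0
  mat$cell_meta <- meta
  mat
}

#' QC profile matched to a simulation configuration
#'
#' Scales the `desk` profile structure to the generator's own scale: lower
#' bounds at a quarter of the mean library size and a fifth of the gene
#' count (which planted healthy cells pass comfortably and planted
#' low-quality cells fail), an upper UMI bound at five times the mean
#' library size, and the 5% mitochondrial cut.
#'
#' @param config A [simulation_config()].
#' @return A `qc_profile`.
#' @export
qc_profile_for_config <- function(config) {
  stop_if_not(inherits(config, "sim_config"), "config must be a sim_config")
  qc_profile("custom",
             min_umis = round(config$mean_libsize / 4),
             min_genes = round(config$n_genes / 5),
             max_umis = 5 * config$mean_libsize,
             max_genes = config$n_genes + 1,
             max_pct_mito = 5,
             min_cells_per_gene = 10)
}

#' Filter cells on QC bounds
#'
#' Removes cells with fewer than `min_umis` UMIs, fewer than `min_genes`
#' detected genes, more than `max_umis` UMIs, more than `max_genes` genes,
#' or a mitochondrial percentage above `max_pct_mito` (all strict).
#'
#' @param mat A `screen_matrix`.
#' @param profile A [qc_profile()].
#' @return The filtered `screen_matrix`, with a `qc_report` attribute
#'   giving removal counts per criterion.
#' @export
filter_cells <- function(mat, profile = qc_profile("screen")) {
  stop_if_not(inherits(mat, "screen_matrix"), "mat must be a screen_matrix")
  mat <- refresh_cell_meta(mat)
  meta <- mat$cell_meta
  fail <- cbind(
    low_umis = meta$total_umis < profile$min_umis,
    low_genes = meta$n_genes_detected < profile$min_genes,
    high_umis = meta$total_umis > profile$max_umis,
    high_genes = meta$n_genes_detected > profile$max_genes,
    high_mito = meta$pct_mito > profile$max_pct_mito
  )
  keep <- rowSums(fail) == 0
  if (!any(keep)) stop("no cells survive quality control", call. = FALSE)
  out <- mat
  out$counts <- mat$counts[keep, , drop = FALSE]
  if (!is.null(mat$repeat_counts)) {
    out$repeat_counts <- mat$repeat_counts[keep, , drop = FALSE]
  }
  out$cell_meta <- meta[keep, , drop = FALSE]
  rownames(out$cell_meta) <- NULL
  attr(out, "qc_report") <- list(
    n_in = nrow(meta), n_out = sum(keep),
    removed_per_criterion = colSums(fail[!keep, , drop = FALSE])
  )
  out
}

#' Filter genes by detection
#'
#' Keeps genes detected (UMI count > 0) in at least `min_cells` of the
#' surviving cells.
#'
#' @param mat A `screen_matrix` (cells already filtered).
#' @param min_cells Minimum number of cells a gene must be detected in.
#' @return The filtered `screen_matrix`.
#' @export
filter_genes <- function(mat, min_cells = 10) {
  stop_if_not(inherits(mat, "screen_matrix"), "mat must be a screen_matrix")
  n_detect <- colSums(mat$counts > 0)
  keep <- n_detect >= min_cells
  if (!any(keep)) stop("no genes survive the detection filter", call. = FALSE)
  mat$counts <- mat$counts[, keep, drop = FALSE]
  mat$gene_meta <- mat$gene_meta[keep, , drop = FALSE]
  rownames(mat$gene_meta) <- NULL
  refresh_cell_meta(mat)
}

#' Library-size normalize and log-transform
#'
#' Each entry becomes `ln(1 + count / total_umis * scale_factor)`: counts
#' adjusted by the cell's library size, scaled by 10,000 and natural-log
#' transformed.
#'
#' @param mat A `screen_matrix` with no zero-total cells.
#' @param scale_factor Scaling constant applied after library-size division.
#' @return A `normalized_matrix`: list with `values` (cells x genes),
#'   `scale_factor`, `gene_meta`, `cell_meta` and (once computed) an
#'   `hvg_mask`.
#' @export
normalize_log <- function(mat, scale_factor = 1e4) {
  stop_if_not(inherits(mat, "screen_matrix"), "mat must be a screen_matrix")
  total <- rowSums(mat$counts)
  if (any(total == 0)) stop("cells with zero total UMIs; run filter_cells first",
                            call. = FALSE)
  values <- log1p(mat$counts * (scale_factor / total))
  structure(list(values = values, scale_factor = scale_factor,
                 cell_meta = mat$cell_meta, gene_meta = mat$gene_meta,
                 hvg_mask = NULL),
            class = "normalized_matrix")
}

#' Select highly variable genes
#'
#' Genes are kept when their mean back-scaled expression (mean of
#' `expm1(value)`) lies strictly inside `(min_mean, max_mean)` and their
#' normalized dispersion exceeds `min_disp`. Dispersion is variance/mean of
#' the back-scaled expression, z-scored within 20 equal-frequency bins of
#' the mean; bins with fewer than two genes or zero spread contribute a
#' normalized dispersion of 0.
#'
#' @param norm A `normalized_matrix`.
#' @param min_mean,max_mean Bounds on the back-scaled mean (strict).
#' @param min_disp Minimum normalized dispersion (strict).
#' @param n_bins Number of equal-frequency mean bins.
#' @return The `normalized_matrix` with `hvg_mask` (logical per gene) and a
#'   `hvg_stats` data.frame (mean, dispersion, normalized dispersion).
#' @export
select_hvg <- function(norm, min_mean = 0.01, max_mean = 5, min_disp = 0.5,
                       n_bins = 20) {
  stop_if_not(inherits(norm, "normalized_matrix"),
              "norm must be a normalized_matrix")
  v <- norm$values
  n <- nrow(v)
  g <- ncol(v)
  mu <- numeric(g); m2 <- numeric(g)
  block <- max(1L, floor(4e6 / n))
  for (s in seq(1L, g, by = block)) {
    cols <- s:min(s + block - 1L, g)
    x <- expm1(v[, cols, drop = FALSE])
    mu[cols] <- colMeans(x)
    m2[cols] <- colMeans(x * x)
  }
  vr <- pmax(0, (m2 - mu^2) * n / max(n - 1, 1))
  disp <- ifelse(mu > 0, vr / mu, 0)
  qs <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mu, breaks = qs, include.lowest = TRUE)
  bm <- tapply(disp, bin, mean)
  bs <- tapply(disp, bin, sd)
  dn <- as.vector((disp - bm[bin]) / bs[bin])
  dn[!is.finite(dn)] <- 0
  mask <- mu > min_mean & mu < max_mean & dn > min_disp
  if (!any(mask)) stop("no gene passes the HVG thresholds", call. = FALSE)
  norm$hvg_mask <- unname(mask)
  norm$hvg_stats <- data.frame(gene_id = norm$gene_meta$gene_id,
                               mean = mu, dispersion = disp,
                               dispersion_norm = as.numeric(dn),
                               stringsAsFactors = FALSE)
  norm
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d cells x %d genes (scale %g)",
              nrow(x$values), ncol(x$values), x$scale_factor))
  if (!is.null(x$hvg_mask)) cat(sprintf(", %d HVGs", sum(x$hvg_mask)))
  cat("\n")
  invisible(x)
}
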