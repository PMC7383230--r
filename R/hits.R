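# Per-sgRNA hit calling on the ZGA-like factor, and expressing-fraction
# summaries of the pilot style.

#' Target-gene activation filter
#'
#' For every targeting sgRNA, the mean log2 fold-change of its own target
#' gene in the sgRNA's cells versus all non-targeting cells, computed on
#' mean normalized expression with a pseudocount of 1. Only sgRNAs with
#' log2FC strictly greater than zero enter hit testing.
#'
#' @param norm A `normalized_matrix` (QC-passed, with `assigned_guide` in
#'   `cell_meta`).
#' @param library A `guide_library`.
#' @return An `activation_summary` data.frame: `sgrna_id`, `target_gene`,
#'   `n_cells`, `log2fc`, `passes_activation`.
#' @export
activation_filter <- function(norm, library) {
  stop_if_not(inherits(norm, "normalized_matrix"),
              "norm must be a normalized_matrix")
  guide <- norm$cell_meta$assigned_guide
  stop_if_not(!all(is.na(guide)), "no assigned guides in cell metadata")
  nt_guides <- library$guide_id[!library$is_targeting]
  nt_cells <- which(guide %in% nt_guides)
  stop_if_not(length(nt_cells) > 0, "no non-targeting cells")
  targ <- library[library$is_targeting, , drop = FALSE]
  gene_idx <- match(targ$target_gene, norm$gene_meta$gene_id)
  res <- data.frame(sgrna_id = targ$guide_id,
                    target_gene = targ$target_gene,
                    n_cells = 0L, log2fc = NA_real_,
                    passes_activation = FALSE, stringsAsFactors = FALSE)
  nt_means <- colMeans(norm$values[nt_cells, , drop = FALSE])
  for (i in seq_len(nrow(targ))) {
    cells <- which(guide == targ$guide_id[i])
    res$n_cells[i] <- length(cells)
    if (length(cells) == 0 || is.na(gene_idx[i])) {
      warning("sgRNA ", targ$guide_id[i],
              " has no assigned cells or unknown target; skipped",
              call. = FALSE)
      next
    }
    m_sg <- mean(norm$values[cells, gene_idx[i]])
    m_nt <- nt_means[gene_idx[i]]
    res$log2fc[i] <- log2((m_sg + 1) / (m_nt + 1))
    res$passes_activation[i] <- res$log2fc[i] > 0
  }
  class(res) <- c("activation_summary", "data.frame")
  res
}

#' Factor-on-indicator regression for one sgRNA
#'
#' Ordinary least squares of the factor values on an intercept plus a
#' binary indicator (1 for the targeting sgRNA's cells, 0 for
#' non-targeting cells), over the union of the two groups. The effect size
#' delta is the indicator coefficient — identically the difference of
#' group means — and the p-value comes from the Gaussian likelihood-ratio
#' test of the indicator (chi-squared, 1 df).
#'
#' @param z_sgrna Factor values of the sgRNA's cells.
#' @param z_nt Factor values of the non-targeting cells.
#' @return List with `delta`, `pvalue`, `lrt_statistic`, `n`.
#' @export
regress_factor <- function(z_sgrna, z_nt) {
  n1 <- length(z_sgrna); n0 <- length(z_nt)
  stop_if_not(n1 >= 2 && n0 >= 2, "each group needs at least 2 cells")
  z <- c(z_sgrna, z_nt)
  n <- n1 + n0
  delta <- mean(z_sgrna) - mean(z_nt)
  rss1 <- sum((z_sgrna - mean(z_sgrna))^2) + sum((z_nt - mean(z_nt))^2)
  rss0 <- sum((z - mean(z))^2)
  lrt <- if (rss1 <= 0) {
    if (rss0 <= rss1 + 1e-300) 0 else Inf
  } else {
    n * log(rss0 / rss1)
  }
  list(delta = delta, pvalue = pchisq(lrt, df = 1, lower.tail = FALSE),
       lrt_statistic = lrt, n = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement, capped at 1.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(pvalues) {
  stop_if_not(all(!is.na(pvalues)) && all(pvalues >= 0 & pvalues <= 1),
              "p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Call screen hits at an FDR threshold
#'
#' Runs the indicator regression for every activation-passing sgRNA against
#' the pooled non-targeting cells, adjusts p-values by Benjamini-Hochberg
#' over that set only, and flags hits at `q < fdr`.
#'
#' @param z Per-cell factor values (the ZGA-like factor).
#' @param guide Per-cell assigned guide ids (same order as `z`).
#' @param library A `guide_library`.
#' @param activation An `activation_summary` (or NULL to test all
#'   targeting sgRNAs).
#' @param fdr FDR threshold.
#' @param min_cells sgRNAs with fewer assigned cells are skipped.
#' @return A `hit_table` data.frame sorted by q-value: `sgrna_id`,
#'   `target_gene`, `n_cells`, `delta`, `pvalue`, `qvalue`, `is_hit`;
#'   attribute `hit_genes` lists target genes whose sgRNAs are all hits.
#' @export
call_hits <- function(z, guide, library, activation = NULL, fdr = 0.10,
                      min_cells = 2) {
  stop_if_not(length(z) == length(guide), "z and guide must be aligned")
  nt_guides <- library$guide_id[!library$is_targeting]
  z_nt <- z[guide %in% nt_guides]
  test_set <- library$guide_id[library$is_targeting]
  if (!is.null(activation)) {
    test_set <- intersect(test_set,
                          activation$sgrna_id[activation$passes_activation])
  }
  rows <- lapply(test_set, function(g) {
    zg <- z[!is.na(guide) & guide == g]
    if (length(zg) < min_cells) return(NULL)
    r <- regress_factor(zg, z_nt)
    data.frame(sgrna_id = g,
               target_gene = library$target_gene[match(g, library$guide_id)],
               n_cells = length(zg), delta = r$delta, pvalue = r$pvalue,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0) {
    res <- data.frame(sgrna_id = character(), target_gene = character(),
                      n_cells = integer(), delta = numeric(),
                      pvalue = numeric(), qvalue = numeric(),
                      is_hit = logical(), stringsAsFactors = FALSE)
    class(res) <- c("hit_table", "data.frame")
    return(res)
  }
  res$qvalue <- bh_adjust(res$pvalue)
  res$is_hit <- res$qvalue < fdr
  res <- res[order(res$qvalue, res$pvalue, res$sgrna_id), , drop = FALSE]
  rownames(res) <- NULL
  hit_targets <- res$target_gene[res$is_hit]
  per_gene <- table(library$target_gene[library$is_targeting])
  both <- names(per_gene)[vapply(names(per_gene), function(g)
    sum(hit_targets == g) == per_gene[[g]], TRUE)]
  attr(res, "hit_genes") <- sort(intersect(both, hit_targets))
  class(res) <- c("hit_table", "data.frame")
  res
}

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf("hit_table: %d sgRNAs tested, %d hits\n", nrow(x),
              sum(x$is_hit)))
  if (sum(x$is_hit)) {
    print.data.frame(head(x[x$is_hit, ], 10), digits = 3)
  }
  invisible(x)
}

#' Fraction of cells expressing a gene signature
#'
#' A cell "expresses" the signature when its summed raw UMIs over the
#' signature genes reach `min_signature_umis`.
#'
#' @param mat A `screen_matrix`.
#' @param cells Indices or barcodes of the group's cells.
#' @param signature Signature gene ids.
#' @param min_signature_umis Minimum summed UMIs to count as expressing.
#' @param group Label carried into the output.
#' @return A `signature_fraction` list: `group`, `fraction`, `n_cells`,
#'   `n_expressing`.
#' @export
signature_fraction <- function(mat, cells, signature,
                               min_signature_umis = 3, group = "group") {
  stop_if_not(inherits(mat, "screen_matrix"), "mat must be a screen_matrix")
  if (is.character(cells)) cells <- match(cells, mat$cell_meta$barcode)
  stop_if_not(length(cells) > 0 && all(!is.na(cells)), "empty or unknown group")
  sig_idx <- which(mat$gene_meta$gene_id %in% signature)
  tot <- rowSums(mat$counts[cells, sig_idx, drop = FALSE])
  expressing <- tot >= min_signature_umis
  structure(list(group = group, fraction = mean(expressing),
                 n_cells = length(cells), n_expressing = sum(expressing)),
            class = "signature_fraction")
}

#' Fold change between expressing fractions
#'
#' @param treated,control `signature_fraction` objects (or plain fractions).
#' @return The ratio `treated / control`.
#' @export
fold_change_of_fractions <- function(treated, control) {
  tf <- if (inherits(treated, "signature_fraction")) treated$fraction else treated
  cf <- if (inherits(control, "signature_fraction")) control$fraction else control
  stop_if_not(cf > 0, "control fraction must be positive")
  tf / cf
}
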