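# Per-sgRNA negative-binomial differential expression and the cumulative
# signature-rank enrichment statistic with its non-targeting background.

# One-parameter NB MLE (log link, offset log s) per gene, vectorized over
# genes. Returns the mu-dependent part of the maximized log-likelihood and
# the fitted offset-adjusted mean.
nb_fit_group <- function(Y, s, phi) {
  cs <- colSums(Y)
  m <- cs / sum(s)
  ll <- numeric(ncol(Y))
  zero <- cs == 0
  if (!all(zero)) {
    idx <- which(!zero)
    beta <- log(m[idx])
    for (it in 1:50) {
      MU <- outer(s, exp(beta))
      PM <- sweep(MU, 2, phi[idx], "*")
      score <- colSums((Y[, idx, drop = FALSE] - MU) / (1 + PM))
      info <- colSums(MU * (1 + sweep(Y[, idx, drop = FALSE], 2, phi[idx], "*")) /
                        (1 + PM)^2)
      step <- score / pmax(info, 1e-12)
      step <- pmax(pmin(step, 2), -2)
      beta <- beta + step
      if (max(abs(step)) < 1e-10) break
    }
    m[idx] <- exp(beta)
    MU <- outer(s, m[idx])
    PM <- sweep(MU, 2, phi[idx], "*")
    Yi <- Y[, idx, drop = FALSE]
    lt <- Yi * log(PM)
    lt[Yi == 0] <- 0
    inv_phi <- rep(1 / phi[idx], each = length(s))
    ll[idx] <- colSums(lt - (Yi + inv_phi) * log1p(PM))
  }
  list(loglik = ll, mean = m)
}

#' Negative-binomial likelihood-ratio test, per gene
#'
#' Fits, for every gene, a negative-binomial model with log link and
#' log-library-size offset under a shared mean (null) and under
#' group-specific means (alternative), with a per-gene dispersion
#' estimated by method of moments on offset-adjusted counts (floored at
#' 1e-8, shared between the two fits). The test statistic is twice the
#' log-likelihood difference, referred to chi-squared with 1 df. Genes
#' with all-zero counts get p = 1 and log2FC = 0.
#'
#' @param counts Cells x genes matrix of raw UMIs (both groups stacked).
#' @param group Logical or 0/1 vector: TRUE/1 marks the sgRNA group,
#'   FALSE/0 the comparison (non-targeting) group.
#' @param libsize Per-cell total UMIs used as offsets (defaults to row
#'   sums of `counts`).
#' @param dispersion Optional fixed per-gene dispersion vector.
#' @return A `dge_result` data.frame: `gene_id`, `log2fc`,
#'   `lrt_statistic`, `pvalue`, `qvalue`, `dispersion`.
#' @export
nb_glm_lrt <- function(counts, group, libsize = NULL, dispersion = NULL) {
  group <- as.logical(group)
  stop_if_not(sum(group) >= 2 && sum(!group) >= 2,
              "each group needs at least 2 cells")
  Y <- as.matrix(counts)
  s <- libsize %||% rowSums(Y)
  stop_if_not(all(s > 0), "library sizes must be positive")
  G <- ncol(Y)
  ids <- colnames(Y) %||% sprintf("gene%05d", seq_len(G))

  m1 <- colSums(Y[group, , drop = FALSE]) / sum(s[group])
  m0 <- colSums(Y[!group, , drop = FALSE]) / sum(s[!group])
  if (is.null(dispersion)) {
    MU <- matrix(0, nrow(Y), G)
    MU[group, ] <- outer(s[group], m1)
    MU[!group, ] <- outer(s[!group], m0)
    n <- nrow(Y)
    num <- colSums((Y - MU)^2) * n / max(n - 2, 1) - colSums(MU)
    den <- colSums(MU^2)
    dispersion <- pmax(ifelse(den > 0, num / den, 0), 1e-8)
  } else {
    dispersion <- rep_len(pmax(dispersion, 1e-8), G)
  }

  f_null <- nb_fit_group(Y, s, dispersion)
  f1 <- nb_fit_group(Y[group, , drop = FALSE], s[group], dispersion)
  f0 <- nb_fit_group(Y[!group, , drop = FALSE], s[!group], dispersion)
  lrt <- pmax(0, 2 * (f1$loglik + f0$loglik - f_null$loglik))
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  eps <- 1e-8
  log2fc <- log2((m1 + eps) / (m0 + eps))
  allzero <- colSums(Y) == 0
  p[allzero] <- 1
  log2fc[allzero] <- 0
  lrt[allzero] <- 0
  res <- data.frame(gene_id = ids, log2fc = log2fc, lrt_statistic = lrt,
                    pvalue = p, qvalue = bh_adjust(p),
                    dispersion = dispersion, stringsAsFactors = FALSE)
  class(res) <- c("dge_result", "data.frame")
  res
}

#' Rank upregulated genes by significance
#'
#' Genes with log2FC > 0 sorted by ascending p-value; ties broken by
#' descending log2FC, then lexicographically by gene id; truncated at
#' `max_rank`.
#'
#' @param dge A `dge_result`.
#' @param max_rank Maximum list length.
#' @return Character vector of gene ids.
#' @export
rank_upregulated <- function(dge, max_rank = 400) {
  up <- dge[dge$log2fc > 0, , drop = FALSE]
  o <- order(up$pvalue, -up$log2fc, up$gene_id)
  head(up$gene_id[o], max_rank)
}

#' Cumulative signature count along a ranked gene list
#'
#' `curve[r]` is the number of signature genes among the top `r` ranked
#' genes; ranks beyond the list length carry the final count forward.
#'
#' @param ranked Character vector of ranked gene ids.
#' @param signature Signature gene ids.
#' @param max_rank Curve length.
#' @return Integer vector of length `max_rank`.
#' @export
cumulative_zga_curve <- function(ranked, signature, max_rank = 400) {
  hits <- cumsum(ranked %in% signature)
  if (length(hits) >= max_rank) return(hits[seq_len(max_rank)])
  c(hits, rep(if (length(hits)) hits[length(hits)] else 0L,
              max_rank - length(hits)))
}

#' Non-targeting background band for the enrichment curve
#'
#' Each non-targeting sgRNA's cells are compared against the union of the
#' other non-targeting cells with the full DGE + curve pipeline; the band
#' is the per-rank mean plus/minus one standard deviation over those
#' curves.
#'
#' @param counts Cells x genes raw UMIs of all non-targeting cells.
#' @param guide Per-cell guide ids (non-targeting labels).
#' @param signature Signature gene ids.
#' @param libsize Optional per-cell totals.
#' @param max_rank Curve length.
#' @return A `background_band` list: `mean`, `sd` (length `max_rank`),
#'   `curves` (matrix, one column per NT sgRNA).
#' @export
nt_background <- function(counts, guide, signature, libsize = NULL,
                          max_rank = 400) {
  nt <- sort(unique(guide))
  stop_if_not(length(nt) >= 3, "need at least 3 non-targeting sgRNAs")
  s <- libsize %||% rowSums(counts)
  curves <- vapply(nt, function(g) {
    grp <- guide == g
    dge <- nb_glm_lrt(counts, grp, s)
    cumulative_zga_curve(rank_upregulated(dge, max_rank), signature,
                         max_rank)
  }, numeric(max_rank))
  structure(list(mean = rowMeans(curves),
                 sd = apply(curves, 1, sd),
                 curves = curves),
            class = "background_band")
}

#' Does an enrichment curve overlap the background band?
#'
#' TRUE when the curve at `rank` does not exceed the background mean plus
#' one standard deviation, i.e. the sgRNA is NOT enriched beyond the
#' non-targeting control behaviour.
#'
#' @param curve An enrichment curve ([cumulative_zga_curve()]).
#' @param band A `background_band`.
#' @param rank Rank at which to compare.
#' @return Logical flag.
#' @export
enrichment_call <- function(curve, band, rank = 400) {
  stop_if_not(rank >= 1 && rank <= length(curve) &&
                rank <= length(band$mean), "rank out of range")
  curve[rank] <= band$mean[rank] + band$sd[rank]
}
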