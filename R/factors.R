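# Multi-view latent factor decomposition of gene and repeat expression.
#
# A deterministic truncated singular-value decomposition of the
# feature-standardized, variance-balanced concatenation of the views.
# Group (sgRNA) labels are carried along and summarised descriptively but
# do not alter the fit.

#' Fit a multi-view factor decomposition
#'
#' Each view's features are centred and scaled to unit variance, the view is
#' rescaled to unit total variance (so views contribute equally regardless
#' of feature count or measurement scale), and the concatenated matrix is
#' decomposed by a rank-`K` SVD. Factor values `Z` (cells x K) have
#' mutually orthogonal columns; per-view loadings `W` are the right
#' singular vectors. The sign convention makes the largest-magnitude
#' loading of each factor positive, so the fit is fully deterministic.
#'
#' @param views Named list of cells-by-features numeric matrices, row
#'   aligned across views (e.g. `genes` and `repeats`).
#' @param groups Optional per-cell group labels (the sgRNA assignment);
#'   reported as per-group factor means, never used in the fit.
#' @param K Number of factors.
#' @return A `factor_fit` with `Z`, `W` (list per view), `d` (singular
#'   values), `var_explained` (K x views), `group_means` (if groups given),
#'   `feature_ids`, `view_of_feature`.
#' @export
fit_factors <- function(views, groups = NULL, K = 5) {
  stop_if_not(is.list(views) && length(views) >= 1 && !is.null(names(views)),
              "views must be a named list of matrices")
  n <- nrow(views[[1]])
  stop_if_not(n >= 2, "need at least two cells")
  for (v in views) stop_if_not(nrow(v) == n, "views must be row-aligned")
  total_features <- sum(vapply(views, ncol, 0L))
  stop_if_not(K >= 1, "K must be at least 1")
  stop_if_not(K <= min(n, total_features),
              "K exceeds min(cells, total features)")
  if (!is.null(groups)) stop_if_not(length(groups) == n,
                                    "groups must label every cell")

  std <- lapply(views, function(v) {
    v <- as.matrix(v)
    cm <- colMeans(v)
    v <- sweep(v, 2, cm)
    csd <- sqrt(colSums(v^2) / max(n - 1, 1))
    nz <- csd > 0
    v[, nz] <- sweep(v[, nz, drop = FALSE], 2, csd[nz], "/")
    # balance views: unit total variance per view
    tv <- sum(nz)
    if (tv > 0) v <- v / sqrt(tv)
    v
  })
  X <- do.call(cbind, std)
  feature_ids <- unlist(lapply(views, function(v)
    colnames(v) %||% as.character(seq_len(ncol(v)))), use.names = FALSE)
  view_of_feature <- rep(names(views), vapply(views, ncol, 0L))

  # eigen-decomposition of the (small) feature-by-feature Gram matrix
  S <- crossprod(X)
  ev <- eigen(S, symmetric = TRUE)
  d2 <- pmax(ev$values[seq_len(K)], 0)
  V <- ev$vectors[, seq_len(K), drop = FALSE]
  Z <- X %*% V
  # deterministic sign: largest |loading| per factor is positive
  for (k in seq_len(K)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) {
      V[, k] <- -V[, k]
      Z[, k] <- -Z[, k]
    }
  }
  colnames(Z) <- paste0("factor_", seq_len(K))
  rownames(Z) <- rownames(views[[1]])
  rownames(V) <- feature_ids
  colnames(V) <- colnames(Z)

  ss_view <- vapply(names(views), function(nm)
    sum(X[, view_of_feature == nm, drop = FALSE]^2), 0)
  ve <- vapply(names(views), function(nm) {
    idx <- view_of_feature == nm
    if (ss_view[nm] == 0) return(rep(0, K))
    colSums(V[idx, , drop = FALSE]^2) * d2 / ss_view[nm]
  }, numeric(K))
  ve <- matrix(ve, nrow = K,
               dimnames = list(colnames(Z), names(views)))

  W <- lapply(names(views), function(nm)
    V[view_of_feature == nm, , drop = FALSE])
  names(W) <- names(views)

  group_means <- NULL
  if (!is.null(groups)) {
    group_means <- apply(Z, 2, function(z) tapply(z, groups, mean))
  }
  structure(list(Z = Z, W = W, d = sqrt(d2), K = K,
                 var_explained = ve, group_means = group_means,
                 feature_ids = feature_ids,
                 view_of_feature = view_of_feature),
            class = "factor_fit")
}

#' @export
print.factor_fit <- function(x, ...) {
  cat(sprintf("factor_fit: %d cells, %d factors, views: %s\n",
              nrow(x$Z), x$K, paste(names(x$W), collapse = ", ")))
  cat("variance explained (per view):\n")
  print(round(x$var_explained, 4))
  invisible(x)
}

#' Rank features by absolute loading
#'
#' @param fit A `factor_fit`.
#' @param factor_index Factor to rank (1-based).
#' @param view View name.
#' @param top_n Number of features returned.
#' @return Data.frame of features sorted by decreasing |loading|, ties
#'   broken lexicographically by feature id.
#' @export
rank_loadings <- function(fit, factor_index, view, top_n = 50) {
  stop_if_not(inherits(fit, "factor_fit"), "fit must be a factor_fit")
  stop_if_not(factor_index >= 1 && factor_index <= fit$K,
              "factor_index out of range")
  stop_if_not(view %in% names(fit$W), "unknown view")
  w <- fit$W[[view]][, factor_index]
  ids <- rownames(fit$W[[view]])
  o <- order(-abs(w), ids)
  o <- o[seq_len(min(top_n, length(o)))]
  data.frame(feature_id = ids[o], loading = w[o],
             abs_loading = abs(w[o]), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Identify the ZGA-like factor
#'
#' For each factor, computes the hypergeometric enrichment p-value of the
#' signature genes among the top `top_n` gene loadings (by absolute value).
#' The ZGA-like factor is the one minimising this p-value, provided
#' p < `p_threshold` and the designated repeat family carries the largest
#' absolute repeat loading of that factor. Absence of a qualifying factor
#' is a valid result (`NA`).
#'
#' @param fit A `factor_fit` with `genes` and `repeats` views.
#' @param signature Character vector of signature gene ids.
#' @param repeat_family Repeat family required at the top of the repeat
#'   loadings.
#' @param top_n Number of top gene loadings tested.
#' @param p_threshold Enrichment significance threshold.
#' @return A list with `factor_index` (NA if none qualifies) and a
#'   per-factor data.frame `table` (enrichment p, overlap, top repeat).
#' @export
identify_zga_factor <- function(fit, signature, repeat_family = "MERVL",
                                top_n = 50, p_threshold = 0.01) {
  stop_if_not(inherits(fit, "factor_fit"), "fit must be a factor_fit")
  stop_if_not(length(signature) > 0, "signature is empty")
  stop_if_not(all(c("genes", "repeats") %in% names(fit$W)),
              "fit must have 'genes' and 'repeats' views")
  gene_ids <- rownames(fit$W$genes)
  m <- sum(gene_ids %in% signature)
  N <- length(gene_ids)
  top_n <- min(top_n, N)
  if (m == 0 || m == N) {
    tab <- data.frame(factor = seq_len(fit$K), p_enrichment = NA_real_,
                      overlap = NA_integer_, top_repeat = NA_character_)
    return(list(factor_index = NA_integer_, table = tab,
                reason = "signature covers none or all genes; enrichment undefined"))
  }
  p <- numeric(fit$K)
  overlap <- integer(fit$K)
  top_rep <- character(fit$K)
  for (k in seq_len(fit$K)) {
    top <- rank_loadings(fit, k, "genes", top_n)$feature_id
    q <- sum(top %in% signature)
    overlap[k] <- q
    p[k] <- phyper(q - 1, m, N - m, top_n, lower.tail = FALSE)
    top_rep[k] <- rank_loadings(fit, k, "repeats", 1)$feature_id
  }
  tab <- data.frame(factor = seq_len(fit$K), p_enrichment = p,
                    overlap = overlap, top_repeat = top_rep,
                    stringsAsFactors = FALSE)
  ok <- p < p_threshold & top_rep == repeat_family
  idx <- if (any(ok)) which(ok)[which.min(p[ok])] else NA_integer_
  list(factor_index = idx, table = tab)
}

#' Variance explained per factor and view
#'
#' The fraction of each view's (standardized) sum of squares reconstructed
#' by each single factor; rows sum to at most 1 per view because factor
#' directions are orthogonal.
#'
#' @param fit A `factor_fit`.
#' @return K x views numeric matrix of fractions in `[0, 1]`.
#' @export
variance_explained <- function(fit) {
  stop_if_not(inherits(fit, "factor_fit"), "fit must be a factor_fit")
  fit$var_explained
}
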