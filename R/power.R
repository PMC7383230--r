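# Exact power and sample size for Fisher's exact test on two proportions.

# Conditional p-values for all outcomes of one table margin.
# pr: hypergeometric pmf over the support of k1 given K successes total.
fisher_pvalues <- function(pr, alternative, midp) {
  cdf <- cumsum(pr)
  sf <- rev(cumsum(rev(pr)))
  eps <- 1e-7  # relative tolerance for probability-mass ties
  if (alternative == "one.sided") {
    pv <- if (midp) sf - 0.5 * pr else sf
  } else if (alternative == "central") {
    pv <- if (midp) 2 * pmin(cdf - 0.5 * pr, sf - 0.5 * pr)
          else 2 * pmin(cdf, sf)
    pv <- pmin(pv, 1)
  } else {  # two.sided: probability-mass method
    o <- order(pr)
    cum <- cumsum(pr[o])
    le <- findInterval(pr * (1 + eps), pr[o])
    pv <- cum[le]
    if (midp) {
      lt <- findInterval(pr * (1 - eps), pr[o])
      p_lt <- ifelse(lt > 0, cum[lt], 0)
      pv <- p_lt + 0.5 * (pv - p_lt)
    }
  }
  pv
}

#' Exact power of Fisher's exact test for two proportions
#'
#' Enumerates both binomial outcome distributions — `k0 ~ Bin(n0, p0)`,
#' `k1 ~ Bin(n, p1)` — and sums the joint probability of every table whose
#' Fisher exact p-value is at most `alpha`. The `two.sided` convention is
#' the probability-mass method (the sum of hypergeometric outcomes no more
#' probable than the observed one, with the customary 1e-7 relative
#' tolerance); `central` doubles the smaller tail; `one.sided` takes the
#' upper tail of the treated group (detecting `p1 > p0`). `midp` subtracts
#' half the observed outcome's probability.
#'
#' @param p0,p1 Control and alternative proportions.
#' @param n Cells in the treated group.
#' @param alpha Significance level.
#' @param alternative P-value convention.
#' @param midp Use the mid-p variant.
#' @param n0 Cells in the control group (defaults to `n`).
#' @return The exact power (a probability).
#' @export
fisher_power <- function(p0, p1, n, alpha = 0.00032,
                         alternative = c("two.sided", "one.sided", "central"),
                         midp = FALSE, n0 = n) {
  alternative <- match.arg(alternative)
  stop_if_not(n >= 1 && n0 >= 1, "group sizes must be at least 1")
  stop_if_not(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  d0 <- dbinom(0:n0, n0, p0)
  d1 <- dbinom(0:n, n, p1)
  pow <- 0
  for (K in 0:(n + n0)) {
    lo <- max(0L, K - n0)
    hi <- min(n, K)
    x <- lo:hi
    pr <- dhyper(x, n, n0, K)
    pv <- fisher_pvalues(pr, alternative, midp)
    sig <- pv <= alpha
    if (!any(sig)) next
    k1 <- x[sig]
    pow <- pow + sum(d1[k1 + 1L] * d0[K - k1 + 1L])
  }
  pow
}

#' Smallest sample size reaching a target power
#'
#' Finds, by bracketing and bisection on the exact power curve, the
#' smallest per-group `n` at which [fisher_power()] reaches
#' `power_target` and stays there for the next `stability` consecutive
#' values of `n` (exact tests have a mildly saw-toothed power curve, so a
#' single crossing can be spurious).
#'
#' @inheritParams fisher_power
#' @param power_target Desired power.
#' @param stability Number of consecutive `n` values that must hold the
#'   target.
#' @param n_max Search ceiling.
#' @return A list with `n_per_group` and `achieved_power`.
#' @export
min_sample_size <- function(p0, p1, alpha = 0.00032, power_target = 0.8,
                            alternative = c("two.sided", "one.sided",
                                            "central"),
                            midp = FALSE, stability = 5, n_max = 20000) {
  alternative <- match.arg(alternative)
  stop_if_not(p0 != p1, "p0 = p1: no finite sample size reaches the target")
  pw <- function(n) fisher_power(p0, p1, n, alpha, alternative, midp)
  # bracket with a normal-approximation starting point
  za <- qnorm(1 - if (alternative == "one.sided") alpha else alpha / 2)
  zb <- qnorm(power_target)
  pbar <- (p0 + p1) / 2
  n_approx <- ((za * sqrt(2 * pbar * (1 - pbar)) +
                  zb * sqrt(p0 * (1 - p0) + p1 * (1 - p1))) /
                 abs(p1 - p0))^2
  lo <- max(2L, floor(0.4 * n_approx))
  hi <- lo
  while (pw(hi) < power_target) {
    lo <- hi
    hi <- min(n_max, hi * 2L)
    if (hi >= n_max && pw(n_max) < power_target) {
      stop("power target not reached below n_max = ", n_max, call. = FALSE)
    }
  }
  while (pw(lo) >= power_target && lo > 2L) {
    hi <- lo
    lo <- max(2L, floor(lo / 2))
  }
  while (hi - lo > 1L) {
    mid <- floor((lo + hi) / 2)
    if (pw(mid) >= power_target) hi <- mid else lo <- mid
  }
  n <- hi
  repeat {
    window <- vapply(n:(n + stability - 1L), pw, 0)
    if (all(window >= power_target)) break
    n <- n + which(window < power_target)[1]
    stop_if_not(n <= n_max, "no stable crossing below n_max")
  }
  list(n_per_group = n, achieved_power = pw(n))
}
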