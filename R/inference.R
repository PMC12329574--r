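#' Exact upper tail of the binomial null
#'
#' Probability of observing a score *strictly greater* than `s` under
#' `Binomial(n, p)`, computed by exact log-space summation of the
#' probability mass from `s + 1` to `n` (no normal approximation).
#'
#' This is the null model for cross-validated classification accuracy:
#' `n` evaluated maps with per-map success probability `1 / #classes`.
#' With `n = 100`, `p = 0.25`, a score of 32 has tail probability 0.045;
#' with `n = 50`, `p = 0.5`, a score of 32 has tail probability 0.0164.
#'
#' @param s Integer score in `[0, n]`.
#' @param n Number of trials.
#' @param p Per-trial success probability in (0, 1).
#' @return `P(X > s)`.
#' @export
tail_p <- function(s, n, p) {
  stopifnot(length(s) == 1L, length(n) == 1L, length(p) == 1L,
            n >= 1, n == round(n), p > 0, p < 1)
  if (s < 0 || s > n || s != round(s)) stop("score must be an integer in [0, n]")
  if (s == n) return(0)
  x <- (s + 1):n
  logmass <- lchoose(n, x) + x * log(p) + (n - x) * log1p(-p)
  m <- max(logmass)
  exp(m + log(sum(exp(logmass - m))))
}

#' Chance-level score threshold
#'
#' Smallest integer score `s` whose exact upper tail falls below
#' `alpha`; scores of `s` or more are then called above chance at level
#' `alpha`. For the 4-class setting (`n = 100`, `p = 0.25`,
#' `alpha = 0.05`) the threshold is 32/100.
#'
#' @param n,p Binomial null parameters, as in [tail_p()].
#' @param alpha Significance level in (0, 1].
#' @return Integer threshold score.
#' @export
chance_threshold <- function(n, p, alpha = 0.05) {
  stopifnot(alpha > 0, alpha <= 1)
  for (s in 0:n) {
    if (tail_p(s, n, p) < alpha) return(as.integer(s))
  }
  as.integer(n)  # unreachable for alpha > 0
}

#' Bonferroni-corrected significance level
#'
#' @param alpha Family-wise level.
#' @param m Number of tests (>= 1).
#' @return `alpha / m` (0.05 over 4 tests gives 0.0125).
#' @export
bonferroni <- function(alpha, m) {
  stopifnot(alpha > 0, m >= 1, m == round(m))
  alpha / m
}

#' Selection-aware tail: maximum of K independent null scores
#'
#' When the reported accuracy is the best over `K` searched
#' configurations, the conservative null is the maximum of `K`
#' independent `Binomial(n, p)` scores:
#' `P(max > s) = 1 - (1 - tail_p(s, n, p))^K`. With `K = 1` this reduces
#' to [tail_p()]. Reported p-values in this package default to the
#' single-binomial tail (which the per-score probabilities quoted above
#' correspond to), with this max-corrected tail available alongside,
#' clearly labeled.
#'
#' @param s,n,p As in [tail_p()].
#' @param K Number of configurations searched (>= 1).
#' @return `P(max of K null scores > s)`.
#' @export
max_corrected_tail <- function(s, n, p, K) {
  stopifnot(K >= 1, K == round(K))
  t1 <- tail_p(s, n, p)
  -expm1(K * log1p(-t1))
}

#' Binomial inference report for an observed accuracy score
#'
#' Bundles the exact single-binomial tail, the selection-aware
#' max-corrected tail, and the chance thresholds at `alpha` and its
#' Bonferroni correction over `m_tests`.
#'
#' @param score Observed integer score (correct classifications).
#' @param n Evaluations (maps scored).
#' @param p Null success probability (1 / #classes).
#' @param K Configurations searched.
#' @param alpha Significance level.
#' @param m_tests Number of tests for the Bonferroni correction.
#' @return List of class `inference_report`.
#' @export
inference_report <- function(score, n, p, K = 5760L, alpha = 0.05,
                             m_tests = 1L) {
  alpha_corr <- bonferroni(alpha, m_tests)
  structure(list(
    score = score, n = n, p = p, K = K, alpha = alpha,
    alpha_corrected = alpha_corr,
    tail_p = tail_p(score, n, p),
    max_corrected_tail = max_corrected_tail(score, n, p, K),
    chance_threshold = chance_threshold(n, p, alpha),
    chance_threshold_corrected = chance_threshold(n, p, alpha_corr),
    note = paste("tail_p is the exact single-binomial upper tail;",
                 "max_corrected_tail treats the score as the best of K",
                 "independent null configurations")),
    class = "inference_report")
}

#' @export
print.inference_report <- function(x, ...) {
  cat(sprintf("score %d/%d (p0 = %g): tail p = %.4g, max-of-%d corrected p = %.4g\n",
              x$score, x$n, x$p, x$tail_p, x$K, x$max_corrected_tail))
  cat(sprintf("chance threshold at alpha %.4g: %d; at corrected alpha %.4g: %d\n",
              x$alpha, x$chance_threshold, x$alpha_corrected,
              x$chance_threshold_corrected))
  invisible(x)
}
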