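#' One-sided exact binomial tail probability
#'
#' Exact p-value for testing whether a binomial success probability exceeds
#' `p0`: the upper tail \eqn{P(X \ge k)} for \eqn{X \sim Bin(n, p_0)},
#' obtained by direct summation of the probability mass function.
#'
#' @param k Number of successes (detections).
#' @param n Number of trials (bootstrap occurrences).
#' @param p0 Null success probability.
#'
#' @return A p-value in \[0, 1\].
#' @export
#' @examples
#' binom_pvalue_greater(43, 72)  # 0.062 at two decimals
binom_pvalue_greater <- function(k, n, p0 = 0.5) {
  check_counts(k, n)
  if (!is.numeric(p0) || p0 <= 0 || p0 >= 1) {
    ob_abort("p0 must lie strictly between 0 and 1", "input")
  }
  vapply(seq_along(k), function(i) {
    min(1, sum(dbinom(k[i]:n[i], n[i], p0)))
  }, numeric(1))
}

#' One-sided Clopper-Pearson lower confidence bound
#'
#' Exact lower bound of the one-sided `1 - alpha` confidence interval for a
#' binomial proportion: the `alpha` quantile of the Beta(k, n - k + 1)
#' distribution, with the conventions 0 when `k = 0` and
#' `alpha^(1/n)` when `k = n`. The corresponding interval is
#' `[lower, 1]`.
#'
#' @inheritParams binom_pvalue_greater
#' @param alpha One minus the confidence level.
#'
#' @return The lower bound, in \[0, 1\].
#' @export
#' @examples
#' clopper_pearson_lower(68, 68)  # 0.9569..., prints as 0.96
clopper_pearson_lower <- function(k, n, alpha = 0.05) {
  check_counts(k, n)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    ob_abort("alpha must lie strictly between 0 and 1", "input")
  }
  ifelse(k == 0, 0, qbeta(alpha, k, n - k + 1))
}

check_counts <- function(k, n) {
  if (length(k) != length(n)) ob_abort("k and n must have equal length", "input")
  bad <- !is.finite(k) | !is.finite(n) | k < 0 | n < 1 | k > n |
    k != round(k) | n != round(n)
  if (any(bad)) ob_abort("counts must satisfy 0 <= k <= n, n >= 1", "input")
}

#' Samples with significantly high outlier probability
#'
#' Filters an [outlier table][bootstrap_outlier_probabilities] to the samples
#' whose one-sided binomial p-value falls below `alpha`, sorted by descending
#' outlier probability and then by sample id.
#'
#' @param table An `outlier_table` (or any tibble with columns `sample_id`,
#'   `probability`, `p_value`).
#' @param alpha Significance level.
#'
#' @return Character vector of sample ids.
#' @export
significant_outliers <- function(table, alpha = 0.05) {
  stopifnot(all(c("sample_id", "probability", "p_value") %in% names(table)))
  hit <- table[!is.na(table$p_value) & table$p_value < alpha, ]
  hit <- hit[order(-hit$probability, hit$sample_id), ]
  hit$sample_id
}
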