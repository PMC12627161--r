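#' Power of a paired two-tailed t-test
#'
#' Exact power from the noncentral t distribution: with `n` pairs, effect
#' size `d` (mean difference in within-pair SD units) and two-tailed level
#' `alpha`, the test statistic is noncentral t with `n - 1` degrees of
#' freedom and noncentrality \eqn{d\sqrt{n}}.
#'
#' @param n Number of pairs (>= 2).
#' @param d Standardized effect size.
#' @param alpha Two-tailed significance level.
#' @return Power in \[0, 1\].
#' @export
power_paired_t <- function(n, d, alpha = 0.05) {
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  df <- n - 1
  crit <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  (1 - stats::pt(crit, df, ncp)) + stats::pt(-crit, df, ncp)
}

#' Minimal sample size for a paired t-test
#'
#' Iterates `n` upward until [power_paired_t()] first reaches the requested
#' power — the a-priori power analysis for a single paired comparison.
#'
#' @param d Standardized effect size.
#' @param power Target power.
#' @param alpha Two-tailed significance level.
#' @param n_max Upper search bound.
#' @return The smallest integer `n` whose power reaches `power`.
#' @examples
#' required_sample_size(d = 0.73)  # 17
#' @export
required_sample_size <- function(d, power = 0.80, alpha = 0.05,
                                 n_max = 10000L) {
  stopifnot(d > 0, power > 0, power < 1)
  for (n in 2:n_max) {
    if (power_paired_t(n, d, alpha) >= power) return(n)
  }
  stop("no n up to ", n_max, " reaches the requested power")
}
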