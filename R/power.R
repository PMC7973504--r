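# Study-design calculations: minimal detectable effect size of a two-sided
# unpaired two-sample t-test (noncentral t), its Monte-Carlo cross-check,
# and the log-normal CV-based conversion between Cohen's d and raw-scale
# fold change.

#' Power of a two-sided two-sample t-test at effect size d
#'
#' Exact power under normality via the noncentral t distribution:
#' `df = 2n - 2`, noncentrality `d * sqrt(n / 2)`.
#'
#' @param d Cohen's d (standardized mean difference).
#' @param n per-group sample size.
#' @param alpha two-sided significance level.
#' @return the rejection probability.
#' @export
powerTwoSampleT <- function(d, n, alpha = 0.05) {
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  df <- 2 * n - 2
  tc <- qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n / 2)
  1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
}

#' Minimal detectable effect size
#'
#' Smallest Cohen's d at which a two-sided unpaired two-sample t-test with
#' `n` replicates per group attains the target power at level `alpha`,
#' solved numerically on the noncentral t power function to |delta d| <
#' 1e-6. With the study design this package models (n = 5, alpha = 0.05,
#' power = 0.9) the answer is d = 2.348.
#'
#' @param n per-group sample size (>= 2).
#' @param alpha two-sided significance level.
#' @param power target power, must exceed `alpha` (the power at d = 0).
#' @return Cohen's d.
#' @examples
#' minDetectableEffect(5, 0.05, 0.9) # 2.348
#' @export
minDetectableEffect <- function(n = 5, alpha = 0.05, power = 0.9) {
  stopifnot(n >= 2, alpha > 0, alpha < 1, power > 0, power < 1)
  if (power <= alpha)
    stop("target power must exceed alpha (the power at d = 0)")
  f <- function(d) powerTwoSampleT(d, n, alpha) - power
  uniroot(f, lower = 1e-8, upper = 1e3, tol = 1e-8)$root
}

#' Monte-Carlo power of the two-sample t-test
#'
#' Independent simulation-based estimate of [powerTwoSampleT()]: `reps`
#' pairs of normal samples at standardized separation `d`, pooled-variance
#' t statistic, rejection fraction.
#'
#' @param d,n,alpha as in [powerTwoSampleT()].
#' @param reps number of simulated tests.
#' @param seed RNG seed.
#' @return the empirical rejection fraction.
#' @export
monteCarloPower <- function(d, n = 5, alpha = 0.05, reps = 1e5,
                            seed = 1L) {
  set.seed(as.integer(seed))
  a <- matrix(rnorm(reps * n), reps, n)
  b <- matrix(rnorm(reps * n, mean = d), reps, n)
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (n - 1)
  vb <- rowSums((b - mb)^2) / (n - 1)
  tstat <- (mb - ma) / sqrt((va + vb) / 2) / sqrt(2 / n)
  mean(abs(tstat) > qt(1 - alpha / 2, 2 * n - 2))
}

#' Fold change required to reach an effect size at a given CV
#'
#' Converts Cohen's d on the log-intensity scale to a raw-scale fold change
#' under the log-normal model: `FC = exp(d * sdln)` with
#' `sdln = sqrt(log(1 + cv^2))` (for small cv, `sdln ~ cv`). Strictly
#' increasing in both arguments.
#'
#' @param d Cohen's d (> 0).
#' @param cv within-group coefficient of variation (fraction, > 0).
#' @return raw-scale fold change (> 1).
#' @export
requiredFoldChange <- function(d, cv) {
  stopifnot(all(d > 0), all(cv > 0))
  exp(d * sqrt(log1p(cv^2)))
}

#' @rdname requiredFoldChange
#' @param fc raw-scale fold change (> 1); inverse of
#'   `requiredFoldChange`.
#' @export
effectFromFoldChange <- function(fc, cv) {
  stopifnot(all(fc > 1), all(cv > 0))
  log(fc) / sqrt(log1p(cv^2))
}
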