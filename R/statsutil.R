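#' Recover a standard error from a 95% confidence interval
#'
#' Assumes a symmetric Wald interval, `se = (hi - lo) / (2 * z)` with
#' `z = 1.96` for 95% coverage (configurable).
#'
#' @param ci_low,ci_high Interval endpoints.
#' @param z Normal quantile used to build the interval.
#' @return Standard error on the same scale as the endpoints.
#' @export
ci_to_se <- function(ci_low, ci_high, z = stats::qnorm(0.975)) {
  (ci_high - ci_low) / (2 * z)
}

#' Recover a standard error from an effect and two-sided p-value
#'
#' `se = |effect| / qnorm(1 - p/2)`; useful when published rows report a
#' point estimate and p-value but no usable confidence interval.
#'
#' @param effect Point estimate.
#' @param p Two-sided p-value in (0, 1).
#' @return Standard error.
#' @export
p_to_se <- function(effect, p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)", call. = FALSE)
  abs(effect) / stats::qnorm(1 - p / 2)
}

#' Wald confidence interval and two-sided normal p-value
#' @param effect,se Estimate and standard error.
#' @param level Coverage, default 0.95.
#' @return List with `ci_low`, `ci_high`, `p`.
#' @export
wald_ci_p <- function(effect, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(
    ci_low = effect - z * se, ci_high = effect + z * se,
    p = 2 * stats::pnorm(-abs(effect / se))
  )
}

#' Two-sample t-test from group summary statistics
#'
#' Computes the Student (pooled-variance) or Welch (Satterthwaite) two-sample
#' t-test directly from per-group means, standard deviations, and sizes, as
#' used for comparing densitometric band-intensity measurements between
#' alleles. SDs are treated as sample (n - 1 denominator) standard
#' deviations. With zero pooled variance the test returns `p = 1` when the
#' means are equal (by convention) and errors otherwise (infinite t).
#'
#' @param mean_a,sd_a,n_a Summary of group A.
#' @param mean_b,sd_b,n_b Summary of group B.
#' @param variant `"pooled"` (classic Student, df = n_a + n_b - 2) or
#'   `"welch"`.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
t_test_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (sd_a < 0 || sd_b < 0) stop("SDs must be non-negative", call. = FALSE)
  if (n_a < 2 || n_b < 2) stop("each group needs n >= 2", call. = FALSE)
  va <- sd_a^2; vb <- sd_b^2
  diff <- mean_a - mean_b
  if (variant == "pooled") {
    df <- n_a + n_b - 2
    sp2 <- ((n_a - 1) * va + (n_b - 1) * vb) / df
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  } else {
    se2a <- va / n_a; se2b <- vb / n_b
    se <- sqrt(se2a + se2b)
    df <- if (se == 0) n_a + n_b - 2 else {
      (se2a + se2b)^2 / (se2a^2 / (n_a - 1) + se2b^2 / (n_b - 1))
    }
  }
  if (se == 0) {
    if (diff == 0) return(list(t = 0, df = df, p = 1))
    stop("zero variance with unequal means: t is infinite", call. = FALSE)
  }
  t <- diff / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
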