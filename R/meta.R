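#' Construct a published study row
#'
#' A single study's published per-SNP estimate, as printed: a point estimate
#' (beta on the linear scale or an odds ratio on the ratio scale) with a 95%
#' confidence interval and/or a p-value and sample counts. Used to recompute
#' combined meta-analysis rows from printed per-study cells.
#'
#' @param label Study label.
#' @param effect Point estimate (beta, or OR on the ratio scale).
#' @param ci_low,ci_high Optional 95% CI endpoints on the same scale.
#' @param se Optional standard error (analysis scale).
#' @param p Optional two-sided p-value.
#' @param n Optional sample size (or total of cases + controls).
#' @param scale `"linear"` or `"odds_ratio"`.
#' @return A `study_row` list.
#' @export
study_row <- function(label, effect, ci_low = NA, ci_high = NA,
                      se = NA, p = NA, n = NA,
                      scale = c("linear", "odds_ratio")) {
  scale <- match.arg(scale)
  if (is.na(se) && is.na(ci_low) && is.na(p)) {
    stop("at least one of se, CI, p must be present", call. = FALSE)
  }
  if (scale == "odds_ratio" &&
    (effect <= 0 || (!is.na(ci_low) && ci_low <= 0))) {
    stop("odds-ratio rows must be strictly positive", call. = FALSE)
  }
  structure(
    list(
      label = label, effect = effect, ci_low = ci_low, ci_high = ci_high,
      se = se, p = p, n = n, scale = scale
    ),
    class = "study_row"
  )
}

#' Recover the analysis-scale effect and SE of a published row
#'
#' For linear-scale rows, `se = (ci_high - ci_low) / (2 z)`. For odds-ratio
#' rows the effect is moved to the log scale and
#' `se = (log ci_high - log ci_low) / (2 z)`. When the CI is absent, or the
#' CI midpoint is inconsistent with the printed point estimate beyond
#' `center_tol` times the CI-implied SE (printed rounding occasionally
#' produces such rows), the SE falls back to the p-value route
#' `se = |effect| / qnorm(1 - p/2)`. The source of the SE is recorded.
#'
#' The default `center_tol` of 0.10 is above the midpoint jitter that pure
#' printed rounding can produce (at most ~0.06 SE for two- to three-decimal
#' tables) while catching genuinely asymmetric printed rows.
#'
#' @param row A [study_row()].
#' @param z Normal quantile of the interval (default 1.96 for 95%).
#' @param center_tol Relative tolerance on `|CI midpoint - effect|` in units
#'   of the CI-implied SE before the p fallback triggers.
#' @return List with `effect` (log scale for OR rows), `se`, and
#'   `source` (`"ci"`, `"p"`, or `"se"`).
#' @export
se_from_published <- function(row, z = stats::qnorm(0.975), center_tol = 0.10) {
  stopifnot(inherits(row, "study_row"))
  if (row$scale == "odds_ratio") {
    effect <- log(row$effect)
    lo <- if (is.na(row$ci_low)) NA else log(row$ci_low)
    hi <- if (is.na(row$ci_high)) NA else log(row$ci_high)
  } else {
    effect <- row$effect
    lo <- row$ci_low
    hi <- row$ci_high
  }
  if (!is.na(row$se)) {
    return(list(effect = effect, se = row$se, source = "se"))
  }
  if (!is.na(lo) && !is.na(hi)) {
    se_ci <- (hi - lo) / (2 * z)
    center <- (hi + lo) / 2
    if (abs(center - effect) <= center_tol * se_ci) {
      return(list(effect = effect, se = se_ci, source = "ci"))
    }
  }
  if (!is.na(row$p)) {
    return(list(effect = effect, se = p_to_se(effect, row$p), source = "p"))
  }
  stop(sprintf(
    "row '%s': CI midpoint inconsistent with the point estimate and no p-value to fall back on",
    row$label
  ), call. = FALSE)
}

.as_meta_input <- function(estimates, z = stats::qnorm(0.975)) {
  # accepts a list of study_row / assoc_estimate objects, or a data frame
  # with columns effect and se (+ optional label)
  if (is.data.frame(estimates)) {
    stopifnot(all(c("effect", "se") %in% names(estimates)))
    lab <- if ("label" %in% names(estimates)) estimates$label else
      if ("cohort_id" %in% names(estimates)) estimates$cohort_id else
        sprintf("study_%d", seq_len(nrow(estimates)))
    return(data.frame(
      label = lab, effect = estimates$effect, se = estimates$se,
      stringsAsFactors = FALSE
    ))
  }
  rows <- lapply(estimates, function(e) {
    if (inherits(e, "study_row")) {
      r <- se_from_published(e, z = z)
      data.frame(label = e$label, effect = r$effect, se = r$se,
        stringsAsFactors = FALSE)
    } else if (inherits(e, "assoc_estimate") || is.list(e)) {
      data.frame(
        label = if (!is.null(e$cohort_id)) e$cohort_id else "study",
        effect = e$effect, se = e$se, stringsAsFactors = FALSE
      )
    } else {
      stop("unsupported estimate type for meta-analysis", call. = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Combines per-study estimates with weights `w_i = 1 / se_i^2`:
#' `effect = sum(w_i b_i) / sum(w_i)`, `se = 1 / sqrt(sum(w_i))`, with a
#' two-sided normal p-value. With two or more studies, Cochran's Q, its
#' chi-square p-value, and the I-squared statistic with a test-based
#' confidence interval are attached (see [heterogeneity()]). All inputs must
#' be on a common scale; odds-ratio [study_row()]s are moved to the log
#' scale automatically.
#'
#' @param estimates A list of [study_row()] or `assoc_estimate` objects, or a
#'   data frame with columns `effect` and `se`.
#' @param level Confidence level for the combined interval.
#' @return A `meta_estimate`: list with `effect`, `se`, `ci_low`, `ci_high`,
#'   `p`, `k`, and (for k >= 2) `Q`, `p_het`, `i2`, `i2_ci`; per-study inputs
#'   are kept in `$studies`.
#' @export
ivw_meta <- function(estimates, level = 0.95) {
  dat <- .as_meta_input(estimates)
  if (!is.list(estimates) || is.data.frame(estimates)) {
    scales <- NULL
  } else {
    scales <- unique(vapply(
      Filter(function(e) inherits(e, "study_row"), estimates),
      function(e) e$scale, character(1)
    ))
    if (length(scales) > 1) {
      stop("mixed scales in meta-analysis input", call. = FALSE)
    }
  }
  if (any(!is.finite(dat$se)) || any(dat$se <= 0)) {
    stop("all standard errors must be positive and finite", call. = FALSE)
  }
  k <- nrow(dat)
  w <- 1 / dat$se^2
  effect <- sum(w * dat$effect) / sum(w)
  se <- 1 / sqrt(sum(w))
  wcp <- wald_ci_p(effect, se, level)
  out <- list(
    effect = effect, se = se,
    ci_low = wcp$ci_low, ci_high = wcp$ci_high, p = wcp$p,
    k = k, Q = NA_real_, p_het = NA_real_,
    i2 = NA_real_, i2_ci = c(NA_real_, NA_real_),
    studies = dat
  )
  if (k >= 2) {
    het <- heterogeneity(dat$effect, dat$se, combined = effect)
    out[c("Q", "p_het", "i2", "i2_ci")] <- het[c("Q", "p_het", "i2", "i2_ci")]
  }
  structure(out, class = "meta_estimate")
}

#' @export
print.meta_estimate <- function(x, ...) {
  cat(sprintf(
    "IVW fixed-effects meta-analysis of %d stud%s\n  effect %.4g (95%% CI %.4g to %.4g), p = %.3g\n",
    x$k, if (x$k == 1) "y" else "ies", x$effect, x$ci_low, x$ci_high, x$p
  ))
  if (x$k >= 2) {
    cat(sprintf(
      "  Q = %.3g (p_het = %.3g), I2 = %.1f%% (95%% CI %.1f-%.1f)\n",
      x$Q, x$p_het, x$i2, x$i2_ci[1], x$i2_ci[2]
    ))
  }
  invisible(x)
}

#' Between-study heterogeneity statistics
#'
#' Cochran's `Q = sum(w_i (b_i - b_hat)^2)` with `w_i = 1/se_i^2`, its
#' chi-square p-value on k - 1 degrees of freedom, and
#' `I2 = max(0, (Q - df) / Q) * 100`. The I-squared confidence interval uses
#' the Higgins-Thompson test-based method on the log of
#' `H = sqrt(Q / df)`, truncated to \[0, 100\].
#'
#' @param effects,ses Per-study estimates and standard errors (k >= 2).
#' @param combined Optional pre-computed IVW combined effect; computed if
#'   missing.
#' @param level Confidence level for the I-squared interval.
#' @return List with `Q`, `df`, `p_het`, `i2`, `i2_ci`.
#' @export
heterogeneity <- function(effects, ses, combined = NULL, level = 0.95) {
  k <- length(effects)
  if (k < 2) stop("heterogeneity requires k >= 2 studies", call. = FALSE)
  w <- 1 / ses^2
  if (is.null(combined)) combined <- sum(w * effects) / sum(w)
  Q <- sum(w * (effects - combined)^2)
  df <- k - 1
  p_het <- stats::pchisq(Q, df, lower.tail = FALSE)
  i2 <- max(0, (Q - df) / Q) * 100
  if (!is.finite(i2)) i2 <- 0 # Q == 0 exactly
  # Higgins-Thompson test-based CI for H = sqrt(Q/df) on the log scale
  z <- stats::qnorm(1 - (1 - level) / 2)
  H <- sqrt(max(Q, .Machine$double.eps) / df)
  se_lnH <- if (Q > k) {
    0.5 * (log(Q) - log(df)) / (sqrt(2 * Q) - sqrt(2 * k - 3))
  } else if (k > 2) {
    sqrt(1 / (2 * (k - 2)) * (1 - 1 / (3 * (k - 2)^2)))
  } else {
    NA_real_ # k = 2 with Q <= k: interval is uninformative
  }
  if (is.na(se_lnH)) {
    i2_ci <- c(0, 100)
  } else {
    H_lo <- exp(log(H) - z * se_lnH)
    H_hi <- exp(log(H) + z * se_lnH)
    to_i2 <- function(h) max(0, min(100, (h^2 - 1) / h^2 * 100))
    i2_ci <- c(to_i2(H_lo), to_i2(H_hi))
  }
  list(Q = Q, df = df, p_het = p_het, i2 = i2, i2_ci = i2_ci)
}

#' Genomic control adjustment of a study's summary statistics
#'
#' Estimates the genomic inflation factor as the median association
#' chi-square divided by 0.4549 (the median of a 1-df chi-square), where the
#' chi-square is `(effect / se)^2`. When lambda exceeds 1, every standard
#' error is inflated by `sqrt(lambda)` (equivalently the chi-squares are
#' divided by lambda); lambda below 1 leaves the summary unchanged (no
#' deflation), but is still reported.
#'
#' @param summary_stats Data frame with columns `effect` and `se` over SNPs.
#' @param min_snps Minimum number of SNPs required to estimate the median.
#' @return List with `lambda` and `adjusted` (the summary data frame, with
#'   `se` and `p` updated when lambda > 1).
#' @export
genomic_control <- function(summary_stats, min_snps = 30) {
  stopifnot(all(c("effect", "se") %in% names(summary_stats)))
  n <- nrow(summary_stats)
  if (n < min_snps) {
    stop(sprintf("need >= %d SNPs to estimate lambda (got %d)", min_snps, n),
      call. = FALSE)
  }
  chisq <- (summary_stats$effect / summary_stats$se)^2
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  adjusted <- summary_stats
  if (lambda > 1) {
    adjusted$se <- adjusted$se * sqrt(lambda)
    adjusted$p <- 2 * stats::pnorm(-abs(adjusted$effect / adjusted$se))
  }
  list(lambda = lambda, adjusted = adjusted)
}

#' SNP-level quality-control filter before meta-analysis
#'
#' Drops per-SNP per-cohort records with minor allele frequency below
#' `maf_min`, records whose imputation quality falls below the
#' metric-specific threshold (`r2hat < r2hat_min` or `info < info_min`;
#' records missing the quality metric are dropped conservatively), and SNPs
#' present in fewer than `cohort_fraction` of the contributing cohorts.
#' Boundary values are retained (strict `<` comparisons throughout).
#'
#' @param records Data frame with columns `snp`, `cohort`, `eaf`, `quality`,
#'   `quality_metric` (`"info"` or `"r2hat"`).
#' @param n_cohorts_total Total number of cohorts contributing to the trait.
#' @param maf_min,r2hat_min,info_min,cohort_fraction Thresholds; defaults
#'   0.01, 0.3, 0.4, 0.5.
#' @return List with `kept` (filtered records) and `tally` (named counts of
#'   exclusions per rule: `maf`, `low_quality`, `missing_info`,
#'   `cohort_coverage`).
#' @export
qc_filter <- function(records, n_cohorts_total,
                      maf_min = 0.01, r2hat_min = 0.3, info_min = 0.4,
                      cohort_fraction = 0.5) {
  stopifnot(all(c("snp", "cohort", "eaf", "quality", "quality_metric")
    %in% names(records)))
  maf <- pmin(records$eaf, 1 - records$eaf)
  bad_maf <- maf < maf_min
  thr <- ifelse(records$quality_metric == "r2hat", r2hat_min, info_min)
  missing_q <- is.na(records$quality)
  bad_q <- !missing_q & records$quality < thr
  keep <- !(bad_maf | bad_q | missing_q)
  kept <- records[keep, , drop = FALSE]
  # coverage rule: SNP must appear in >= cohort_fraction of all cohorts
  n_per_snp <- table(kept$snp)
  low_cov <- names(n_per_snp)[n_per_snp / n_cohorts_total < cohort_fraction]
  bad_cov <- kept$snp %in% low_cov
  tally <- c(
    maf = sum(bad_maf),
    low_quality = sum(bad_q & !bad_maf),
    missing_info = sum(missing_q & !bad_maf),
    cohort_coverage = sum(bad_cov)
  )
  list(kept = kept[!bad_cov, , drop = FALSE], tally = tally)
}
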