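#' Assign binary birth-timing trait labels from gestational duration
#'
#' Trait definitions on the day scale: early preterm birth is delivery before
#' gestational week 34+0 (< 238 days); preterm birth before week 37+0
#' (< 259 days, including the early preterm cases); postterm birth at or
#' after week 42+0 (>= 294 days). Controls for all three binary traits are
#' births at or after week 39+0 and before week 42+0 (273 <= days < 294).
#' Anything else is excluded for the binary traits.
#'
#' @param gestational_days Positive numeric vector of gestational days.
#' @return A data frame with factor columns `early_preterm`, `preterm`,
#'   `postterm`, each with levels case/control/excluded.
#' @export
assign_traits <- function(gestational_days) {
  if (any(gestational_days <= 0)) {
    stop("gestational_days must be positive", call. = FALSE)
  }
  d <- gestational_days
  control <- d >= 273 & d < 294
  lab <- function(case) {
    factor(ifelse(case, "case", ifelse(control, "control", "excluded")),
      levels = c("case", "control", "excluded")
    )
  }
  data.frame(
    early_preterm = lab(d < 238),
    preterm = lab(d < 259),
    postterm = lab(d >= 294)
  )
}

#' Remove individuals matching exclusion criteria
#'
#' Drops every individual with any of the requested exclusion flags set
#' (set-union semantics: an individual flagged for several criteria is
#' removed once). A per-criterion removal count is attached as the
#' `"exclusion_report"` attribute; because of the union semantics these
#' counts may sum to more than the number of individuals removed.
#'
#' @param cohort A `duo_cohort`.
#' @param criteria Character vector of flag names to apply; the empty set
#'   leaves the cohort unchanged.
#' @return The filtered `duo_cohort` with an `exclusion_report` attribute
#'   (named integer vector plus a `total_removed` attribute).
#' @export
apply_exclusions <- function(cohort, criteria = character()) {
  stopifnot(inherits(cohort, "duo_cohort"))
  available <- names(cohort$exclusion_flags)
  unknown <- setdiff(criteria, available)
  if (length(unknown) > 0) {
    stop(sprintf(
      "unknown exclusion flag(s): %s; available: %s",
      paste(unknown, collapse = ", "), paste(available, collapse = ", ")
    ), call. = FALSE)
  }
  if (length(criteria) == 0) {
    attr(cohort, "exclusion_report") <- integer(0)
    return(cohort)
  }
  flagged <- as.matrix(cohort$exclusion_flags[, criteria, drop = FALSE])
  report <- colSums(flagged)
  drop <- rowSums(flagged) > 0
  out <- .subset_cohort(cohort, !drop)
  counts <- as.integer(report)
  names(counts) <- criteria
  attr(counts, "total_removed") <- sum(drop)
  attr(out, "exclusion_report") <- counts
  out
}

#' Sex-adjusted rank-based inverse normal transform
#'
#' Regresses gestational duration in days on infant sex (with intercept) and
#' maps the residual ranks through the standard normal quantile function.
#' The default rank offset is the Blom constant, `(r - 3/8) / (n + 1/4)`;
#' `offset = "half"` gives `(r - 1/2) / n`. Ties receive average ranks and
#' therefore map to the same z value. The output is standard-normal by
#' construction (sample mean ~0, variance ~1) and invariant to any strictly
#' monotone re-expression of the residuals.
#'
#' @param gestational_days Numeric vector, complete.
#' @param sex Binary vector (same length); the sex regression is skipped if
#'   sex is constant.
#' @param offset Rank offset rule, `"blom"` (default) or `"half"`.
#' @return Numeric vector of transformed z values.
#' @export
quantile_transform <- function(gestational_days, sex,
                               offset = c("blom", "half")) {
  offset <- match.arg(offset)
  n <- length(gestational_days)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(sex) != n) stop("days and sex must have equal length", call. = FALSE)
  if (anyNA(gestational_days) || anyNA(sex)) {
    stop("day and sex vectors must be complete", call. = FALSE)
  }
  if (stats::sd(gestational_days) == 0) {
    stop("constant gestational_days: ranks undefined", call. = FALSE)
  }
  resid <- if (stats::sd(sex) == 0) {
    gestational_days - mean(gestational_days)
  } else {
    stats::resid(stats::lm(gestational_days ~ sex))
  }
  r <- rank(resid, ties.method = "average")
  p <- switch(offset,
    blom = (r - 3 / 8) / (n + 1 / 4),
    half = (r - 0.5) / n
  )
  unname(stats::qnorm(p))
}

#' Map an ascertained cohort onto a population phenotype scale
#'
#' Case-control studies of preterm birth have bimodal gestational-duration
#' distributions, so the within-cohort inverse normal transform distorts the
#' effect scale relative to population-based cohorts. This maps each day
#' value to the z value that the population reference's empirical day-to-z
#' mapping assigns (linear interpolation between distinct reference day
#' values; clamped at the reference range). The mapping is an empirical
#' quantile anchoring, an approximation suitable for synthetic pipelines.
#'
#' @param cohort A `duo_cohort` (typically ascertained) or a numeric vector
#'   of day values.
#' @param reference A population-based `duo_cohort` with at least 50
#'   individuals.
#' @return Numeric vector of z values on the reference scale.
#' @export
rescale_case_control <- function(cohort, reference) {
  stopifnot(inherits(reference, "duo_cohort"))
  if (n_individuals(reference) < 50) {
    stop("reference must contain at least 50 individuals", call. = FALSE)
  }
  days <- if (inherits(cohort, "duo_cohort")) cohort$gestational_days else cohort
  ref_days <- reference$gestational_days
  ref_z <- quantile_transform(ref_days, reference$sex)
  # average z within distinct day values so the mapping is a function
  map <- tapply(ref_z, ref_days, mean)
  xs <- as.numeric(names(map))
  stats::approx(xs, as.numeric(map), xout = days, rule = 2)$y
}
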