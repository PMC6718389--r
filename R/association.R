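#' @keywords internal
#' @noRd
.assoc_estimate <- function(snp_id, trait, cohort_id, stratum, effect, se,
                            n, n_cases = NA_integer_, n_controls = NA_integer_,
                            eaf = NA_real_, quality = NA_real_,
                            converged = TRUE, skip_reason = NA_character_) {
  p <- if (is.na(se) || se <= 0) NA_real_ else 2 * stats::pnorm(-abs(effect / se))
  structure(
    list(
      snp_id = snp_id, trait = trait, cohort_id = cohort_id,
      stratum = stratum, effect = effect, se = se, p = p,
      eaf = eaf, n = n, n_cases = n_cases, n_controls = n_controls,
      quality = quality, converged = converged, skip_reason = skip_reason
    ),
    class = "assoc_estimate"
  )
}

#' @export
print.assoc_estimate <- function(x, ...) {
  cat(sprintf(
    "assoc: %s [%s] effect %.4g (se %.4g), p = %.3g, n = %d\n",
    x$snp_id, x$trait, x$effect, x$se, x$p, x$n
  ))
  invisible(x)
}

.design_matrix <- function(dosage, covariates) {
  X <- cbind(intercept = 1, dosage = dosage)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- sprintf("cov%d", seq_len(ncol(covariates)))
    }
    X <- cbind(X, covariates)
  }
  X
}

#' Single-SNP linear association test
#'
#' Ordinary least squares of a (typically inverse-normal transformed)
#' phenotype on allelic dosage, an intercept, and optional covariates, under
#' an additive genetic model. Individuals with any missing value are removed
#' listwise. The two-sided p-value uses the Wald normal approximation
#' (`p = 2 (1 - Phi(|effect/se|))`), matching meta-analysis conventions.
#'
#' @param z Numeric phenotype vector.
#' @param dosage Allelic dosage in \[0, 2\]; must be non-constant after
#'   listwise deletion.
#' @param covariates Optional numeric matrix/data frame of covariates.
#' @param snp_id,trait,cohort_id,stratum Metadata carried on the estimate.
#' @return An `assoc_estimate`.
#' @export
linear_assoc <- function(z, dosage, covariates = NULL,
                         snp_id = "snp", trait = "gestational_duration",
                         cohort_id = "cohort", stratum = NA_character_) {
  keep <- stats::complete.cases(z, dosage,
    if (is.null(covariates)) rep(TRUE, length(z)) else covariates)
  z <- z[keep]; dosage <- dosage[keep]
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)[keep, , drop = FALSE]
  }
  n <- length(z)
  X <- .design_matrix(dosage, covariates)
  if (n < ncol(X) + 2) stop("too few observations for the model", call. = FALSE)
  if (stats::var(dosage) == 0) stop("monomorphic SNP", call. = FALSE)
  fit <- stats::lm.fit(X, z)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - ncol(X))
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtX_inv[2, 2])
  .assoc_estimate(
    snp_id = snp_id, trait = trait, cohort_id = cohort_id, stratum = stratum,
    effect = unname(fit$coefficients["dosage"]), se = se,
    n = n, eaf = mean(dosage) / 2
  )
}

#' Single-SNP logistic association test
#'
#' Maximum-likelihood logistic regression of case status on allelic dosage
#' plus optional covariates. The effect is reported as a log odds ratio with
#' its Wald standard error and normal-approximation p-value; the odds ratio
#' itself is `exp(effect)`. Studies contribute a trait only with at least
#' `min_cases` cases; smaller strata are skipped (the returned estimate
#' carries `skip_reason` and no effect). Quasi-separated or non-converged
#' fits are flagged (`converged = FALSE`) rather than silently dropped so
#' that downstream filter counts stay auditable.
#'
#' @param status Binary case indicator (1 = case).
#' @param dosage Allelic dosage.
#' @param covariates Optional covariates.
#' @param min_cases Minimum case count (default 50).
#' @param snp_id,trait,cohort_id,stratum Metadata.
#' @return An `assoc_estimate` on the log-odds scale.
#' @export
logistic_assoc <- function(status, dosage, covariates = NULL, min_cases = 50,
                           snp_id = "snp", trait = "binary_trait",
                           cohort_id = "cohort", stratum = NA_character_) {
  keep <- stats::complete.cases(status, dosage,
    if (is.null(covariates)) rep(TRUE, length(status)) else covariates)
  status <- status[keep]; dosage <- dosage[keep]
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)[keep, , drop = FALSE]
  }
  n_cases <- sum(status == 1)
  n_controls <- sum(status == 0)
  if (n_cases < min_cases) {
    return(.assoc_estimate(
      snp_id, trait, cohort_id, stratum,
      effect = NA_real_, se = NA_real_, n = length(status),
      n_cases = n_cases, n_controls = n_controls,
      eaf = mean(dosage) / 2, converged = FALSE,
      skip_reason = sprintf("fewer than %d cases (%d)", min_cases, n_cases)
    ))
  }
  if (n_controls == 0) stop("both classes must be present", call. = FALSE)
  if (stats::var(dosage) == 0) stop("monomorphic SNP", call. = FALSE)
  X <- if (is.null(covariates)) data.frame(dosage = dosage) else
    data.frame(dosage = dosage, covariates)
  fit <- suppressWarnings(stats::glm(status ~ ., data = X, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  beta <- sm["dosage", "Estimate"]
  se <- sm["dosage", "Std. Error"]
  separated <- !fit$converged || abs(beta) > 10 || se > 50
  .assoc_estimate(
    snp_id, trait, cohort_id, stratum,
    effect = beta, se = se, n = length(status),
    n_cases = n_cases, n_controls = n_controls,
    eaf = mean(dosage) / 2, converged = !separated,
    skip_reason = if (separated) "quasi-separation or non-convergence" else NA_character_
  )
}

#' Stratified association with internal fixed-effects combination
#'
#' Runs the per-stratum association (linear for the transformed quantitative
#' trait, logistic for the binary birth-timing traits) within each disease
#' group of a cohort and combines the stratum estimates by inverse-variance
#' fixed-effects meta-analysis. Strata that cannot be analyzed (too few
#' cases, monomorphic dosage, non-convergence) are dropped with a warning.
#'
#' @param cohort A `duo_cohort`.
#' @param trait `"gestational_duration"` (quantitative) or one of
#'   `"early_preterm"`, `"preterm"`, `"postterm"`.
#' @param snp SNP column name or index (default first SNP).
#' @param covariates Optional covariate matrix aligned with the cohort.
#' @param min_cases Minimum per-stratum case count for binary traits.
#' @return List with `per_stratum` (list of `assoc_estimate`) and `combined`
#'   (an `assoc_estimate`; heterogeneity attached as attribute `"meta"`).
#' @export
stratified_assoc <- function(cohort, trait = "gestational_duration",
                             snp = 1L, covariates = NULL, min_cases = 50) {
  stopifnot(inherits(cohort, "duo_cohort"))
  dosage <- cohort$child_dosage[, snp]
  snp_id <- cohort$snp_meta$snp_id[[if (is.numeric(snp)) snp else match(snp, cohort$snp_meta$snp_id)]]
  strata <- unique(cohort$stratum)
  quantitative <- trait == "gestational_duration"
  if (quantitative) {
    z <- quantile_transform(cohort$gestational_days, cohort$sex)
  } else {
    labels <- assign_traits(cohort$gestational_days)[[trait]]
  }
  per_stratum <- list()
  for (s in strata) {
    idx <- cohort$stratum == s
    est <- tryCatch(
      {
        if (quantitative) {
          linear_assoc(z[idx], dosage[idx],
            covariates = if (is.null(covariates)) NULL else covariates[idx, , drop = FALSE],
            snp_id = snp_id, trait = trait,
            cohort_id = cohort$cohort_id[1], stratum = s
          )
        } else {
          lab <- labels[idx]
          use <- lab != "excluded"
          logistic_assoc(
            as.integer(lab[use] == "case"), dosage[idx][use],
            covariates = if (is.null(covariates)) NULL else covariates[idx, , drop = FALSE][use, , drop = FALSE],
            min_cases = min_cases, snp_id = snp_id, trait = trait,
            cohort_id = cohort$cohort_id[1], stratum = s
          )
        }
      },
      error = function(e) e
    )
    if (inherits(est, "error") || !isTRUE(est$converged) || is.na(est$se)) {
      msg <- if (inherits(est, "error")) conditionMessage(est) else
        if (!is.na(est$skip_reason)) est$skip_reason else "unusable estimate"
      warning(sprintf("stratum '%s' dropped: %s", s, msg), call. = FALSE)
      next
    }
    per_stratum[[s]] <- est
  }
  if (length(per_stratum) == 0) {
    stop("all strata failed; no combinable estimates", call. = FALSE)
  }
  if (length(per_stratum) == 1) {
    combined <- per_stratum[[1]]
    combined$stratum <- "combined"
    return(list(per_stratum = per_stratum, combined = combined))
  }
  meta <- ivw_meta(data.frame(
    label = names(per_stratum),
    effect = vapply(per_stratum, `[[`, numeric(1), "effect"),
    se = vapply(per_stratum, `[[`, numeric(1), "se")
  ))
  combined <- .assoc_estimate(
    snp_id, trait, cohort$cohort_id[1], "combined",
    effect = meta$effect, se = meta$se,
    n = sum(vapply(per_stratum, `[[`, integer(1), "n")),
    n_cases = if (quantitative) NA_integer_ else
      sum(vapply(per_stratum, `[[`, integer(1), "n_cases")),
    n_controls = if (quantitative) NA_integer_ else
      sum(vapply(per_stratum, `[[`, integer(1), "n_controls")),
    eaf = mean(dosage) / 2
  )
  attr(combined, "meta") <- meta
  list(per_stratum = per_stratum, combined = combined)
}

#' Per-allele effect on the raw day scale
#'
#' Regresses untransformed gestational duration in days on allelic dosage,
#' adjusting for infant sex, within each stratum (disease group); stratum
#' estimates are combined by fixed-effects inverse-variance meta-analysis.
#' This yields the clinically interpretable effect in days per effect allele
#' that complements the z-scale GWAS estimates.
#'
#' @param gestational_days,dosage,sex Aligned vectors.
#' @param strata Optional stratum labels; a single stratum if omitted.
#' @param snp_id,cohort_id Metadata.
#' @return An `assoc_estimate` in days/allele (combined across strata).
#' @export
days_scale_effect <- function(gestational_days, dosage, sex, strata = NULL,
                              snp_id = "snp", cohort_id = "cohort") {
  if (is.null(strata)) strata <- rep("all", length(gestational_days))
  ests <- list()
  for (s in unique(strata)) {
    idx <- strata == s
    ests[[s]] <- linear_assoc(gestational_days[idx], dosage[idx],
      covariates = cbind(sex = sex[idx]),
      snp_id = snp_id, trait = "gestational_days", cohort_id = cohort_id,
      stratum = s
    )
  }
  if (length(ests) == 1) {
    out <- ests[[1]]
    out$stratum <- "combined"
    return(out)
  }
  meta <- ivw_meta(data.frame(
    label = names(ests),
    effect = vapply(ests, `[[`, numeric(1), "effect"),
    se = vapply(ests, `[[`, numeric(1), "se")
  ))
  out <- .assoc_estimate(
    snp_id, "gestational_days", cohort_id, "combined",
    effect = meta$effect, se = meta$se,
    n = sum(vapply(ests, `[[`, integer(1), "n")),
    eaf = mean(dosage, na.rm = TRUE) / 2
  )
  attr(out, "meta") <- meta
  out
}

#' Fraction of phenotypic variance explained by a single SNP
#'
#' Incremental R-squared of dosage after the covariates: the difference in
#' R-squared between the model with and without the dosage term. For a
#' standardized phenotype and an additive locus with allele frequency p and
#' per-allele effect b this approaches `2 p (1 - p) b^2`.
#'
#' @param z Phenotype (typically inverse-normal transformed).
#' @param dosage Allelic dosage.
#' @param covariates Optional covariates (e.g. disease-group indicators).
#' @return Fraction in \[0, 1\].
#' @export
variance_explained <- function(z, dosage, covariates = NULL) {
  keep <- stats::complete.cases(z, dosage,
    if (is.null(covariates)) rep(TRUE, length(z)) else covariates)
  z <- z[keep]; dosage <- dosage[keep]
  if (stats::var(dosage) == 0) stop("monomorphic SNP", call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)[keep, , drop = FALSE]
    r2 <- function(X) {
      fit <- stats::lm.fit(cbind(1, X), z)
      1 - sum(fit$residuals^2) / sum((z - mean(z))^2)
    }
    r2(cbind(covariates, dosage)) - r2(covariates)
  } else {
    fit <- stats::lm.fit(cbind(1, dosage), z)
    1 - sum(fit$residuals^2) / sum((z - mean(z))^2)
  }
}
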