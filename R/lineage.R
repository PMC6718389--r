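#' Conditional mother-child (duo) association
#'
#' On complete mother-child pairs only, estimates four quantities for one
#' SNP: the marginal (unadjusted) fetal effect from `z ~ g_child`, the
#' marginal maternal effect from `z ~ g_mother`, and the mutually adjusted
#' fetal and maternal effects as the two coefficients of the joint model
#' `z ~ g_child + g_mother`. Because mother and child share half their
#' genome (dosage correlation one half), the marginal estimates mix both
#' effects; the joint model disentangles them.
#'
#' @param z Phenotype vector (typically the inverse-normal transformed
#'   gestational duration).
#' @param g_child,g_mother Aligned dosage vectors; rows with any missing
#'   value are dropped (complete-pair restriction).
#' @param min_pairs Minimum number of complete pairs (default 30).
#' @param snp_id,cohort_id Metadata.
#' @return A `duo_estimates` list with `assoc_estimate` elements
#'   `fetal_unadj`, `fetal_adj`, `maternal_unadj`, `maternal_adj`, and
#'   `n_pairs`.
#' @export
conditional_duo_assoc <- function(z, g_child, g_mother, min_pairs = 30,
                                  snp_id = "snp", cohort_id = "cohort") {
  keep <- stats::complete.cases(z, g_child, g_mother)
  z <- z[keep]; g_child <- g_child[keep]; g_mother <- g_mother[keep]
  n <- length(z)
  if (n < min_pairs) {
    stop(sprintf("need >= %d complete mother-child pairs (got %d)", min_pairs, n),
      call. = FALSE)
  }
  if (stats::var(g_child) == 0 || stats::var(g_mother) == 0) {
    stop("monomorphic SNP in child or mother dosages", call. = FALSE)
  }
  if (abs(stats::cor(g_child, g_mother)) > 0.99) {
    stop("child and mother dosages are collinear", call. = FALSE)
  }
  mk <- function(effect, se, which) {
    .assoc_estimate(snp_id, "gestational_duration", cohort_id,
      stratum = which, effect = effect, se = se, n = n,
      eaf = mean(g_child) / 2
    )
  }
  marginal <- function(g) {
    est <- linear_assoc(z, g, snp_id = snp_id, cohort_id = cohort_id)
    c(est$effect, est$se)
  }
  fu <- marginal(g_child)
  mu <- marginal(g_mother)
  # joint model: coefficients mutually adjusted
  X <- cbind(1, child = g_child, mother = g_mother)
  fit <- stats::lm.fit(X, z)
  sigma2 <- sum(fit$residuals^2) / (n - 3)
  V <- sigma2 * chol2inv(chol(crossprod(X)))
  structure(
    list(
      fetal_unadj = mk(fu[1], fu[2], "fetal_unadj"),
      fetal_adj = mk(unname(fit$coefficients["child"]), sqrt(V[2, 2]), "fetal_adj"),
      maternal_unadj = mk(mu[1], mu[2], "maternal_unadj"),
      maternal_adj = mk(unname(fit$coefficients["mother"]), sqrt(V[3, 3]), "maternal_adj"),
      n_pairs = n
    ),
    class = "duo_estimates"
  )
}

#' Run the conditional duo association on a simulated cohort
#'
#' Convenience wrapper: transforms the cohort phenotype with
#' [quantile_transform()] and calls [conditional_duo_assoc()] on one SNP.
#'
#' @param cohort A `duo_cohort` with maternal dosages.
#' @param snp SNP column name or index.
#' @param ... Passed to [conditional_duo_assoc()].
#' @return A `duo_estimates`.
#' @export
duo_assoc_cohort <- function(cohort, snp = 1L, ...) {
  stopifnot(inherits(cohort, "duo_cohort"))
  if (is.null(cohort$mother_dosage)) stop("cohort has no maternal dosages", call. = FALSE)
  z <- quantile_transform(cohort$gestational_days, cohort$sex)
  conditional_duo_assoc(z, cohort$child_dosage[, snp], cohort$mother_dosage[, snp],
    snp_id = cohort$snp_meta$snp_id[[if (is.numeric(snp)) snp else match(snp, cohort$snp_meta$snp_id)]],
    cohort_id = cohort$cohort_id[1], ...
  )
}

#' Weighted-linear-model adjustment of marginal fetal and maternal effects
#'
#' Closed-form transformation of marginal (unadjusted) fetal and maternal
#' GWAS estimates into mutually adjusted estimates, exploiting the one-half
#' mother-child genotype correlation:
#' \deqn{\hat\beta_{f,adj} = -\tfrac{2}{3}\hat\beta_{m,unadj} +
#'       \tfrac{4}{3}\hat\beta_{f,unadj}}
#' with standard error
#' \deqn{SE(\hat\beta_{f,adj}) = \sqrt{\tfrac{4}{9}var(\hat\beta_{m,unadj}) +
#'       \tfrac{16}{9}var(\hat\beta_{f,unadj})}}
#' and symmetrically for the maternal side (swap the fetal and maternal
#' roles). Test statistics `Z = beta/SE` are compared to a standard normal
#' distribution for two-sided p-values. This is the duo (no paternal term)
#' version; under noiseless marginal expectations
#' `E[fetal_unadj] = beta_f + beta_m/2` and
#' `E[maternal_unadj] = beta_m + beta_f/2` it inverts the mixing exactly.
#'
#' @param beta_f_unadj,se_f_unadj Marginal fetal estimate and SE.
#' @param beta_m_unadj,se_m_unadj Marginal maternal estimate and SE.
#' @return A `wlm_estimate`: list with `beta_f_adj`, `se_f_adj`, `z_f`,
#'   `p_f`, `ci_f`, and the maternal analogues.
#' @export
wlm_adjust <- function(beta_f_unadj, se_f_unadj, beta_m_unadj, se_m_unadj) {
  if (se_f_unadj <= 0 || se_m_unadj <= 0) {
    stop("standard errors must be positive", call. = FALSE)
  }
  var_f <- se_f_unadj^2
  var_m <- se_m_unadj^2
  beta_f_adj <- -2 / 3 * beta_m_unadj + 4 / 3 * beta_f_unadj
  se_f_adj <- sqrt(4 / 9 * var_m + 16 / 9 * var_f)
  beta_m_adj <- -2 / 3 * beta_f_unadj + 4 / 3 * beta_m_unadj
  se_m_adj <- sqrt(4 / 9 * var_f + 16 / 9 * var_m)
  z_f <- beta_f_adj / se_f_adj
  z_m <- beta_m_adj / se_m_adj
  zq <- stats::qnorm(0.975)
  structure(
    list(
      beta_f_adj = beta_f_adj, se_f_adj = se_f_adj, z_f = z_f,
      p_f = 2 * stats::pnorm(-abs(z_f)),
      ci_f = c(beta_f_adj - zq * se_f_adj, beta_f_adj + zq * se_f_adj),
      beta_m_adj = beta_m_adj, se_m_adj = se_m_adj, z_m = z_m,
      p_m = 2 * stats::pnorm(-abs(z_m)),
      ci_m = c(beta_m_adj - zq * se_m_adj, beta_m_adj + zq * se_m_adj)
    ),
    class = "wlm_estimate"
  )
}

#' @export
print.wlm_estimate <- function(x, ...) {
  cat(sprintf(
    "WLM-adjusted effects\n  fetal:    %.4g (95%% CI %.4g to %.4g), p = %.3g\n  maternal: %.4g (95%% CI %.4g to %.4g), p = %.3g\n",
    x$beta_f_adj, x$ci_f[1], x$ci_f[2], x$p_f,
    x$beta_m_adj, x$ci_m[1], x$ci_m[2], x$p_m
  ))
  invisible(x)
}
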