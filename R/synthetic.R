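#' Simulation configuration for a mother-child duo cohort
#'
#' Bundles the generative quantities for [simulate_duo_cohort()]: sample size,
#' effect-allele frequency, additive fetal and maternal effects on gestational
#' duration (days per effect allele), an infant-sex effect, the day-scale mean
#' and residual SD, the number of additional null SNPs, the ascertainment
#' scheme, disease-group strata weights, and the RNG seed.
#'
#' Defaults emulate the 2q13 regime seen for rs7594852: a fetal effect of
#' 0.37 days per C allele at frequency 0.53, no direct maternal effect, and a
#' day-scale residual SD of 12 days.
#'
#' @param n_duos Number of mother-child pairs.
#' @param eaf Effect-allele frequency, strictly in (0, 1).
#' @param beta_fetal Fetal (child-genotype) effect, days per allele.
#' @param beta_maternal Maternal-genotype effect, days per allele.
#' @param sex_effect Additive effect of male sex on gestational days.
#' @param mean_days Mean gestational duration in days.
#' @param sd_days Residual SD of gestational duration in days; must be > 0.
#' @param n_snps_null Number of additional independent null SNPs.
#' @param ascertainment `"population"` or `"preterm_case_control"`.
#' @param strata_weights Named numeric vector of stratum proportions summing
#'   to 1 (e.g. iPSYCH-style disease groups plus population controls).
#' @param dosage_noise If `TRUE`, blur hard genotypes toward imputed dosages
#'   in \[0, 2\] with beta-distributed noise so imputation-quality filters can
#'   be exercised; default off.
#' @param info Imputation info score recorded in `snp_meta` (and used to set
#'   the blur strength when `dosage_noise = TRUE`).
#' @param case_fraction Target case fraction for the preterm case-control
#'   ascertainment scheme.
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_duos,
                       eaf = 0.53,
                       beta_fetal = 0.37,
                       beta_maternal = 0,
                       sex_effect = -1,
                       mean_days = 280,
                       sd_days = 12,
                       n_snps_null = 0,
                       ascertainment = c("population", "preterm_case_control"),
                       strata_weights = c(pop = 1),
                       dosage_noise = FALSE,
                       info = 1,
                       case_fraction = 0.45,
                       seed = 1L) {
  ascertainment <- match.arg(ascertainment)
  if (!is.numeric(n_duos) || n_duos < 1) {
    stop("'n_duos' must be a positive count", call. = FALSE)
  }
  if (!is.numeric(eaf) || eaf <= 0 || eaf >= 1) {
    stop("'eaf' must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(sd_days) || sd_days <= 0) {
    stop("'sd_days' must be > 0", call. = FALSE)
  }
  if (is.null(names(strata_weights)) || any(!nzchar(names(strata_weights)))) {
    stop("'strata_weights' must be a named vector", call. = FALSE)
  }
  if (abs(sum(strata_weights) - 1) > 1e-8) {
    stop("'strata_weights' must sum to 1", call. = FALSE)
  }
  if (case_fraction <= 0 || case_fraction >= 1) {
    stop("'case_fraction' must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      n_duos = as.integer(n_duos), eaf = eaf,
      beta_fetal = beta_fetal, beta_maternal = beta_maternal,
      sex_effect = sex_effect, mean_days = mean_days, sd_days = sd_days,
      n_snps_null = as.integer(n_snps_null),
      ascertainment = ascertainment, strata_weights = strata_weights,
      dosage_noise = isTRUE(dosage_noise), info = info,
      case_fraction = case_fraction, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# exclusion-flag prevalences used by the generator; names mirror the cohort
# exclusion criteria (stillbirth, multiple birth, ancestry outlier, growth
# outlier, Caesarian for complications, physician-initiated birth, pregnancy
# complication, maternal pre-existing condition, congenital anomaly)
.flag_prevalence <- c(
  stillbirth = 0.003, multiple_birth = 0.02, ancestry_outlier = 0.01,
  growth_outlier = 0.01, csection_complication = 0.03,
  physician_initiated = 0.05, pregnancy_complication = 0.04,
  maternal_condition = 0.03, congenital_anomaly = 0.02
)

# Mendelian transmission: one maternal allele (P(effect allele) = g_m / 2)
# plus one paternal allele drawn from the population at `eaf`
.transmit_child <- function(g_mother, eaf) {
  transmitted <- stats::rbinom(length(g_mother), 1L, g_mother / 2)
  paternal <- stats::rbinom(length(g_mother), 1L, eaf)
  transmitted + paternal
}

.blur_dosage <- function(g, info) {
  # beta-distributed blur toward the genotype; lower info -> wider blur
  conc <- 2 + 48 * info^2
  n <- length(g)
  target <- pmin(pmax(g / 2, 0.02), 0.98)
  stats::rbeta(n, conc * target, conc * (1 - target)) * 2
}

#' Simulate a mother-child duo cohort
#'
#' Draws maternal genotypes under Hardy-Weinberg equilibrium at the configured
#' effect-allele frequency, transmits one maternal allele to the child (with
#' probability `g_mother / 2` of transmitting the effect allele) and adds one
#' paternal allele drawn from the population, then generates gestational
#' duration as
#' `mean_days + beta_fetal * g_child + beta_maternal * g_mother +
#'  sex_effect * sex + N(0, sd_days)`.
#' Null SNPs are independent of the phenotype and of each other (no LD).
#' Exclusion flags are drawn independently at fixed small prevalences so the
#' flag-based filtering stage is exercisable.
#'
#' @param config A [sim_config()] object.
#' @param cohort_id Cohort label stored with every individual.
#' @return A `duo_cohort`: a list with matrices `child_dosage` and
#'   `mother_dosage` (individuals x SNPs), vectors `gestational_days`, `sex`
#'   (1 = male), `stratum`, `cohort_id`, a logical data frame
#'   `exclusion_flags`, and a data frame `snp_meta` (snp_id, effect_allele,
#'   other_allele, eaf, info) aligned with the dosage columns. The first SNP
#'   (`"snp_causal"`) carries the configured effects.
#' @export
simulate_duo_cohort <- function(config, cohort_id = "cohort_1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_duos
  n_snp <- 1L + config$n_snps_null

  g_mother <- matrix(0L, n, n_snp)
  g_child <- matrix(0L, n, n_snp)
  for (j in seq_len(n_snp)) {
    gm <- stats::rbinom(n, 2L, config$eaf)
    g_mother[, j] <- gm
    g_child[, j] <- .transmit_child(gm, config$eaf)
  }

  sex <- stats::rbinom(n, 1L, 0.514)
  days <- config$mean_days +
    config$beta_fetal * g_child[, 1L] +
    config$beta_maternal * g_mother[, 1L] +
    config$sex_effect * sex +
    stats::rnorm(n, 0, config$sd_days)
  days <- pmax(days, 140) # physiological floor; keeps day values positive

  stratum <- sample(names(config$strata_weights), n,
    replace = TRUE, prob = config$strata_weights
  )

  flags <- as.data.frame(lapply(.flag_prevalence, function(p) {
    stats::rbinom(n, 1L, p) == 1L
  }))

  child_dosage <- g_child * 1.0
  mother_dosage <- g_mother * 1.0
  if (config$dosage_noise) {
    child_dosage[] <- .blur_dosage(g_child, config$info)
    mother_dosage[] <- .blur_dosage(g_mother, config$info)
  }
  snp_ids <- c("snp_causal",
    if (config$n_snps_null > 0) sprintf("snp_null_%04d", seq_len(config$n_snps_null)))
  colnames(child_dosage) <- colnames(mother_dosage) <- snp_ids

  cohort <- structure(
    list(
      child_dosage = child_dosage,
      mother_dosage = mother_dosage,
      gestational_days = days,
      sex = sex,
      stratum = stratum,
      cohort_id = rep(cohort_id, n),
      exclusion_flags = flags,
      snp_meta = data.frame(
        snp_id = snp_ids,
        effect_allele = "C", other_allele = "T",
        eaf = config$eaf, info = config$info,
        stringsAsFactors = FALSE
      ),
      ascertainment = "population",
      config = config
    ),
    class = "duo_cohort"
  )
  validate_duo_cohort(cohort)
  cohort
}

#' Validate the internal consistency of a duo cohort
#'
#' Checks dosage bounds, positive day values, and alignment between the SNP
#' metadata and the dosage columns. Called by the generators; exported so
#' readers of externally supplied cohorts can reuse it.
#'
#' @param cohort A `duo_cohort`.
#' @return The cohort, invisibly; errors on violation.
#' @export
validate_duo_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "duo_cohort"))
  d <- cohort$child_dosage
  if (any(d < 0 | d > 2, na.rm = TRUE)) stop("child dosages outside [0, 2]")
  if (!is.null(cohort$mother_dosage) &&
    any(cohort$mother_dosage < 0 | cohort$mother_dosage > 2, na.rm = TRUE)) {
    stop("mother dosages outside [0, 2]")
  }
  if (any(cohort$gestational_days <= 0)) stop("gestational_days must be > 0")
  if (length(cohort$stratum) != nrow(d) || length(cohort$cohort_id) != nrow(d)) {
    stop("every individual needs a stratum and cohort_id")
  }
  if (nrow(cohort$snp_meta) != ncol(d) ||
    !identical(cohort$snp_meta$snp_id, colnames(d))) {
    stop("snp_meta must align one-to-one with dosage columns")
  }
  invisible(cohort)
}

#' @export
print.duo_cohort <- function(x, ...) {
  cat(sprintf(
    "duo_cohort '%s': %d individuals, %d SNP(s), ascertainment = %s\n",
    x$cohort_id[1], length(x$gestational_days), ncol(x$child_dosage),
    x$ascertainment
  ))
  invisible(x)
}

#' Number of individuals in a cohort
#' @param cohort A `duo_cohort`.
#' @return Integer count.
#' @export
n_individuals <- function(cohort) length(cohort$gestational_days)

.subset_cohort <- function(cohort, keep) {
  cohort$child_dosage <- cohort$child_dosage[keep, , drop = FALSE]
  if (!is.null(cohort$mother_dosage)) {
    cohort$mother_dosage <- cohort$mother_dosage[keep, , drop = FALSE]
  }
  cohort$gestational_days <- cohort$gestational_days[keep]
  cohort$sex <- cohort$sex[keep]
  cohort$stratum <- cohort$stratum[keep]
  cohort$cohort_id <- cohort$cohort_id[keep]
  cohort$exclusion_flags <- cohort$exclusion_flags[keep, , drop = FALSE]
  cohort
}

#' Simulate a preterm-enriched case-control cohort
#'
#' Draws a population cohort under `config` and retains every individual born
#' before 259 days (preterm) plus a random subsample of the remaining term
#' births, sized so that preterm cases make up approximately
#' `config$case_fraction` of the cohort. The resulting day distribution is
#' bimodal, emulating preterm case-control study designs.
#'
#' @param config A [sim_config()] with `ascertainment = "preterm_case_control"`.
#' @param cohort_id Cohort label.
#' @return A `duo_cohort` with `ascertainment = "preterm_case_control"`.
#' @export
simulate_case_control_cohort <- function(config, cohort_id = "cc_cohort") {
  stopifnot(inherits(config, "sim_config"))
  if (config$ascertainment != "preterm_case_control") {
    stop("config$ascertainment must be 'preterm_case_control'", call. = FALSE)
  }
  cohort <- simulate_duo_cohort(config, cohort_id = cohort_id)
  is_case <- cohort$gestational_days < 259
  n_case <- sum(is_case)
  if (n_case < 20) {
    stop(sprintf(
      "only %d preterm individuals generated; increase n_duos (need >= 20)",
      n_case
    ), call. = FALSE)
  }
  n_keep_term <- round(n_case * (1 - config$case_fraction) / config$case_fraction)
  term_idx <- which(!is_case)
  if (n_keep_term > length(term_idx)) n_keep_term <- length(term_idx)
  keep <- sort(c(which(is_case), sample(term_idx, n_keep_term)))
  cohort <- .subset_cohort(cohort, keep)
  cohort$ascertainment <- "preterm_case_control"
  validate_duo_cohort(cohort)
  cohort
}

#' Detect bimodality of a day distribution
#'
#' Looks for two kernel-density modes separated by a genuine valley: a
#' second mode counts only if its height exceeds `prominence` times the
#' global mode and the density between the two peaks dips below
#' `valley_ratio` times the smaller peak. Used to flag ascertained
#' (preterm-enriched) cohorts whose gestational-duration distribution is
#' bimodal.
#'
#' @param days Numeric vector of gestational days.
#' @param prominence Minimum relative height for a secondary mode.
#' @param valley_ratio Maximum valley depth (relative to the smaller peak)
#'   separating two modes.
#' @return `TRUE` if a well-separated second mode is found.
#' @export
bimodality_check <- function(days, prominence = 0.1, valley_ratio = 0.8) {
  d <- stats::density(days, n = 512, adjust = 1.5)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  peaks <- peaks[y[peaks] > prominence * max(y)]
  if (length(peaks) < 2) return(FALSE)
  for (i in seq_len(length(peaks) - 1)) {
    for (j in seq(i + 1, length(peaks))) {
      valley <- min(y[peaks[i]:peaks[j]])
      if (valley < valley_ratio * min(y[peaks[i]], y[peaks[j]])) return(TRUE)
    }
  }
  FALSE
}

#' Simulate a multi-study consortium
#'
#' Generates independent cohorts with distinct identifiers; per-cohort seeds
#' are derived deterministically from `master_seed` so that the whole
#' consortium is reproducible while cohorts remain mutually independent.
#'
#' @param configs Named list of [sim_config()] objects; names become cohort
#'   identifiers and must be unique.
#' @param master_seed Integer master seed.
#' @return Named list of `duo_cohort` objects.
#' @export
simulate_consortium <- function(configs, master_seed = 1L) {
  stopifnot(length(configs) >= 1)
  ids <- names(configs)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
    stop("configs must carry unique, non-empty cohort ids as names", call. = FALSE)
  }
  seeds <- derive_seeds(master_seed, length(configs))
  out <- vector("list", length(configs))
  names(out) <- ids
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    cfg$seed <- seeds[i]
    out[[i]] <- if (cfg$ascertainment == "preterm_case_control") {
      simulate_case_control_cohort(cfg, cohort_id = ids[i])
    } else {
      simulate_duo_cohort(cfg, cohort_id = ids[i])
    }
  }
  out
}

#' Derive deterministic stream seeds from a master seed
#'
#' Linear-congruential scrambling keeping every derived seed a positive
#' 32-bit integer; the same master seed always yields the same streams.
#'
#' @param master_seed Integer.
#' @param n Number of seeds to derive.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master_seed, n) {
  m <- 2147483647 # 2^31 - 1
  s <- as.double(master_seed %% m)
  out <- integer(n)
  for (i in seq_len(n)) {
    s <- (s * 48271 + 104729) %% m
    out[i] <- as.integer(max(s, 1))
  }
  out
}
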