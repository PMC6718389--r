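#' Default end-to-end pipeline configuration
#'
#' Assembles a validated configuration for [run_pipeline()]: cohort
#' simulation specs, the trait list, exclusion criteria, SNP-level QC
#' thresholds (MAF 0.01, info 0.4, r2hat 0.3, cohort fraction 0.5, minimum
#' 50 cases per stratum), genomic-control policy, bootstrap and power
#' options, and the master seed from which every stochastic stage derives
#' its stream.
#'
#' @param cohorts Named list of [sim_config()] objects (names are cohort
#'   ids); a small two-cohort default is supplied.
#' @param replication_cohorts Optional named list of configs analyzed as the
#'   replication stage.
#' @param traits Traits to analyze.
#' @param exclusions Exclusion-flag names applied before analysis.
#' @param qc List of QC thresholds.
#' @param gc_policy `"per_study"` (single GC pass) or `"two_stage"` (GC per
#'   stratum summary, then again after the within-study meta, the pattern
#'   used for multi-stratum studies).
#' @param bootstrap List with `B`, `n_bins`.
#' @param power List with `n_sims`, `alpha_discovery`, `alpha_replication`.
#' @param master_seed Integer master seed.
#' @param out_dir Output directory for [run_pipeline()] artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohorts = NULL, replication_cohorts = NULL,
                            traits = c("gestational_duration", "postterm"),
                            exclusions = c("stillbirth", "multiple_birth"),
                            qc = list(maf = 0.01, info = 0.4, r2hat = 0.3,
                              cohort_fraction = 0.5, min_cases = 50),
                            gc_policy = c("per_study", "two_stage"),
                            bootstrap = list(B = 10000, n_bins = 5),
                            power = list(n_sims = 5000,
                              alpha_discovery = 5e-8,
                              alpha_replication = 0.05),
                            master_seed = 1L,
                            out_dir = "pipeline_out") {
  gc_policy <- match.arg(gc_policy)
  if (is.null(cohorts)) {
    cohorts <- list(
      ipsych_like = sim_config(20000, n_snps_null = 49,
        strata_weights = c(
          autism = 0.14, adhd = 0.17, schizophrenia = 0.02,
          bipolar = 0.02, depression = 0.27, anorexia = 0.04, control = 0.34
        )),
      birth_cohort = sim_config(8000, n_snps_null = 49)
    )
  }
  stopifnot(!is.null(names(cohorts)), all(nzchar(names(cohorts))))
  structure(
    list(
      cohorts = cohorts, replication_cohorts = replication_cohorts,
      traits = traits, exclusions = exclusions, qc = qc,
      gc_policy = gc_policy, bootstrap = bootstrap, power = power,
      master_seed = as.integer(master_seed), out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' The configuration round-trips read -> write -> read identically.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns the `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  ser <- unclass(config)
  ser$cohorts <- lapply(ser$cohorts, function(cc) {
    x <- unclass(cc)
    x$strata_weights <- as.list(x$strata_weights)
    x
  })
  if (!is.null(ser$replication_cohorts)) {
    ser$replication_cohorts <- lapply(ser$replication_cohorts, function(cc) {
      x <- unclass(cc)
      x$strata_weights <- as.list(x$strata_weights)
      x
    })
  }
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  revive <- function(x) {
    sim_config(
      n_duos = x$n_duos, eaf = x$eaf, beta_fetal = x$beta_fetal,
      beta_maternal = x$beta_maternal, sex_effect = x$sex_effect,
      mean_days = x$mean_days, sd_days = x$sd_days,
      n_snps_null = x$n_snps_null, ascertainment = x$ascertainment,
      strata_weights = unlist(x$strata_weights),
      dosage_noise = x$dosage_noise, info = x$info,
      case_fraction = x$case_fraction, seed = x$seed
    )
  }
  pipeline_config(
    cohorts = lapply(raw$cohorts, revive),
    replication_cohorts = if (is.null(raw$replication_cohorts)) NULL else
      lapply(raw$replication_cohorts, revive),
    traits = unlist(raw$traits), exclusions = unlist(raw$exclusions),
    qc = raw$qc, gc_policy = raw$gc_policy,
    bootstrap = raw$bootstrap, power = raw$power,
    master_seed = raw$master_seed, out_dir = raw$out_dir
  )
}

.stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

.cohort_trait_stats <- function(cohort, trait, min_cases) {
  # per-SNP stratified association across all SNP columns of a cohort
  ests <- lapply(seq_len(ncol(cohort$child_dosage)), function(j) {
    tryCatch(
      suppressWarnings(stratified_assoc(cohort, trait = trait, snp = j,
        min_cases = min_cases))$combined,
      error = function(e) NULL
    )
  })
  ests <- Filter(Negate(is.null), ests)
  if (length(ests) == 0) return(NULL)
  df <- summary_stats_frame(ests)
  df$INFO <- cohort$snp_meta$info[match(df$SNP, cohort$snp_meta$snp_id)]
  df
}

#' Run the full synthetic GWAS pipeline
#'
#' Executes the study stages end to end on simulated data: cohort
#' simulation, exclusion filtering, trait labeling and phenotype
#' transformation, per-cohort stratified association over all SNPs, genomic
#' control per study, SNP-level QC, discovery meta-analysis (plus
#' replication and combined meta when replication cohorts are configured),
#' duo-based fetal/maternal partitioning with the weighted-linear-model
#' cross-check, the residual-bootstrap test of a duration-dependent effect
#' at the causal SNP, and a power calculation. All tabular artifacts are
#' written under `config$out_dir` together with a manifest recording the
#' package version, a configuration hash, and every derived seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of in-memory results (`cohorts`, `assoc`,
#'   `lambda`, `qc_tally`, `meta`, `duo`, `wlm`, `bootstrap`, `power`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$master_seed, 3 + length(config$cohorts))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  .stage_msg("simulate", "generating %d discovery cohort(s)", length(config$cohorts))
  cohorts <- stage("simulate", simulate_consortium(config$cohorts, config$master_seed))
  repl <- if (!is.null(config$replication_cohorts)) {
    stage("simulate", simulate_consortium(config$replication_cohorts, seeds[1]))
  }

  .stage_msg("exclusions", "applying criteria: %s", paste(config$exclusions, collapse = ", "))
  cohorts <- stage("exclusions", lapply(cohorts, apply_exclusions, criteria = config$exclusions))
  excl_report <- lapply(cohorts, attr, "exclusion_report")

  .stage_msg("association", "stratified per-SNP association, traits: %s",
    paste(config$traits, collapse = ", "))
  assoc <- list()
  lambda <- list()
  for (trait in config$traits) {
    per_cohort <- list()
    for (id in names(cohorts)) {
      df <- stage("association",
        .cohort_trait_stats(cohorts[[id]], trait, config$qc$min_cases))
      if (is.null(df)) next
      if (nrow(df) >= 30) {
        gc_res <- genomic_control(data.frame(effect = df$EFFECT, se = df$SE))
        lambda[[paste(trait, id, sep = ":")]] <- gc_res$lambda
        df$SE <- gc_res$adjusted$se
        df$P <- 2 * stats::pnorm(-abs(df$EFFECT / df$SE))
      }
      per_cohort[[id]] <- df
    }
    assoc[[trait]] <- per_cohort
  }

  .stage_msg("qc", "SNP-level filters (MAF %.2g, info %.2g)", config$qc$maf, config$qc$info)
  qc_tally <- list()
  meta_results <- list()
  for (trait in names(assoc)) {
    per_cohort <- assoc[[trait]]
    if (length(per_cohort) == 0) next
    records <- do.call(rbind, lapply(names(per_cohort), function(id) {
      df <- per_cohort[[id]]
      data.frame(snp = df$SNP, cohort = id, eaf = df$EAF,
        quality = df$INFO, quality_metric = "info",
        effect = df$EFFECT, se = df$SE, stringsAsFactors = FALSE)
    }))
    filt <- qc_filter(records, n_cohorts_total = length(per_cohort),
      maf_min = config$qc$maf, r2hat_min = config$qc$r2hat,
      info_min = config$qc$info, cohort_fraction = config$qc$cohort_fraction)
    qc_tally[[trait]] <- filt$tally
    kept <- filt$kept
    metas <- lapply(split(kept, kept$snp), function(d) {
      ivw_meta(data.frame(label = d$cohort, effect = d$effect, se = d$se))
    })
    meta_results[[trait]] <- data.frame(
      SNP = names(metas),
      EFFECT = vapply(metas, `[[`, numeric(1), "effect"),
      SE = vapply(metas, `[[`, numeric(1), "se"),
      P = vapply(metas, `[[`, numeric(1), "p"),
      K = vapply(metas, `[[`, numeric(1), "k"),
      I2 = vapply(metas, `[[`, numeric(1), "i2"),
      stringsAsFactors = FALSE
    )
    utils::write.table(meta_results[[trait]],
      file.path(config$out_dir, sprintf("meta_%s.tsv", trait)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  .stage_msg("lineage", "duo partitioning on the causal SNP")
  duo_main <- stage("lineage", duo_assoc_cohort(cohorts[[1]], snp = "snp_causal"))
  wlm <- stage("lineage", wlm_adjust(
    duo_main$fetal_unadj$effect, duo_main$fetal_unadj$se,
    duo_main$maternal_unadj$effect, duo_main$maternal_unadj$se
  ))

  .stage_msg("nonlinear", "residual-bootstrap duration-dependence test (B = %d)",
    config$bootstrap$B)
  boot <- stage("nonlinear", bootstrap_nonlinearity_test(
    cohorts[[1]]$gestational_days, cohorts[[1]]$child_dosage[, "snp_causal"],
    B = config$bootstrap$B, n_bins = config$bootstrap$n_bins, seed = seeds[2]
  ))

  .stage_msg("power", "replication power at alpha %.3g", config$power$alpha_replication)
  pow <- stage("power", power_binary(
    n_cases = 670, n_controls = 5626, eaf = 0.55, or = 1.1,
    alpha = config$power$alpha_replication,
    n_sims = config$power$n_sims, seed = seeds[3]
  ))

  manifest <- list(
    package_version = as.character(utils::packageVersion("gestgwas")),
    master_seed = config$master_seed,
    derived_seeds = seeds,
    config_hash = sum(utf8ToInt(paste(
      deparse(unclass(config)[setdiff(names(config), "out_dir")]),
      collapse = ""
    ))),
    cohorts = names(cohorts),
    lambda = lambda,
    exclusion_report = excl_report
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    cohorts = cohorts, replication = repl, assoc = assoc, lambda = lambda,
    qc_tally = qc_tally, meta = meta_results, duo = duo_main, wlm = wlm,
    bootstrap = boot, power = pow, manifest = manifest
  ))
}
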