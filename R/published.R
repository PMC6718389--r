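#' Published per-study estimates for rs7594852
#'
#' Transcribed published per-study association estimates for the 2q13 lead
#' SNP rs7594852 (effect allele C), shipped with the package so that the
#' combined meta-analysis rows, the weighted-linear-model adjustment, and the
#' replication power calculation can be recomputed from printed inputs:
#'
#' * `"gestational_duration"` — per-study betas for quantile-transformed
#'   gestational duration (discovery combined plus the three replication
#'   cohorts), linear scale.
#' * `"postterm"` — discovery combined and replication odds ratios for
#'   postterm birth.
#' * `"duo_pairs"` — the seven mother-child pair studies with fetal and
#'   maternal effects, each unadjusted and adjusted for the other genome
#'   (long format; `estimate` column names the quantity).
#' * `"day_scale"` — the marginal day-scale effects: fetal 0.37 days per C
#'   allele (95% CI 0.22-0.51, from 51,357 infants) and maternal 0.22 days
#'   (95% CI -0.01-0.45, from an independent maternal GWAS of 43,568 women).
#' * `"densitometry"` — HIC1 band-intensity summaries for the two alleles
#'   (mean, SD, n per group).
#'
#' @param which Which table to return.
#' @return A data frame (see above).
#' @export
published_rs7594852 <- function(which = c("gestational_duration", "postterm",
                                          "duo_pairs", "day_scale",
                                          "densitometry")) {
  which <- match.arg(which)
  if (which == "day_scale") {
    return(data.frame(
      genome = c("fetal", "maternal"),
      effect = c(0.37, 0.22),
      ci_low = c(0.22, -0.01),
      ci_high = c(0.51, 0.45),
      n = c(51357, 43568),
      units = "days_per_allele",
      stringsAsFactors = FALSE
    ))
  }
  if (which == "densitometry") {
    return(data.frame(
      allele = c("C", "T"),
      mean = c(204.0, 76.6),
      sd = c(60.0, 42.3),
      n = c(4, 4),
      stringsAsFactors = FALSE
    ))
  }
  file <- switch(which,
    gestational_duration = "rs7594852_gd_studies.csv",
    postterm = "rs7594852_postterm_studies.csv",
    duo_pairs = "rs7594852_duo_pairs.csv"
  )
  path <- system.file("extdata", file, package = "gestgwas", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Study rows for one column of the published duo-pair table
#'
#' Convenience selector turning the long-format duo-pair table into a list
#' of [study_row()] objects for [ivw_meta()].
#'
#' @param estimate One of `"fetal_unadj"`, `"fetal_adj"`,
#'   `"maternal_unadj"`, `"maternal_adj"`.
#' @return List of `study_row` objects (linear scale).
#' @export
duo_pair_rows <- function(estimate = c("fetal_unadj", "fetal_adj",
                                       "maternal_unadj", "maternal_adj")) {
  estimate <- match.arg(estimate)
  tab <- published_rs7594852("duo_pairs")
  tab <- tab[tab$estimate == estimate, , drop = FALSE]
  lapply(seq_len(nrow(tab)), function(i) {
    study_row(
      label = tab$label[i], effect = tab$effect[i],
      ci_low = tab$ci_low[i], ci_high = tab$ci_high[i],
      p = tab$p[i], n = tab$n[i], scale = "linear"
    )
  })
}
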