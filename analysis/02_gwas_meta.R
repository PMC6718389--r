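#!/usr/bin/env Rscript
# Discovery-style GWAS over the simulated consortium: exclusion filtering,
# sex-adjusted inverse normal transform, stratified per-SNP association with
# fixed-effects combination across disease groups, per-study genomic
# control, SNP-level QC, and the discovery meta-analysis.
# Writes results/meta_gestational_duration.tsv and a per-study lambda table.

suppressPackageStartupMessages(library(gestgwas))

cfg <- pipeline_config(
  cohorts = list(
    ipsych_like = sim_config(20000,
      n_snps_null = 49,
      strata_weights = c(
        autism = 0.14, adhd = 0.17, schizophrenia = 0.02, bipolar = 0.02,
        depression = 0.27, anorexia = 0.04, control = 0.34
      )
    ),
    birth_cohort_a = sim_config(6000, n_snps_null = 49),
    birth_cohort_b = sim_config(2100, n_snps_null = 49)
  ),
  traits = "gestational_duration",
  bootstrap = list(B = 2000, n_bins = 5),
  power = list(n_sims = 1000, alpha_discovery = 5e-8, alpha_replication = 0.05),
  master_seed = 20190902,
  out_dir = "results"
)

res <- run_pipeline(cfg)

lam <- data.frame(
  study = names(res$lambda),
  lambda = round(as.numeric(unlist(res$lambda)), 4)
)
write.table(lam, "results/genomic_control_lambda.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)

meta <- res$meta$gestational_duration
causal <- meta[meta$SNP == "snp_causal", ]
cat(sprintf(
  "\nDiscovery meta over %d SNPs, %d cohorts\n", nrow(meta), length(cfg$cohorts)
))
cat(sprintf(
  "causal SNP: beta = %.4f (SE %.4f), P = %.3g, I2 = %.1f%%\n",
  causal$EFFECT, causal$SE, causal$P, causal$I2
))
cat(sprintf(
  "smallest null-SNP P: %.3g (49 null SNPs x 3 cohorts; none should\napproach 5e-8)\n",
  min(meta$P[meta$SNP != "snp_causal"])
))
cat("per-study genomic-control lambdas written to results/genomic_control_lambda.tsv\n")
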