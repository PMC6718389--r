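#!/usr/bin/env Rscript
# Partition fetal from maternal genetic effects two ways and check that
# they agree: (a) conditional mother-child regression in a simulated
# seven-cohort duo consortium matching the published pair counts, combined
# by fixed-effects meta-analysis; (b) the closed-form weighted-linear-model
# (WLM) adjustment applied to the printed marginal day-scale estimates.
# Writes results/duo_partitioning.tsv.

suppressPackageStartupMessages(library(gestgwas))

ns <- c(MoBa_HARVEST = 6362, ALSPAC = 4305, DNBC = 1396, BiB = 1182,
  MoBa_2008 = 854, FIN = 833, EFSOCH = 656)
seeds <- derive_seeds(20190902, length(ns))

ests <- lapply(seq_along(ns), function(i) {
  co <- simulate_duo_cohort(
    sim_config(ns[i], beta_fetal = 0.37, beta_maternal = 0, sd_days = 12,
      seed = seeds[i]),
    cohort_id = names(ns)[i]
  )
  duo_assoc_cohort(co)
})

combine <- function(field) {
  ivw_meta(data.frame(
    label = names(ns),
    effect = vapply(ests, function(e) e[[field]]$effect, numeric(1)),
    se = vapply(ests, function(e) e[[field]]$se, numeric(1))
  ))
}
fields <- c("fetal_unadj", "fetal_adj", "maternal_unadj", "maternal_adj")
comb <- lapply(fields, combine)
names(comb) <- fields

tab <- do.call(rbind, lapply(fields, function(f) {
  m <- comb[[f]]
  data.frame(estimate = f, effect = m$effect, se = m$se,
    ci_low = m$ci_low, ci_high = m$ci_high, p = m$p)
}))
dir.create("results", showWarnings = FALSE)
write.table(format(tab, digits = 4), "results/duo_partitioning.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)

cat("Simulated duo consortium (15,588 pairs, fetal-only truth, z scale):\n")
for (f in fields) {
  m <- comb[[f]]
  cat(sprintf("  %-15s %+0.4f (%+0.4f to %+0.4f), P = %.3g\n",
    f, m$effect, m$ci_low, m$ci_high, m$p))
}
cat("\nThe adjusted fetal effect stays close to its unadjusted value while\n")
cat("the adjusted maternal effect is compatible with zero - the signature\n")
cat("of a fetal-origin association.\n\n")

ds <- published_rs7594852("day_scale")
wlm <- wlm_adjust(
  ds$effect[1], ci_to_se(ds$ci_low[1], ds$ci_high[1]),
  ds$effect[2], ci_to_se(ds$ci_low[2], ds$ci_high[2])
)
cat("WLM on the printed marginal day-scale estimates (0.37 fetal, 0.22 maternal):\n")
print(wlm)
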