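#!/usr/bin/env Rscript
# Does the causal allele act uniformly across the gestational-duration
# distribution? Bin a large simulated cohort into duration quintiles,
# profile the effect-allele frequency per bin, and run the semi-parametric
# residual-bootstrap test, (a) under the uniform-effect truth and (b) under
# an effect confined to the upper 40% of the distribution.
# Writes results/duration_dependence.tsv.

suppressPackageStartupMessages(library(gestgwas))

n <- 51357 # matches the largest contributing study
set.seed(20190902)
g <- rbinom(n, 2, 0.53)

run_case <- function(label, days, B = 10000, seed = 1) {
  res <- bootstrap_nonlinearity_test(days, g, B = B, seed = seed)
  cat(sprintf("\n%s\n", label))
  cat(sprintf("  bin mean days:  %s\n",
    paste(sprintf("%.1f", res$observed$bin_means), collapse = "  ")))
  cat(sprintf("  bin freqs:      %s  (overall %.3f)\n",
    paste(sprintf("%.3f", res$observed$freqs), collapse = "  "),
    res$observed$overall_freq))
  cat(sprintf("  bootstrap p (B = %d): %.4f\n", res$B, res$p))
  data.frame(scenario = label,
    t(setNames(res$observed$freqs, paste0("f", 1:5))),
    overall = res$observed$overall_freq, p = res$p)
}

days_uniform <- 280 + 0.37 * g + rnorm(n, 0, 12)
base <- 280 + rnorm(n, 0, 12)
days_upper <- base + 1.2 * g * (base > quantile(base, 0.6))

tab <- rbind(
  run_case("uniform linear effect (H0 true)", days_uniform, seed = 11),
  run_case("effect confined to the upper 40% of the distribution", days_upper,
    seed = 12)
)
dir.create("results", showWarnings = FALSE)
write.table(format(tab, digits = 4), "results/duration_dependence.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)

cat("\nUnder the upper-tail alternative the bootstrap p collapses to zero\n")
cat("and the frequency profile rises steeply into the top bin. Caution:\n")
cat("the bootstrap p is a directional-octant probability, not a\n")
cat("size-calibrated p-value - it can be small even under the uniform\n")
cat("truth, as the first scenario shows (see the methods vignette).\n")
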