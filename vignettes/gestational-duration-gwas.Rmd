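---
title: "Methods: fetal GWAS of gestational duration on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fetal GWAS of gestational duration on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gestgwas)
```

## Scope and model

`gestgwas` implements the statistical machinery of a fetal genome-wide
association study of gestational duration: the length of pregnancy in days,
analyzed both as a quantitative trait and as the clinical dichotomies early
preterm (< 238 days), preterm (< 259 days), and postterm (>= 294 days)
birth, with term controls defined as births in [273, 294). Because
individual-level consortium data cannot be redistributed, the package pairs
every analysis stage with a synthetic-data generator whose genetic
architecture is known exactly, so that each stage can be validated against
its own simulation truth. Printed per-study summary estimates for the 2q13
lead SNP rs7594852 ship with the package so the aggregate (combined)
quantities can be recomputed from published inputs.

The generative model for a mother–child duo cohort is:

* maternal genotype \(g_m \sim \mathrm{Binomial}(2, p)\) under
  Hardy–Weinberg equilibrium at effect-allele frequency \(p\);
* the child receives one maternal allele (the effect allele with
  probability \(g_m/2\)) and one paternal allele drawn from the population
  at frequency \(p\) — paternal genotypes are marginalized because all
  analyses are duo-based;
* gestational duration
  \(y = \mu + \beta_f g_c + \beta_m g_m + \beta_s\,\mathrm{sex} +
  \varepsilon\), \(\varepsilon \sim N(0, \sigma^2)\).

This transmission scheme makes \(\mathrm{cor}(g_m, g_c) = 1/2\) exactly (a
property the tests check against a brute-force enumeration of the 3×3
mother–child genotype table), which is the structural fact every
fetal-versus-maternal decomposition below exploits.

### Generator defaults

| parameter | default | rationale |
|---|---|---|
| `eaf` | 0.53 | frequency regime of the rs7594852 C allele |
| `beta_fetal` | 0.37 d/allele | the day-scale fetal effect regime at 2q13 |
| `beta_maternal` | 0 | fetal-origin architecture (the 2q13 conclusion) |
| `sex_effect` | −1 d | boys deliver slightly earlier; magnitude is a conventional choice, not a published value |
| `mean_days` | 280 | term gestation |
| `sd_days` | 12 | plausible population SD; a configurable placeholder, not a published value |

Null SNPs are simulated independently (no linkage disequilibrium), there is
no population structure or X chromosome, and imputation is emulated only as
an optional beta-distributed blur of hard genotypes (so the info-score QC
filter has something to act on). Passing tests on these cohorts therefore
demonstrates correctness of the statistical machinery, not robustness to
LD, stratification, or genotyping artifacts that real cohorts carry.

Every stochastic operation takes an explicit seed; `derive_seeds()` expands
a single master seed into deterministic per-stream seeds so consortium
simulations and pipelines are bit-reproducible.

## Phenotype processing

Exclusion criteria (stillbirth, multiple birth, ancestry or growth
outliers, complicated Caesarians, physician-initiated delivery, pregnancy
complications, maternal conditions, congenital anomalies) are carried as
per-individual flags; `apply_exclusions()` removes the union of the
requested flags and reports per-criterion counts, which may sum to more
than the individuals removed when flags overlap.

The quantitative phenotype is processed as in standard GWAS practice:
gestational days are regressed on infant sex and the residuals are mapped
through a rank-based inverse normal transform. The rank offset is the Blom
constant \((r - 3/8)/(n + 1/4)\) (configurable to \((r - 1/2)/n\)); ties
get average ranks and map to the same z value, keeping the transform
deterministic. The result is standard normal by construction, so per-allele
effects on this scale are in phenotypic SD units; `days_scale_effect()`
provides the clinically interpretable days-per-allele companion estimate.

Preterm case–control cohorts have bimodal day distributions, and an
inverse normal transform computed within such a cohort would distort the
effect scale. `rescale_case_control()` maps each day value through the
empirical day-to-z mapping of a population reference cohort (linear
interpolation between distinct reference day values, clamped at the
range). This quantile anchoring is this package's own approximation — the
exact procedure used with the real case-control cohorts is not public —
and it requires a reference of at least 50 individuals.

## Association and meta-analysis

Single-SNP tests are ordinary least squares (quantitative) or
maximum-likelihood logistic regression (binary) on allelic dosage under an
additive model, with Wald normal-approximation p-values; the normal rather
than t reference matches the downstream meta-analysis Z algebra and is
inconsequential at GWAS sample sizes. Disease-group strata are analyzed
separately and combined by fixed-effects inverse-variance weighting.
Binary analyses require 50 cases per stratum; smaller or quasi-separated
strata are flagged and dropped with a warning rather than silently, so
filter tallies remain auditable.

Meta-analysis follows the standard fixed-effects pipeline: per-study
genomic control (\(\lambda = \mathrm{median}(\chi^2)/0.4549\); standard
errors inflated by \(\sqrt\lambda\) only when \(\lambda > 1\) — no
deflation, the dominant GWAS convention, with \(\lambda\) reported either
way), SNP-level QC (MAF < 0.01, info < 0.4 or r2hat < 0.3, presence in
under half the cohorts; strict inequalities, missing quality dropped
conservatively), then inverse-variance weighting with Cochran's Q, its
chi-square p-value, and \(I^2 = \max(0, (Q - df)/Q) \cdot 100\).

The \(I^2\) confidence interval uses the Higgins–Thompson test-based
method on \(\log H\). The method behind the intervals printed alongside
the published per-SNP rows is not identifiable from those rows, and the
test-based intervals here do not reproduce their upper bounds; the point
\(I^2\) and heterogeneity p-values do reproduce.

For literature meta-analysis, `se_from_published()` recovers standard
errors from printed 95% CIs (\(se = \mathrm{width}/3.92\); log scale for
odds ratios). When a printed CI midpoint disagrees with the printed point
estimate by more than 0.10 of the CI-implied SE — a discrepancy that pure
two-decimal rounding cannot produce (its ceiling is about 0.06 SE) — the
SE falls back to the p-value route \(|{\hat\beta}|/\Phi^{-1}(1-p/2)\).
This threshold was chosen because one of the shipped duo-pair rows
exhibits exactly such an inconsistency, and only the p-route SE reproduces
the corresponding printed combined row.

## Fetal versus maternal effects

Two complementary decompositions are implemented.

**Conditional duo regression** fits, on complete mother–child pairs only,
the marginal models \(z \sim g_c\) and \(z \sim g_m\) and the joint model
\(z \sim g_c + g_m\); the joint coefficients are the mutually adjusted
fetal and maternal effects. All four estimates use the identical
complete-pair subset.

**The weighted linear model (WLM)** needs only marginal summary
statistics. Because \(\mathrm{cor}(g_m, g_c) = 1/2\), the marginal
expectations are \(E[\hat\beta_{f,unadj}] = \beta_f + \beta_m/2\) and
\(E[\hat\beta_{m,unadj}] = \beta_m + \beta_f/2\); inverting this mixing
gives
\[
\hat\beta_{f,adj} = -\tfrac{2}{3}\hat\beta_{m,unadj}
                    + \tfrac{4}{3}\hat\beta_{f,unadj},
\qquad
SE = \sqrt{\tfrac{4}{9}\mathrm{var}(\hat\beta_{m,unadj})
           + \tfrac{16}{9}\mathrm{var}(\hat\beta_{f,unadj})},
\]
with the maternal analog obtained by swapping roles, and two-sided normal
p-values from \(Z = \hat\beta/SE\). The SE formula treats the two marginal
estimates as independent, which is exact when they come from
non-overlapping samples (as for the shipped day-scale inputs: a fetal
estimate from one study and a maternal estimate from an independent
maternal GWAS). Property tests verify the algebra to machine precision and
verify against simulated duos that the WLM agrees with the joint
regression within sampling error. Only the duo (no paternal term) version
is implemented. When fed printed two-decimal estimates, reproduction is
exact only up to the ±0.005 input-rounding envelope, and the tests
propagate that envelope explicitly.

## Test of a duration-dependent SNP effect

To ask whether an allele acts uniformly across the duration distribution,
births are binned by gestational duration (default: five equal-count
quantile bins, ties at an edge going to the lower bin; the anchors
available for the original grouping are consistent with quantile-style
binning, but the exact boundaries are not published, so explicit day edges
can be supplied). The effect-allele frequency \(f_b\) is profiled per bin.
The semi-parametric bootstrap then regresses days on dosage (dosage only
by default; a covariate-extended variant is provided as an explicit
extension), resamples the empirical residuals onto the fitted values to
generate data under the uniform-effect null, recomputes \(f_1^*, f_2^*,
f_5^*\) with the observed bin edges held fixed (re-deriving edges per
replicate is available but non-default; the statistic compares frequencies
at fixed cut-points), and reports
\[
p = \frac{1}{B}\sum_{b=1}^{B}
    \mathbf{1}(f_1^{*} > f_1)\,
    \mathbf{1}(f_2^{*} < f_2)\,
    \mathbf{1}(f_5^{*} > f_5),
\]
with strict inequalities and bins 1, 2, 5 only — the directional
alternative that a weak early-pregnancy effect leaves \(f_1\) near the
overall frequency while depressing \(f_2\) and elevating \(f_5\). Default
\(B = 10{,}000\).

**Calibration caveat.** This \(p\) is the bootstrap probability of a
specific joint directional octant, not a size-calibrated p-value. Each
indicator is approximately uniform under the null, so their product
concentrates near 1/8 and falls below 0.05 far more often than 5% of the
time: in simulations at \(n = 1{,}000\)–\(4{,}000\) the null rejection
rate at the 0.05 threshold is roughly 0.23–0.27. The statistic is
faithfully implemented as defined (the vectorized path is tested for exact
equality against a naive per-replicate loop), and it has genuine power —
an effect confined to the upper 40% of the distribution drives the
rejection rate far above the statistic's own null rate — but its numeric
value should be read as a descriptive extremity measure, compared against
the statistic's empirical null behavior rather than against nominal
thresholds.

## Power simulations

`power_quantitative()` draws Binomial(2, p) dosages, a standardized
phenotype \(z = \beta g + N(0,1)\), and counts Wald rejections; it matches
the closed form \(\Phi(|\beta|\sqrt{2p(1-p)n} - z_{\alpha/2})\).
`power_binary()` defaults to retrospective sampling — control genotypes at
Hardy–Weinberg proportions, case genotype probabilities tilted by
\(OR^g\), the exact case distribution under a log-additive logistic model
— because the study designs fix case/control counts without stating a
prevalence. The prospective alternative (solve the logistic intercept for
a target prevalence, sample status prospectively to fixed counts) sits
behind `scheme = "prospective"`; at non-negligible prevalence its controls
are depleted of the risk allele and its power is somewhat higher. Each
replicate's logistic fit runs on the grouped 3-genotype table, which has
the identical likelihood to the individual-level fit at a fraction of the
cost. Defaults: 5,000 simulations, \(\alpha = 5\times10^{-8}\) for
discovery and 0.05 for replication. For the postterm replication scenario
(670 cases, 5,626 controls, EAF 0.55, OR 1.1) the retrospective design
yields about 37–38% power (the closed-form non-centrality gives 37.5%),
modestly below the published headline figure of 40%, which the
retrospective scheme cannot reach at these inputs.

## Numerical and degenerate-input policy

Monomorphic SNPs, constant phenotypes, zero residual variance, collinear
mother–child dosages (correlation above 0.99), non-positive SEs, and
empty or under-occupied bins all raise immediate errors naming the
problem. Logistic non-convergence and quasi-separation are flagged on the
estimate rather than raised, since in a genome scan they must be counted,
not fatal. Missing dosages are handled by listwise deletion per SNP, never
imputed. Strand-ambiguous (A/T, C/G) records that do not match the
reference orientation are dropped during harmonization with a warning.

## Problem sizes used in the test suite

The suites validate parameter recovery on cohorts of 30,000–100,000
individuals (seconds each), null calibration on 300–1,000 replicate fits,
the bootstrap's behavior on 500 replicates of \(n = 1{,}000\) at
\(B = 1{,}000\), and the duo consortium at its true size (15,588 pairs,
repeated over 30 consortium draws). These sizes give Monte-Carlo
resolution comfortably inside every asserted tolerance while keeping the
full suite at a few minutes on one CPU.

## Known limitations

* No LD, relatedness, population structure, or X-chromosome handling — by
  design, out of scope.
* The case-control rescaling is an empirical quantile anchoring, not the
  original (unpublished) procedure.
* The bootstrap duration-dependence p is descriptive, not size-calibrated
  (see above).
* Genome-wide variance-explained and genetic-correlation analyses (LD
  score regression) are out of scope; only the per-SNP WLM transform that
  would feed them is provided.
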