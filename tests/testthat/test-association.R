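test_that("linear association is exact on noiseless data and shift-equivariant", {
  set.seed(1)
  g <- rbinom(200, 2, 0.5)
  est <- linear_assoc(0.5 * g, g)
  expect_equal(est$effect, 0.5, tolerance = 1e-10)
  expect_lt(est$p, 1e-100)
  # adding a constant to the phenotype changes only the intercept
  est2 <- linear_assoc(0.5 * g + 7, g)
  expect_equal(est2$effect, est$effect, tolerance = 1e-10)
  expect_equal(est2$se, est$se, tolerance = 1e-10)
  # Wald identity holds on every emitted estimate
  expect_equal(est2$p, 2 * pnorm(-abs(est2$effect / est2$se)), tolerance = 1e-12)
  expect_error(linear_assoc(rnorm(100), rep(1, 100)), "monomorphic")
  expect_error(linear_assoc(rnorm(3), c(0, 1, 2)), "too few")
})

test_that("linear association p-values are uniform under the null", {
  set.seed(5)
  n <- 400
  g <- rbinom(n, 2, 0.4)
  ps <- replicate(1000, linear_assoc(rnorm(n), g)$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("linear association recovers a GWAS-scale effect of 0.034 on the z scale", {
  set.seed(6)
  n <- 80000
  g <- rbinom(n, 2, 0.53)
  z <- 0.034 * g + rnorm(n)
  est <- linear_assoc(z, g)
  expect_lt(abs(est$effect - 0.034), 3 * est$se)
})

test_that("logistic association recovers a retrospective odds ratio near 1.1", {
  set.seed(7)
  eaf <- 0.55; or <- 1.1
  hw <- dbinom(0:2, 2, eaf)
  p_case <- hw * or^(0:2); p_case <- p_case / sum(p_case)
  g_case <- sample(0:2, 8000, replace = TRUE, prob = p_case)
  g_ctrl <- sample(0:2, 52000, replace = TRUE, prob = hw)
  est <- logistic_assoc(
    rep(1:0, c(8000, 52000)), c(g_case, g_ctrl)
  )
  expect_lt(abs(est$effect - log(1.1)), 3 * est$se)
  expect_true(est$converged)
})

test_that("logistic association flags degenerate designs instead of failing silently", {
  # complete separation
  est <- logistic_assoc(rep(1:0, each = 60), rep(c(2, 0), each = 60))
  expect_false(est$converged)
  expect_match(est$skip_reason, "separation")
  # below the 50-case minimum: skipped with reason, not an error
  est2 <- logistic_assoc(rep(1:0, c(20, 500)), rbinom(520, 2, 0.5))
  expect_false(est2$converged)
  expect_match(est2$skip_reason, "fewer than 50 cases")
  expect_true(is.na(est2$effect))
})

test_that("null logistic p-values are uniform", {
  set.seed(8)
  ps <- replicate(500, {
    g <- rbinom(600, 2, 0.5)
    logistic_assoc(rep(1:0, c(100, 500)), g)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("stratified association combines strata by inverse-variance weighting", {
  co <- simulate_duo_cohort(sim_config(12000,
    beta_fetal = 0.8,
    strata_weights = c(a = 0.3, b = 0.3, c = 0.4), seed = 9
  ))
  res <- stratified_assoc(co, "gestational_duration")
  expect_length(res$per_stratum, 3)
  w <- 1 / vapply(res$per_stratum, `[[`, numeric(1), "se")^2
  b <- vapply(res$per_stratum, `[[`, numeric(1), "effect")
  expect_equal(res$combined$effect, sum(w * b) / sum(w), tolerance = 1e-12)
  expect_equal(res$combined$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  # single stratum: combined equals the stratum estimate
  co1 <- quick_cohort(1000, seed = 10)
  res1 <- stratified_assoc(co1, "gestational_duration")
  expect_equal(res1$combined$effect, res1$per_stratum[[1]]$effect)
  # combined estimate close to the pooled stratum-indicator model
  z <- quantile_transform(co$gestational_days, co$sex)
  pooled <- summary(lm(z ~ co$child_dosage[, 1] + factor(co$stratum)))$coefficients[2, 1]
  expect_lt(abs(res$combined$effect - pooled) / abs(pooled), 0.01)
})

test_that("stratified binary-trait analysis runs logistic models per disease group", {
  co <- simulate_duo_cohort(sim_config(16000,
    beta_fetal = 0, strata_weights = c(a = 0.5, b = 0.5), seed = 19
  ))
  res <- suppressWarnings(stratified_assoc(co, trait = "postterm"))
  expect_gte(length(res$per_stratum), 1)
  comb <- res$combined
  expect_false(is.na(comb$effect))
  # null truth on the log-odds scale
  expect_lt(abs(comb$effect), 3 * comb$se)
  lab <- assign_traits(co$gestational_days)$postterm
  expect_equal(comb$n_cases, sum(lab == "case"))
  expect_equal(comb$n_controls, sum(lab == "control"))
})

test_that("stratified combined estimates recover a common truth across six disease groups", {
  w6 <- c(autism = 0.14, adhd = 0.17, scz = 0.02, bipolar = 0.02,
    depression = 0.27, anorexia = 0.04, control = 0.34)
  co <- simulate_duo_cohort(sim_config(30000,
    beta_fetal = 0.37, strata_weights = w6, seed = 12
  ))
  truth_z <- 0.37 / sd(co$gestational_days) # approximate z-scale truth
  res <- suppressWarnings(stratified_assoc(co, "gestational_duration"))
  expect_lt(abs(res$combined$effect - truth_z), 3 * res$combined$se)
  het <- attr(res$combined, "meta")
  expect_gt(het$p_het, 0.001) # homogeneous truth: no strong heterogeneity signal
})

test_that("day-scale effects recover the configured days-per-allele truth", {
  co <- simulate_duo_cohort(sim_config(50000,
    beta_fetal = 0.37, strata_weights = c(a = 0.5, b = 0.3, c = 0.2), seed = 14
  ))
  est <- days_scale_effect(
    co$gestational_days, co$child_dosage[, 1], co$sex, co$stratum
  )
  expect_lt(abs(est$effect - 0.37), 3 * est$se)
  # null truth is centered at zero
  co0 <- simulate_duo_cohort(sim_config(20000, beta_fetal = 0, seed = 15))
  est0 <- days_scale_effect(co0$gestational_days, co0$child_dosage[, 1], co0$sex)
  expect_lt(abs(est0$effect), 3 * est0$se)
})

test_that("z-scale and day-scale slopes are linked by the phenotype SD", {
  co <- simulate_duo_cohort(sim_config(60000, beta_fetal = 0.37, seed = 16))
  z <- quantile_transform(co$gestational_days, co$sex)
  est_z <- linear_assoc(z, co$child_dosage[, 1])
  est_d <- days_scale_effect(co$gestational_days, co$child_dosage[, 1], co$sex)
  implied <- est_d$effect / sd(co$gestational_days)
  expect_lt(abs(est_z$effect - implied), 3 * sqrt(est_z$se^2 + (est_d$se / sd(co$gestational_days))^2))
})

test_that("variance explained matches the 2p(1-p)b^2 closed form", {
  set.seed(17)
  n <- 200000
  p <- 0.53
  g <- rbinom(n, 2, p)
  # null effect explains nothing
  expect_lt(variance_explained(rnorm(n), g), 1e-4)
  b <- 0.1
  z <- b * g + rnorm(n) * sqrt(1 - 2 * p * (1 - p) * b^2)
  expect_equal(variance_explained(z, g), 2 * p * (1 - p) * b^2, tolerance = 0.15)
  # effect size constructed so the fraction is 0.066%
  b2 <- sqrt(0.00066 / (2 * p * (1 - p)))
  z2 <- b2 * g + rnorm(n) * sqrt(1 - 0.00066)
  expect_equal(variance_explained(z2, g) * 100, 0.066, tolerance = 0.25)
  # incremental definition subtracts the covariate-only fit
  covar <- rnorm(n)
  z3 <- 0.5 * covar + b * g + rnorm(n)
  r2_inc <- variance_explained(z3, g, covariates = cbind(covar))
  expect_lt(abs(r2_inc - 2 * p * (1 - p) * b^2 / (1 + 0.25 + 2 * p * (1 - p) * b^2)), 0.002)
})
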