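test_that("WLM adjustment evaluates its closed forms to machine precision", {
  set.seed(31)
  for (i in 1:25) {
    bf <- rnorm(1); bm <- rnorm(1)
    sf <- runif(1, 0.01, 1); sm <- runif(1, 0.01, 1)
    w <- wlm_adjust(bf, sf, bm, sm)
    expect_identical(w$beta_f_adj, -2 / 3 * bm + 4 / 3 * bf)
    expect_identical(w$se_f_adj, sqrt(4 / 9 * sm^2 + 16 / 9 * sf^2))
    expect_identical(w$beta_m_adj, -2 / 3 * bf + 4 / 3 * bm)
    expect_identical(w$se_m_adj, sqrt(4 / 9 * sf^2 + 16 / 9 * sm^2))
    expect_equal(w$z_f, w$beta_f_adj / w$se_f_adj, tolerance = 1e-15)
    expect_equal(w$p_m, 2 * pnorm(-abs(w$z_m)), tolerance = 1e-15)
  }
  expect_error(wlm_adjust(0.1, 0, 0.1, 0.1), "positive")
})

test_that("WLM inverts the noiseless marginal mixing exactly", {
  # transmission correlation 1/2 implies marginal expectations
  # E[fetal_unadj] = bf + bm/2 and E[maternal_unadj] = bm + bf/2
  for (truth in list(c(0.37, 0), c(0.2, 0.3), c(-0.1, 0.5))) {
    bf <- truth[1]; bm <- truth[2]
    w <- wlm_adjust(bf + bm / 2, 0.01, bm + bf / 2, 0.01)
    expect_equal(w$beta_f_adj, bf, tolerance = 1e-12)
    expect_equal(w$beta_m_adj, bm, tolerance = 1e-12)
  }
  # zero maternal marginal: fetal adjustment is 4/3 of the fetal marginal
  w0 <- wlm_adjust(0.3, 0.05, 0, 0.05)
  expect_equal(w0$beta_f_adj, 4 / 3 * 0.3, tolerance = 1e-14)
})

test_that("conditional duo regression separates fetal from maternal signal", {
  co <- simulate_duo_cohort(sim_config(30000,
    beta_fetal = 0.5, beta_maternal = 0, seed = 33
  ))
  d <- duo_assoc_cohort(co)
  expect_equal(d$n_pairs, 30000)
  truth_z <- 0.5 / sd(co$gestational_days)
  expect_lt(abs(d$fetal_adj$effect - truth_z), 3 * d$fetal_adj$se)
  expect_lt(abs(d$maternal_adj$effect), 3 * d$maternal_adj$se)
  # marginal maternal estimate picks up half the fetal effect
  expect_lt(abs(d$maternal_unadj$effect - truth_z / 2), 3 * d$maternal_unadj$se)
  # conditioning on an independent maternal column leaves the fetal estimate alone
  set.seed(34)
  z <- quantile_transform(co$gestational_days, co$sex)
  g_noise <- rbinom(30000, 2, 0.53)
  d2 <- conditional_duo_assoc(z, co$child_dosage[, 1], g_noise)
  expect_lt(abs(d2$fetal_adj$effect - d2$fetal_unadj$effect), 2 * d2$fetal_adj$se)
})

test_that("duo regression enforces its preconditions", {
  z <- rnorm(20); g <- rbinom(20, 2, 0.5)
  expect_error(conditional_duo_assoc(z, g, g + 0), "complete mother-child pairs")
  z50 <- rnorm(50); g50 <- rbinom(50, 2, 0.5)
  expect_error(conditional_duo_assoc(z50, g50, g50), "collinear")
  expect_error(conditional_duo_assoc(z50, g50, rep(1, 50)), "monomorphic")
})

test_that("WLM on marginal estimates agrees with the joint duo regression", {
  co <- simulate_duo_cohort(sim_config(40000,
    beta_fetal = 0.37, beta_maternal = 0.2, seed = 35
  ))
  d <- duo_assoc_cohort(co)
  w <- wlm_adjust(
    d$fetal_unadj$effect, d$fetal_unadj$se,
    d$maternal_unadj$effect, d$maternal_unadj$se
  )
  expect_lt(abs(w$beta_f_adj - d$fetal_adj$effect),
    3 * sqrt(w$se_f_adj^2 + d$fetal_adj$se^2))
  expect_lt(abs(w$beta_m_adj - d$maternal_adj$effect),
    3 * sqrt(w$se_m_adj^2 + d$maternal_adj$se^2))
})

test_that("maternal-adjusted p-values are uniform when the maternal effect is null", {
  set.seed(36)
  ps <- replicate(300, {
    n <- 1500
    gm <- rbinom(n, 2, 0.5)
    gc <- rbinom(n, 1, gm / 2) + rbinom(n, 1, 0.5)
    z <- 0.1 * gc + rnorm(n)
    conditional_duo_assoc(z, gc, gm)$maternal_adj$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("a seven-cohort duo meta-analysis detects the fetal-origin signal", {
  # per-cohort pair counts mirror the seven duo studies (15,588 pairs total);
  # at a fetal-only effect of 0.37 d (sd 12 d) the design has ~55% power at
  # alpha 0.05, so significance is asserted over repeated consortium draws
  # with a bound set three binomial SDs below that power
  ns <- c(6362, 4305, 1396, 1182, 854, 833, 656)
  run_consortium <- function(master_seed) {
    seeds <- derive_seeds(master_seed, 7)
    ests <- lapply(seq_along(ns), function(i) {
      co <- simulate_duo_cohort(
        sim_config(ns[i], beta_fetal = 0.37, beta_maternal = 0, sd_days = 12,
          seed = seeds[i]),
        cohort_id = sprintf("duo_%d", i)
      )
      duo_assoc_cohort(co)
    })
    comb <- function(field) ivw_meta(data.frame(
      effect = vapply(ests, function(e) e[[field]]$effect, numeric(1)),
      se = vapply(ests, function(e) e[[field]]$se, numeric(1))
    ))
    list(fa = comb("fetal_adj"), ma = comb("maternal_adj"))
  }
  runs <- lapply(1:30, run_consortium)
  truth_z <- 0.37 / 12.1
  # recovery: pooling the consortium replicates pins down the truth
  fa_eff <- vapply(runs, function(r) r$fa$effect, numeric(1))
  fa_se <- vapply(runs, function(r) r$fa$se, numeric(1))
  pooled <- ivw_meta(data.frame(effect = fa_eff, se = fa_se))
  expect_lt(abs(pooled$effect - truth_z), 3 * pooled$se)
  expect_lt(pooled$p, 1e-6)
  # significant positive fetal-adjusted results far above the 5% null rate
  sig <- mean(vapply(runs, function(r) r$fa$p < 0.05 & r$fa$effect > 0, logical(1)))
  expect_gte(sig, 0.3)
  # maternal-adjusted effects stay null
  ma_eff <- vapply(runs, function(r) r$ma$effect, numeric(1))
  ma_se <- vapply(runs, function(r) r$ma$se, numeric(1))
  pooled_ma <- ivw_meta(data.frame(effect = ma_eff, se = ma_se))
  expect_lt(abs(pooled_ma$effect), 3 * pooled_ma$se)
})
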