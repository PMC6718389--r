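test_that("trait labels honor the day-scale boundaries", {
  days <- c(237, 238, 258, 259, 272, 273, 293, 294, 300)
  lab <- assign_traits(days)
  expect_equal(as.character(lab$early_preterm[1]), "case") # < 238
  expect_equal(as.character(lab$preterm[1]), "case")
  expect_equal(as.character(lab$early_preterm[2]), "excluded") # 238: preterm only
  expect_equal(as.character(lab$preterm[2]), "case")
  expect_equal(as.character(lab$preterm[3]), "case") # 258
  # 259 is neither preterm case nor control (outside [273, 294))
  expect_equal(as.character(lab$preterm[4]), "excluded")
  expect_equal(as.character(lab$preterm[5]), "excluded") # 272
  # 273 is control for all three binary traits
  expect_true(all(vapply(lab, function(col) col[6] == "control", logical(1))))
  expect_equal(as.character(lab$postterm[7]), "control") # 293
  expect_equal(as.character(lab$postterm[8]), "case") # 294
  expect_equal(as.character(lab$preterm[8]), "excluded")
  expect_error(assign_traits(c(250, 0)), "positive")
})

test_that("trait statuses partition each cohort, with shared controls", {
  co <- quick_cohort(3000)
  lab <- assign_traits(co$gestational_days)
  for (trait in names(lab)) {
    expect_false(anyNA(lab[[trait]]))
  }
  # controls identical across the three binary traits
  expect_identical(lab$early_preterm == "control", lab$preterm == "control")
  expect_identical(lab$preterm == "control", lab$postterm == "control")
  # early preterm cases are a subset of preterm cases
  expect_true(all(which(lab$early_preterm == "case") %in% which(lab$preterm == "case")))
  # idempotent and order-independent
  expect_identical(lab, assign_traits(co$gestational_days))
  ord <- sample(nrow(lab))
  expect_identical(lab[ord, ], local({
    x <- assign_traits(co$gestational_days[ord]); rownames(x) <- ord; x
  }))
})

test_that("exclusion filtering uses set-union semantics with per-criterion counts", {
  co <- quick_cohort(200, seed = 1)
  # hand-build a 5-row overlap fixture inside the cohort
  co$exclusion_flags[] <- FALSE
  co$exclusion_flags$stillbirth[1:3] <- TRUE
  co$exclusion_flags$multiple_birth[3:5] <- TRUE
  out <- apply_exclusions(co, c("stillbirth", "multiple_birth"))
  rep <- attr(out, "exclusion_report")
  expect_equal(unname(rep["stillbirth"]), 3L)
  expect_equal(unname(rep["multiple_birth"]), 3L)
  # brute-force union on the fixture: rows 1-5 removed once each
  expect_equal(attr(rep, "total_removed"), 5L)
  expect_equal(n_individuals(out), 195L)
  expect_gt(sum(rep), attr(rep, "total_removed"))
  # empty criteria set leaves the cohort unchanged
  same <- apply_exclusions(co, character())
  expect_equal(n_individuals(same), n_individuals(co))
  expect_error(apply_exclusions(co, "no_such_flag"), "available")
})

test_that("exclusion counts match flagged individuals in simulated cohorts", {
  co <- quick_cohort(5000, seed = 8)
  n_twin <- sum(co$exclusion_flags$multiple_birth)
  out <- apply_exclusions(co, "multiple_birth")
  expect_equal(n_individuals(co) - n_individuals(out), n_twin)
  expect_equal(unname(attr(out, "exclusion_report")["multiple_birth"]), n_twin)
})

test_that("inverse normal transform is rank-invariant with the Blom offset", {
  set.seed(2)
  days <- 280 + rnorm(101, sd = 9)
  sex <- rep(0, 101)
  z <- quantile_transform(days, sex)
  expect_equal(mean(z), 0, tolerance = 1e-2)
  expect_equal(var(z), 1, tolerance = 5e-2)
  # any strictly monotone re-expression of the residuals gives identical output
  expect_equal(z, quantile_transform(2 * days - 100, sex))
  expect_equal(z, quantile_transform(days^3, sex))
  # the median residual of an odd, same-sex, tie-free sample maps to 0
  expect_equal(z[which(days == median(days))], 0, tolerance = 1e-12)
  # direct Blom oracle at n = 5
  d5 <- c(270, 275, 280, 290, 295)
  z5 <- quantile_transform(d5, rep(1, 5))
  r <- rank(d5)
  expect_equal(z5, qnorm((r - 3 / 8) / (5 + 1 / 4)), tolerance = 1e-12)
  # alternative offset rule
  expect_equal(
    quantile_transform(d5, rep(1, 5), offset = "half"),
    qnorm((r - 0.5) / 5),
    tolerance = 1e-12
  )
  expect_error(quantile_transform(rep(280, 10), rep(0, 10)), "constant")
  expect_error(quantile_transform(c(1, 2), c(0, 1)), "at least 3")
})

test_that("transform output is normal even for heavy-tailed day distributions", {
  set.seed(4)
  days <- 280 + 5 * rt(1000, df = 2)
  sex <- rbinom(1000, 1, 0.5)
  z <- quantile_transform(days, sex)
  expect_gt(stats::ks.test(z, "pnorm")$p.value, 0.01)
  expect_gt(stats::shapiro.test(z)$p.value, 0.01)
})

test_that("case-control rescaling maps onto the population z scale", {
  ref <- quick_cohort(20000, seed = 21)
  # identity: rescaling the reference onto itself recovers its own transform
  z_self <- rescale_case_control(ref, ref)
  expect_equal(z_self, quantile_transform(ref$gestational_days, ref$sex),
    tolerance = 1e-8
  )
  # a day value at the reference median maps to z near 0
  z_med <- rescale_case_control(median(ref$gestational_days), ref)
  expect_lt(abs(z_med), 0.05)
  expect_error(rescale_case_control(ref, quick_cohort(40)), "at least 50")
})

test_that("rescaled ascertained cohorts recover the population effect size", {
  cfg_cc <- sim_config(40000,
    beta_fetal = 1.5, ascertainment = "preterm_case_control", seed = 31
  )
  cc <- simulate_case_control_cohort(cfg_cc)
  ref <- simulate_duo_cohort(sim_config(40000, beta_fetal = 1.5, seed = 32))
  z_cc <- rescale_case_control(cc, ref)
  est_cc <- linear_assoc(z_cc, cc$child_dosage[, 1])
  z_ref <- quantile_transform(ref$gestational_days, ref$sex)
  est_ref <- linear_assoc(z_ref, ref$child_dosage[, 1])
  expect_lt(
    abs(est_cc$effect - est_ref$effect),
    3 * sqrt(est_cc$se^2 + est_ref$se^2)
  )
})
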