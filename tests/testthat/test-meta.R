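test_that("genomic control estimates lambda near 1 on null summaries and never deflates", {
  set.seed(21)
  null_sum <- data.frame(effect = rnorm(10000, 0, 0.02), se = 0.02)
  gc <- genomic_control(null_sum)
  expect_gt(gc$lambda, 0.95)
  expect_lt(gc$lambda, 1.05)
  # a deflated study is reported but left unchanged
  defl <- data.frame(effect = rnorm(1000, 0, 0.01), se = 0.02)
  gc2 <- genomic_control(defl)
  expect_lt(gc2$lambda, 1)
  expect_identical(gc2$adjusted$se, defl$se)
  expect_error(genomic_control(null_sum[1:10, ]), ">= 30")
})

test_that("an inflated study has all standard errors scaled by sqrt(lambda)", {
  # constant chi-square gives lambda exactly chi2/0.4549...
  lambda_target <- 1.049
  chi <- lambda_target * qchisq(0.5, 1)
  inflated <- data.frame(effect = rep(sqrt(chi) * 0.05, 50), se = 0.05)
  gc <- genomic_control(inflated)
  expect_equal(gc$lambda, lambda_target, tolerance = 1e-12)
  expect_equal(gc$adjusted$se, inflated$se * sqrt(lambda_target), tolerance = 1e-12)
})

test_that("QC filters apply the strict MAF, quality, and coverage thresholds", {
  rec <- data.frame(
    snp = c("s1", "s2", "s3", "s4", "s5", "s6"),
    cohort = "c1",
    eaf = c(0.009, 0.01, 0.5, 0.5, 0.5, 0.995),
    quality = c(0.9, 0.9, 0.40, 0.39, NA, 0.9),
    quality_metric = "info",
    stringsAsFactors = FALSE
  )
  out <- qc_filter(rec, n_cohorts_total = 1)
  expect_setequal(out$kept$snp, c("s2", "s3")) # 0.01 and info 0.40 retained
  expect_equal(unname(out$tally["maf"]), 2L) # eaf 0.009 and 0.995 (MAF 0.005)
  expect_equal(unname(out$tally["low_quality"]), 1L)
  expect_equal(unname(out$tally["missing_info"]), 1L)
  # r2hat records use the 0.3 threshold
  rec2 <- data.frame(
    snp = c("a", "b"), cohort = "c1", eaf = 0.5,
    quality = c(0.3, 0.29), quality_metric = "r2hat",
    stringsAsFactors = FALSE
  )
  expect_identical(qc_filter(rec2, 1)$kept$snp, "a")
  # a SNP in 9 of 20 cohorts is dropped; 10 of 20 is kept
  rec3 <- rbind(
    data.frame(snp = "few", cohort = sprintf("c%d", 1:9), eaf = 0.5,
      quality = 0.9, quality_metric = "info", stringsAsFactors = FALSE),
    data.frame(snp = "enough", cohort = sprintf("c%d", 1:10), eaf = 0.5,
      quality = 0.9, quality_metric = "info", stringsAsFactors = FALSE)
  )
  out3 <- qc_filter(rec3, n_cohorts_total = 20)
  expect_setequal(unique(out3$kept$snp), "enough")
  expect_equal(unname(out3$tally["cohort_coverage"]), 9L)
})

test_that("IVW meta is a weighted mean with the textbook invariances", {
  set.seed(22)
  df <- data.frame(effect = rnorm(6, 0.1, 0.05), se = runif(6, 0.02, 0.2))
  m <- ivw_meta(df)
  # permutation invariance
  m_perm <- ivw_meta(df[sample(6), ])
  expect_equal(m$effect, m_perm$effect, tolerance = 1e-14)
  # single-study identity
  m1 <- ivw_meta(df[3, ])
  expect_equal(m1$effect, df$effect[3])
  expect_equal(m1$se, df$se[3])
  # associativity: meta of metas equals meta of all studies
  ma <- ivw_meta(df[1:3, ])
  mb <- ivw_meta(df[4:6, ])
  m_of_m <- ivw_meta(data.frame(effect = c(ma$effect, mb$effect), se = c(ma$se, mb$se)))
  expect_equal(m_of_m$effect, m$effect, tolerance = 1e-13)
  expect_equal(m_of_m$se, m$se, tolerance = 1e-13)
  # combined SE strictly below the smallest input SE
  expect_lt(m$se, min(df$se))
  # two equal-SE studies combine to the arithmetic mean
  m2 <- ivw_meta(data.frame(effect = c(0.1, 0.3), se = c(0.05, 0.05)))
  expect_equal(m2$effect, 0.2, tolerance = 1e-14)
  expect_error(ivw_meta(data.frame(effect = 1, se = 0)), "positive")
})

test_that("IVW results agree with an independent fixed-effects implementation", {
  skip_if_not_installed("metafor")
  set.seed(23)
  df <- data.frame(effect = rnorm(8, 0.05, 0.1), se = runif(8, 0.01, 0.3))
  m <- ivw_meta(df)
  rma <- metafor::rma(yi = df$effect, sei = df$se, method = "FE")
  expect_equal(m$effect, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(m$se, rma$se, tolerance = 1e-10)
  expect_equal(m$Q, rma$QE, tolerance = 1e-10)
  expect_equal(m$p_het, rma$QEp, tolerance = 1e-10)
  expect_equal(m$i2, max(0, (rma$QE - (8 - 1)) / rma$QE) * 100, tolerance = 1e-10)
})

test_that("heterogeneity statistics match a brute-force loop and handle degeneracy", {
  set.seed(24)
  b <- rnorm(5, 0.2, 0.1)
  s <- runif(5, 0.05, 0.2)
  het <- heterogeneity(b, s)
  w <- 1 / s^2
  bhat <- sum(w * b) / sum(w)
  Q_loop <- 0
  for (i in 1:5) Q_loop <- Q_loop + w[i] * (b[i] - bhat)^2
  expect_equal(het$Q, Q_loop, tolerance = 1e-12)
  # identical estimates: Q = 0, I2 = 0, p_het = 1
  het0 <- heterogeneity(rep(0.1, 4), rep(0.05, 4))
  expect_equal(het0$Q, 0, tolerance = 1e-20)
  expect_equal(het0$i2, 0)
  expect_equal(het0$p_het, 1)
  expect_error(heterogeneity(0.1, 0.05), "k >= 2")
  # I2 CI stays inside [0, 100]
  expect_true(all(het$i2_ci >= 0 & het$i2_ci <= 100))
})

test_that("p_het is uniform on homogeneous inputs and I2 grows with true heterogeneity", {
  set.seed(25)
  ps <- replicate(500, {
    s <- runif(5, 0.05, 0.15)
    b <- rnorm(5, 0.1, s)
    heterogeneity(b, s)$p_het
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  mean_i2 <- vapply(c(0, 0.1, 0.2), function(tau) {
    mean(replicate(300, {
      s <- runif(5, 0.05, 0.15)
      b <- rnorm(5, 0.1, sqrt(s^2 + tau^2))
      heterogeneity(b, s)$i2
    }))
  }, numeric(1))
  expect_true(all(diff(mean_i2) > 0))
})

test_that("published-row SE recovery uses CI when consistent and p otherwise", {
  r1 <- study_row("x", 0.049, 0.016, 0.082, scale = "linear")
  out1 <- se_from_published(r1)
  expect_equal(out1$se, (0.082 - 0.016) / (2 * qnorm(0.975)), tolerance = 1e-10)
  expect_equal(out1$se, 0.01684, tolerance = 1e-3)
  expect_identical(out1$source, "ci")
  # odds-ratio rows are moved to the log scale
  r2 <- study_row("y", 1.05, 0.89, 1.24, scale = "odds_ratio")
  out2 <- se_from_published(r2)
  expect_equal(out2$effect, log(1.05))
  expect_equal(out2$se, (log(1.24) - log(0.89)) / (2 * qnorm(0.975)), tolerance = 1e-10)
  expect_equal(out2$se, 0.0846, tolerance = 1e-3)
  # CI midpoint inconsistent with the printed estimate: p fallback
  r3 <- study_row("z", 0.041, 0.001, 0.076, p = 0.020, scale = "linear")
  out3 <- se_from_published(r3)
  expect_identical(out3$source, "p")
  expect_equal(out3$se, 0.041 / qnorm(1 - 0.020 / 2), tolerance = 1e-10)
  expect_equal(out3$se, 0.0176, tolerance = 1e-2)
  expect_error(study_row("w", 0.1), "at least one")
  expect_error(study_row("neg", -1, scale = "odds_ratio", p = 0.5), "positive")
})

test_that("mixed-scale meta-analysis input is rejected", {
  rows <- list(
    study_row("a", 0.1, 0.0, 0.2, scale = "linear"),
    study_row("b", 1.1, 1.0, 1.2, scale = "odds_ratio")
  )
  expect_error(ivw_meta(rows), "mixed scales")
})
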