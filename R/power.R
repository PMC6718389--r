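#' Simulation-based power for a quantitative single-SNP test
#'
#' Per replicate: dosages are drawn Binomial(2, eaf), the standardized
#' phenotype is `z = beta * g + N(0, 1)`, and the OLS slope is tested with
#' the Wald normal approximation. Power is the fraction of replicates with
#' two-sided p below `alpha`. For a standardized trait the non-centrality is
#' approximately `|beta| * sqrt(2 p (1-p) n)`, giving the closed-form check
#' `Phi(ncp - z_{alpha/2})`.
#'
#' @param n Sample size per replicate.
#' @param eaf Effect-allele frequency.
#' @param beta Per-allele effect on the standardized phenotype.
#' @param alpha Significance threshold (default genome-wide, 5e-8).
#' @param n_sims Number of simulated data sets (default 5000).
#' @param seed RNG seed.
#' @return A `power_result`: list with `power`, `mc_se`
#'   (`sqrt(power (1-power) / n_sims)`), and the spec echo.
#' @export
power_quantitative <- function(n, eaf, beta, alpha = 5e-8,
                               n_sims = 5000, seed = 1L) {
  .check_power_spec(eaf, alpha, n_sims)
  set.seed(seed)
  zcrit <- stats::qnorm(1 - alpha / 2)
  rej <- 0L
  chunk <- max(1L, min(n_sims, floor(5e6 / n)))
  done <- 0L
  while (done < n_sims) {
    b <- min(chunk, n_sims - done)
    g <- matrix(stats::rbinom(n * b, 2L, eaf), n, b)
    z <- beta * g + matrix(stats::rnorm(n * b), n, b)
    sg <- colSums(g); sz <- colSums(z)
    sgg <- colSums(g * g); sgz <- colSums(g * z); szz <- colSums(z * z)
    sxx <- sgg - sg^2 / n
    sxy <- sgz - sg * sz / n
    syy <- szz - sz^2 / n
    slope <- sxy / sxx
    rss <- syy - slope * sxy
    se <- sqrt(rss / (n - 2) / sxx)
    rej <- rej + sum(abs(slope / se) > zcrit)
    done <- done + b
  }
  .power_result(rej / n_sims, n_sims,
    spec = list(trait_type = "quantitative", n = n, eaf = eaf, beta = beta,
      alpha = alpha, n_sims = n_sims, seed = seed))
}

#' Simulation-based power for a case-control single-SNP test
#'
#' Default generative scheme is retrospective: control genotypes are drawn
#' from Hardy-Weinberg proportions at `eaf`, case genotype probabilities are
#' the Hardy-Weinberg proportions tilted by `OR^g` (the exact case genotype
#' distribution under a log-additive logistic model in the rare-disease
#' retrospective design). Each replicate fits a logistic regression of case
#' status on dosage (on the grouped 3-genotype table, which is the identical
#' likelihood) and applies the Wald test. The prospective alternative
#' (`scheme = "prospective"`) solves the logistic intercept for a target
#' population `prevalence`, simulates status prospectively, and samples to
#' the fixed case/control counts; at non-negligible prevalence the controls
#' are depleted of the risk allele and power is slightly higher.
#'
#' @param n_cases,n_controls Fixed per-replicate counts.
#' @param eaf Effect-allele frequency (controls / population).
#' @param or Per-allele odds ratio (> 0).
#' @param alpha Significance threshold (default replication-stage, 0.05).
#' @param n_sims Number of simulated data sets (default 5000).
#' @param seed RNG seed.
#' @param scheme `"retrospective"` (default) or `"prospective"`.
#' @param prevalence Population prevalence for the prospective scheme.
#' @return A `power_result` (see [power_quantitative()]).
#' @export
power_binary <- function(n_cases, n_controls, eaf, or, alpha = 0.05,
                         n_sims = 5000, seed = 1L,
                         scheme = c("retrospective", "prospective"),
                         prevalence = 0.1) {
  scheme <- match.arg(scheme)
  .check_power_spec(eaf, alpha, n_sims)
  if (or <= 0) stop("odds ratio must be positive", call. = FALSE)
  g <- 0:2
  hw <- stats::dbinom(g, 2L, eaf)
  p_case <- hw * or^g
  p_case <- p_case / sum(p_case)
  if (any(p_case <= 0) || any(p_case >= 1)) {
    stop("degenerate implied genotype frequencies", call. = FALSE)
  }
  if (scheme == "prospective") {
    # intercept such that marginal P(case) = prevalence
    f <- function(a) sum(hw * stats::plogis(a + log(or) * g)) - prevalence
    a0 <- stats::uniroot(f, c(-30, 30))$root
    p_case_given_g <- stats::plogis(a0 + log(or) * g)
    p_case <- hw * p_case_given_g / sum(hw * p_case_given_g)
    p_ctrl <- hw * (1 - p_case_given_g) / sum(hw * (1 - p_case_given_g))
  } else {
    p_ctrl <- hw
  }
  set.seed(seed)
  rej <- vapply(seq_len(n_sims), function(i) {
    cca <- stats::rmultinom(1, n_cases, p_case)[, 1]
    cco <- stats::rmultinom(1, n_controls, p_ctrl)[, 1]
    .grouped_logistic_p(cca, cco) < alpha
  }, logical(1))
  .power_result(mean(rej), n_sims,
    spec = list(trait_type = "binary", n_cases = n_cases,
      n_controls = n_controls, eaf = eaf, or = or, alpha = alpha,
      n_sims = n_sims, seed = seed, scheme = scheme))
}

# Wald p for logistic regression of status on genotype, fit on the grouped
# 3-genotype x 2-status table (identical likelihood to the individual fit)
.grouped_logistic_p <- function(case_counts, control_counts) {
  w <- c(case_counts, control_counts)
  keep <- w > 0
  df <- data.frame(g = rep(0:2, 2), y = rep(c(1L, 0L), each = 3), w = w)[keep, ]
  fit <- suppressWarnings(
    stats::glm(y ~ g, family = stats::binomial(), weights = w, data = df)
  )
  sm <- summary(fit)$coefficients
  if (!"g" %in% rownames(sm)) return(1)
  sm["g", "Pr(>|z|)"]
}

.check_power_spec <- function(eaf, alpha, n_sims) {
  if (eaf <= 0 || eaf >= 1) stop("eaf must lie in (0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (n_sims < 100) stop("n_sims must be at least 100", call. = FALSE)
}

.power_result <- function(power, n_sims, spec) {
  structure(
    list(
      power = power,
      mc_se = sqrt(power * (1 - power) / n_sims),
      spec = spec
    ),
    class = "power_result"
  )
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "power = %.1f%% (MC SE %.2f pp) over %d simulations\n",
    100 * x$power, 100 * x$mc_se, x$spec$n_sims
  ))
  invisible(x)
}

#' Power over a grid of effect sizes and allele frequencies
#'
#' Evaluates [power_quantitative()] or [power_binary()] on the Cartesian
#' grid of effects and frequencies and returns a long-format table.
#'
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param effects Vector of betas (quantitative) or odds ratios (binary).
#' @param eafs Vector of effect-allele frequencies.
#' @param ... Remaining arguments passed to the underlying power function
#'   (sample sizes, `alpha`, `n_sims`, `seed`).
#' @return Data frame with columns `effect`, `eaf`, `power`, `mc_se`.
#' @export
power_grid <- function(trait_type = c("quantitative", "binary"),
                       effects, eafs, ...) {
  trait_type <- match.arg(trait_type)
  grid <- expand.grid(effect = effects, eaf = eafs)
  res <- mapply(function(eff, p) {
    r <- if (trait_type == "quantitative") {
      power_quantitative(eaf = p, beta = eff, ...)
    } else {
      power_binary(eaf = p, or = eff, ...)
    }
    c(r$power, r$mc_se)
  }, grid$effect, grid$eaf)
  grid$power <- res[1, ]
  grid$mc_se <- res[2, ]
  grid
}
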