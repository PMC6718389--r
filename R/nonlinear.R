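#' Allele frequencies within gestational-duration bins
#'
#' Partitions births into bins by gestational duration (default: five
#' equal-count quantile bins) and computes the effect-allele frequency as
#' `mean(dosage) / 2` within each bin and in the whole sample. Ties at bin
#' edges are assigned to the lower bin, deterministically.
#'
#' @param gestational_days,dosage Aligned vectors.
#' @param n_bins Number of equal-count bins (default 5); ignored when
#'   `edges` is supplied.
#' @param edges Optional explicit interior day cut-points (increasing); an
#'   observation equal to an edge falls in the lower bin.
#' @param min_bin Minimum occupancy per bin.
#' @return A `bin_profile`: list with `bin_edges` (interior cut-points),
#'   `bin_means` (mean days per bin), `freqs`, `overall_freq`, `bin_counts`,
#'   and the per-observation `bin` assignment.
#' @export
bin_allele_freq <- function(gestational_days, dosage, n_bins = 5,
                            edges = NULL, min_bin = 20) {
  n <- length(gestational_days)
  if (length(dosage) != n) stop("days and dosage must align", call. = FALSE)
  if (is.null(edges)) {
    probs <- seq_len(n_bins - 1) / n_bins
    edges <- unname(stats::quantile(gestational_days, probs, type = 1))
    if (anyDuplicated(edges)) {
      stop("degenerate quantile edges (heavy ties); supply explicit edges",
        call. = FALSE)
    }
  }
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("edges must be strictly increasing", call. = FALSE)
  }
  bin <- .assign_bins(gestational_days, edges)
  k <- length(edges) + 1L
  counts <- tabulate(bin, nbins = k)
  if (any(counts == 0)) {
    stop("empty bin; choose different edges", call. = FALSE)
  }
  if (any(counts < min_bin)) {
    stop(sprintf("bin occupancy below %d; need more data or wider bins", min_bin),
      call. = FALSE)
  }
  freqs <- vapply(seq_len(k), function(b) mean(dosage[bin == b]) / 2, numeric(1))
  structure(
    list(
      bin_edges = edges,
      bin_means = vapply(seq_len(k), function(b) mean(gestational_days[bin == b]), numeric(1)),
      freqs = freqs,
      overall_freq = mean(dosage) / 2,
      bin_counts = counts,
      bin = bin
    ),
    class = "bin_profile"
  )
}

# ties at an edge go to the lower bin: bin = 1 + #{edges < x}
.assign_bins <- function(x, edges) {
  findInterval(x, edges, left.open = TRUE) + 1L
}

#' Semi-parametric bootstrap test for a duration-dependent SNP effect
#'
#' Tests the null hypothesis that a variant contributes equally to longer
#' gestational duration regardless of when the child is born, against the
#' alternative that its effect is concentrated in part of the distribution.
#' The procedure: (i) regress gestational days on dosage (OLS, dosage only by
#' default); (ii) in each bootstrap replicate, form
#' `days* = fitted + residuals resampled with replacement` (the
#' semi-parametric null: a uniform linear effect plus exchangeable noise);
#' (iii) recompute the allele frequencies in bins 1, 2, and 5 using the
#' observed bin edges held fixed; (iv) score the replicate as extreme when
#' `f1* > f1` and `f2* < f2` and `f5* > f5` (strict inequalities); (v) the
#' p-value is the proportion of extreme replicates.
#'
#' @param gestational_days,dosage Aligned vectors.
#' @param B Number of bootstrap replicates (>= 100; 10,000 by default).
#' @param n_bins,edges,min_bin Passed to [bin_allele_freq()].
#' @param seed RNG seed.
#' @param refit_bins If `TRUE`, re-derive quantile bin edges within each
#'   replicate instead of freezing the observed edges (non-default variant).
#' @param covariates Optional covariates added to the step (i) regression;
#'   an extension beyond the dosage-only default.
#' @return A `boot_result`: list with `observed` ([bin_allele_freq()]
#'   profile), `B`, `p`, `exceed_counts` (per-indicator tallies), `seed`.
#' @export
bootstrap_nonlinearity_test <- function(gestational_days, dosage, B = 10000,
                                        n_bins = 5, edges = NULL, min_bin = 20,
                                        seed = 1L, refit_bins = FALSE,
                                        covariates = NULL) {
  if (B < 100) stop("B must be at least 100", call. = FALSE)
  obs <- bin_allele_freq(gestational_days, dosage,
    n_bins = n_bins, edges = edges, min_bin = min_bin)
  n <- length(gestational_days)
  X <- .design_matrix(dosage, covariates)
  fit <- stats::lm.fit(X, gestational_days)
  res <- fit$residuals
  if (stats::var(res) == 0) {
    stop("zero residual variance; bootstrap undefined", call. = FALSE)
  }
  fitted <- fit$fitted.values
  set.seed(seed)
  f1 <- obs$freqs[1]; f2 <- obs$freqs[2]; f5 <- obs$freqs[n_bins]
  count1 <- count2 <- count5 <- 0L
  extreme <- 0L
  chunk <- max(1L, min(B, floor(5e6 / n)))
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    idx <- sample.int(n, n * b, replace = TRUE)
    days_star <- matrix(fitted + res[idx], n, b)
    if (refit_bins) {
      probs <- seq_len(n_bins - 1) / n_bins
      stats_b <- vapply(seq_len(b), function(j) {
        e <- unname(stats::quantile(days_star[, j], probs, type = 1))
        bn <- .assign_bins(days_star[, j], e)
        c(
          mean(dosage[bn == 1L]) / 2,
          mean(dosage[bn == 2L]) / 2,
          mean(dosage[bn == n_bins]) / 2
        )
      }, numeric(3))
      f1s <- stats_b[1, ]; f2s <- stats_b[2, ]; f5s <- stats_b[3, ]
    } else {
      binmat <- matrix(.assign_bins(days_star, obs$bin_edges), n, b)
      freq_in <- function(target) {
        m <- binmat == target
        colSums(dosage * m) / (2 * colSums(m))
      }
      f1s <- freq_in(1L); f2s <- freq_in(2L); f5s <- freq_in(n_bins)
    }
    i1 <- f1s > f1; i2 <- f2s < f2; i5 <- f5s > f5
    count1 <- count1 + sum(i1, na.rm = TRUE)
    count2 <- count2 + sum(i2, na.rm = TRUE)
    count5 <- count5 + sum(i5, na.rm = TRUE)
    extreme <- extreme + sum(i1 & i2 & i5, na.rm = TRUE)
    done <- done + b
  }
  structure(
    list(
      observed = obs, B = B, p = extreme / B,
      exceed_counts = c(f1_above = count1, f2_below = count2, f5_above = count5),
      seed = seed
    ),
    class = "boot_result"
  )
}

#' @export
print.boot_result <- function(x, ...) {
  cat(sprintf(
    "residual-bootstrap test of duration-dependent SNP effect\n  bin frequencies: %s (overall %.4f)\n  B = %d, p = %.4g\n",
    paste(sprintf("%.4f", x$observed$freqs), collapse = " "),
    x$observed$overall_freq, x$B, x$p
  ))
  invisible(x)
}
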