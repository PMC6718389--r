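# shared fixtures and independent oracles

# exact joint distribution of (mother, child) genotypes under Hardy-Weinberg
# parents and Mendelian transmission of one maternal allele plus one
# population paternal allele: brute-force enumeration over the 3x3 table
mendelian_joint_table <- function(eaf) {
  p_m <- stats::dbinom(0:2, 2, eaf)
  joint <- matrix(0, 3, 3, dimnames = list(mother = 0:2, child = 0:2))
  for (gm in 0:2) {
    p_transmit <- gm / 2
    for (t in 0:1) {
      pt <- if (t == 1) p_transmit else 1 - p_transmit
      if (pt == 0) next
      for (pat in 0:1) {
        pp <- if (pat == 1) eaf else 1 - eaf
        gc <- t + pat
        joint[gm + 1, gc + 1] <- joint[gm + 1, gc + 1] + p_m[gm + 1] * pt * pp
      }
    }
  }
  joint
}

# correlation implied by an exact joint genotype table
joint_table_cor <- function(joint) {
  g <- 0:2
  pm <- rowSums(joint)
  pc <- colSums(joint)
  em <- sum(g * pm); ec <- sum(g * pc)
  vm <- sum(g^2 * pm) - em^2
  vc <- sum(g^2 * pc) - ec^2
  egmgc <- sum(outer(g, g) * joint)
  (egmgc - em * ec) / sqrt(vm * vc)
}

# small population cohort reused across tests
quick_cohort <- function(n = 2000, seed = 42, ...) {
  simulate_duo_cohort(sim_config(n, seed = seed, ...))
}

# values with exactly the requested sample mean and sd (n = 4)
moment_matched_sample <- function(m, s, n = 4) {
  v <- seq_len(n) - (n + 1) / 2
  m + s * v / stats::sd(v)
}
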