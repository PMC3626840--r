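# Independent oracles used across the suite.  They deliberately avoid the
# package's own conditional-table formulas: everything is built from first
# principles by enumerating ordered haplotype pairs.

# Joint distribution Pr(disease genotype i, marker genotype j) from random
# union of haplotypes (rows AA, Aa, aa; columns MM, Mm, mm).
enum_joint <- function(p, q, D) {
  hap <- c(MA = p * q + D, Ma = p * (1 - q) - D,
           mA = (1 - p) * q - D, ma = (1 - p) * (1 - q) + D)
  nM <- c(MA = 1, Ma = 1, mA = 0, ma = 0)
  nA <- c(MA = 1, Ma = 0, mA = 1, ma = 0)
  joint <- matrix(0, 3, 3,
                  dimnames = list(c("AA", "Aa", "aa"), c("MM", "Mm", "mm")))
  for (h1 in 1:4) for (h2 in 1:4) {
    i <- 3L - (nA[h1] + nA[h2])       # 2 copies of A -> row 1
    j <- 3L - (nM[h1] + nM[h2])
    joint[i, j] <- joint[i, j] + hap[h1] * hap[h2]
  }
  joint
}

# Joint genotype distributions among cases/controls from the enumeration
# oracle plus penetrance weighting.
enum_cc_joint <- function(p, q, D, f) {
  joint <- enum_joint(p, q, D)
  pi_ <- sum(f * rowSums(joint))
  list(case = f * joint / pi_, control = (1 - f) * joint / (1 - pi_),
       pi = pi_)
}

# Random feasible population parameters; D drawn as a fraction of its
# feasibility bound (negative fractions allowed).
rand_params <- function(d_frac = NULL) {
  p <- runif(1, 0.1, 0.9)
  q <- runif(1, 0.1, 0.9)
  b <- ld_bounds(p, q)
  if (is.null(d_frac)) d_frac <- runif(1, -0.9, 0.9)
  D <- if (d_frac >= 0) d_frac * b[2] else -d_frac * b[1]
  pop_params(p, q, D)
}

# Random non-degenerate count table.
rand_counts <- function(n_case = 200, n_control = 200) {
  repeat {
    case <- as.vector(stats::rmultinom(1, n_case, runif(3, 0.1, 1)))
    ctrl <- as.vector(stats::rmultinom(1, n_control, runif(3, 0.1, 1)))
    if (sum(case) > 0 && sum(ctrl) > 0) return(genotype_counts(case, ctrl))
  }
}

# Exact (conditional) Hardy-Weinberg test: probability of the heterozygote
# count given the minor-allele count, summed over outcomes at most as
# probable as the observed one.
exact_hwe_p <- function(counts) {
  n <- sum(counts)
  nA <- 2 * counts[1] + counts[2]
  if (nA > n) {
    counts <- rev(counts)
    nA <- 2 * counts[1] + counts[2]
  }
  hets <- seq(nA %% 2, nA, by = 2)
  logp <- vapply(hets, function(h) {
    hom1 <- (nA - h) / 2
    hom2 <- n - hom1 - h
    lfactorial(n) - lfactorial(hom1) - lfactorial(h) - lfactorial(hom2) +
      h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) -
      lfactorial(2 * n)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- probs[match(counts[2], hets)]
  sum(probs[probs <= obs + 1e-12])
}
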