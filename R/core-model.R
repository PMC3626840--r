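# Population-genetic model for a biallelic marker locus (alleles M/m, M
# frequency p) and a biallelic disease locus (alleles A/a, A frequency q)
# linked by the linkage-disequilibrium coefficient D = Pr(MA) - p*q.
#
# Genotype index convention used throughout the package:
#   i, j = 1, 2, 3  <->  AA/MM, Aa/Mm, aa/mm
# M and A are the counted alleles.

.FEAS_TOL <- 1e-12

#' Feasibility bounds for the LD coefficient
#'
#' Given allele frequencies `p` (marker allele M) and `q` (disease allele A),
#' the LD coefficient `D = Pr(MA) - p*q` is constrained by the requirement
#' that all four haplotype frequencies be non-negative:
#' `max(-p*q, -(1-p)*(1-q)) <= D <= min(p*(1-q), (1-p)*q)`.
#'
#' @param p Marker allele frequency, in (0, 1).
#' @param q Disease allele frequency, in (0, 1).
#' @return Numeric vector `c(D_min, D_max)`.
#' @examples
#' ld_bounds(0.5, 0.5)  # c(-0.25, 0.25)
#' @export
ld_bounds <- function(p, q) {
  if (!is.numeric(p) || !is.numeric(q) || length(p) != 1L || length(q) != 1L ||
      !is.finite(p) || !is.finite(q) || p <= 0 || p >= 1 || q <= 0 || q >= 1)
    stop("'p' and 'q' must be single frequencies strictly inside (0, 1)")
  c(max(-p * q, -(1 - p) * (1 - q)), min(p * (1 - q), (1 - p) * q))
}

#' Population parameters (p, q, D)
#'
#' Bundles the marker allele frequency `p`, the disease allele frequency `q`
#' and the LD coefficient `D`, checking feasibility.  `D` exactly at a bound
#' (one haplotype frequency zero) is accepted but flagged as `boundary`;
#' downstream likelihood code treats `0 * log(0)` as 0.
#'
#' @param p,q Allele frequencies in (0, 1).
#' @param D LD coefficient, within [ld_bounds()] of `p` and `q` (checked with
#'   tolerance `1e-12` so bound-adjacent values returned by optimisation are
#'   not rejected).
#' @return An object of class `pop_params` with fields `p`, `q`, `D`,
#'   `hap` (haplotype frequencies MA, Ma, mA, ma) and `boundary`.
#' @export
pop_params <- function(p, q, D) {
  b <- ld_bounds(p, q)
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D))
    stop("'D' must be a single finite number")
  if (D < b[1] - .FEAS_TOL || D > b[2] + .FEAS_TOL)
    stop(sprintf("D = %g outside feasibility bounds [%g, %g] for p = %g, q = %g",
                 D, b[1], b[2], p, q))
  D <- min(max(D, b[1]), b[2])
  hap <- c(MA = p * q + D, Ma = p * (1 - q) - D,
           mA = (1 - p) * q - D, ma = (1 - p) * (1 - q) + D)
  structure(list(p = p, q = q, D = D, hap = hap,
                 boundary = any(abs(hap) <= .FEAS_TOL)),
            class = "pop_params")
}

#' @export
print.pop_params <- function(x, ...) {
  cat(sprintf("pop_params: p = %.4g, q = %.4g, D = %.4g%s\n",
              x$p, x$q, x$D, if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Penetrance model (f1, f2, f3)
#'
#' Penetrances of the disease-locus genotypes AA, Aa, aa.  The classical
#' presets are `"dominant"` (1, 1, 0), `"additive"` (1, 1/2, 0) and
#' `"recessive"` (1, 0, 0); any triplet in [0, 1] is accepted.
#'
#' @param f Either a preset name or a numeric vector `c(f1, f2, f3)`.
#' @return An object of class `penetrance` (numeric length-3 vector).
#' @export
penetrance <- function(f = c("additive", "dominant", "recessive")) {
  if (is.character(f)) {
    f <- switch(match.arg(f),
                dominant = c(1, 1, 0),
                additive = c(1, 0.5, 0),
                recessive = c(1, 0, 0))
  }
  if (!is.numeric(f) || length(f) != 3L || any(!is.finite(f)) ||
      any(f < 0) || any(f > 1))
    stop("penetrances must be three numbers in [0, 1]")
  structure(as.numeric(f), names = c("f1", "f2", "f3"), class = "penetrance")
}

#' Population prevalence attributable to the disease locus
#'
#' `pi = f1*q^2 + 2*f2*q*(1-q) + f3*(1-q)^2`.
#'
#' @param pen A [penetrance()] object (or coercible numeric triplet).
#' @param q Disease allele frequency in (0, 1).
#' @return Prevalence in [0, 1].
#' @export
prevalence <- function(pen, q) {
  pen <- unclass(penetrance(pen))
  unname(pen[1] * q^2 + 2 * pen[2] * q * (1 - q) + pen[3] * (1 - q)^2)
}

# Hardy-Weinberg genotype probabilities at allele frequency x
hwe_probs <- function(x) c(x^2, 2 * x * (1 - x), (1 - x)^2)

# The shared conditional-genotype table: rows are the conditioning genotype
# (homozygote for the focal allele, het, other homozygote); within a row the
# two transmitted alleles are independent with focal-allele probabilities
# (Q, Q), (Q, R), (R, R).
cond_rows <- function(Q, R) {
  rbind(c(Q^2, 2 * Q * (1 - Q), (1 - Q)^2),
        c(Q * R, Q + R - 2 * Q * R, (1 - Q) * (1 - R)),
        c(R^2, 2 * R * (1 - R), (1 - R)^2))
}

#' Conditional distribution of marker genotype given disease genotype
#'
#' Returns the 3x3 matrix `g` with `g[i, j] = Pr(marker genotype j | disease
#' genotype i)`, computed from `Q = p + D/q` and `R = p - D/(1-q)` (the
#' frequencies of allele M on A- and a-bearing haplotypes).  Rows sum to 1.
#'
#' @param params A [pop_params()] object.
#' @return 3x3 matrix with rows AA, Aa, aa and columns MM, Mm, mm.
#' @export
marker_given_disease <- function(params) {
  stopifnot(inherits(params, "pop_params"))
  Q <- params$p + params$D / params$q
  R <- params$p - params$D / (1 - params$q)
  g <- cond_rows(Q, R)
  dimnames(g) <- list(c("AA", "Aa", "aa"), c("MM", "Mm", "mm"))
  g
}

#' Conditional distribution of disease genotype given marker genotype
#'
#' Returns the 3x3 matrix `h` with `h[i, j] = Pr(disease genotype i | marker
#' genotype j)`, computed from `Q' = q + D/p` and `R' = q - D/(1-p)` (the
#' frequencies of allele A on M- and m-bearing haplotypes).  Columns sum
#' to 1, and `h[i, j] * HWE_p(j) = g[i, j] * HWE_q(i)` (Bayes).
#'
#' @param params A [pop_params()] object.
#' @return 3x3 matrix with rows AA, Aa, aa and columns MM, Mm, mm.
#' @export
disease_given_marker <- function(params) {
  stopifnot(inherits(params, "pop_params"))
  Qp <- params$q + params$D / params$p
  Rp <- params$q - params$D / (1 - params$p)
  h <- t(cond_rows(Qp, Rp))
  dimnames(h) <- list(c("AA", "Aa", "aa"), c("MM", "Mm", "mm"))
  h
}

#' Joint genotype distributions among cases and among controls
#'
#' Each disease genotype carries its own disease risk, so conditioning on
#' case/control status reweights the unconditional joint
#' `Pr(X = i) * g[i, j]`:
#' `case[i, j] = f_i * HWE_q(i) * g[i, j] / pi` and
#' `control[i, j] = (1 - f_i) * HWE_q(i) * g[i, j] / (1 - pi)`.
#'
#' @param params A [pop_params()] object.
#' @param pen A [penetrance()] object.
#' @return List with `case` and `control` (3x3 matrices, each summing to 1;
#'   `NULL` for a degenerate arm, i.e. `case` when `pi = 0`, `control` when
#'   `pi = 1`) and `pi`, the prevalence.
#' @export
case_control_joint <- function(params, pen) {
  pen <- penetrance(pen)
  g <- marker_given_disease(params)
  pri <- hwe_probs(params$q)
  pi_ <- sum(pen * pri)
  case <- if (pi_ > .FEAS_TOL) (pen * pri) * g / pi_ else NULL
  control <- if (pi_ < 1 - .FEAS_TOL) ((1 - pen) * pri) * g / (1 - pi_)
             else NULL
  list(case = case, control = control, pi = pi_)
}

#' Posterior weights of disease genotypes given marker genotype and status
#'
#' The E-step weights of the EM algorithm:
#' `w[i, j] = f_i * h[i, j] / sum_i' f_i' * h[i', j]` for cases and
#' `v[i, j] = (1 - f_i) * h[i, j] / sum_i' (1 - f_i') * h[i', j]` for
#' controls.  Columns of `w` and `v` sum to 1.  A column whose denominator
#' is zero (that marker genotype cannot occur in that arm) is returned as
#' `NA` and must not receive observed counts.
#'
#' @param params A [pop_params()] object.
#' @param pen A [penetrance()] object.
#' @return List with 3x3 matrices `w` (cases) and `v` (controls).
#' @export
posterior_weights <- function(params, pen) {
  pen <- penetrance(pen)
  h <- disease_given_marker(params)
  fh <- pen * h
  cfh <- (1 - pen) * h
  dw <- colSums(fh)
  dv <- colSums(cfh)
  w <- sweep(fh, 2, ifelse(dw > 0, dw, NA_real_), "/")
  v <- sweep(cfh, 2, ifelse(dv > 0, dv, NA_real_), "/")
  list(w = w, v = v)
}

#' Expected case-control difference in marker allele frequency
#'
#' Decomposes the expected difference in marker allele frequency between
#' cases and controls drawn from `k` (sub)populations into a structure term,
#' `sum_i (r_i - s_i) * p_i`, present even without LD, and an LD term,
#' `sum_i D_i / (q_i (1 - q_i)) * (r_i (q_case_i - q_i) - s_i (q_ctrl_i - q_i))`,
#' where `q_case` and `q_ctrl` are the disease-allele frequencies among cases
#' and controls implied by the penetrance model.
#'
#' @param pops List of [pop_params()], one per population.
#' @param pens A single [penetrance()] shared by all populations, or a list,
#'   one per population.
#' @param r,s Case and control sampling proportions, each summing to 1
#'   (tolerance 1e-9), one entry per population.
#' @return Expected `delta p_M` (scalar).
#' @export
expected_delta_pM <- function(pops, pens, r, s) {
  if (inherits(pops, "pop_params")) pops <- list(pops)
  k <- length(pops)
  if (inherits(pens, "penetrance") || (is.numeric(pens) && length(pens) == 3L))
    pens <- rep(list(penetrance(pens)), k)
  if (length(pens) != k || length(r) != k || length(s) != k)
    stop("'pops', 'pens', 'r' and 's' must have one entry per population")
  if (abs(sum(r) - 1) > 1e-9 || abs(sum(s) - 1) > 1e-9)
    stop("'r' and 's' must each sum to 1")
  total <- 0
  for (i in seq_len(k)) {
    par <- pops[[i]]; f <- unclass(penetrance(pens[[i]]))
    q <- par$q
    pi_ <- prevalence(f, q)
    q_case <- (f[1] * q^2 + f[2] * q * (1 - q)) / pi_
    q_ctrl <- ((1 - f[1]) * q^2 + (1 - f[2]) * q * (1 - q)) / (1 - pi_)
    total <- total + (r[i] - s[i]) * par$p +
      par$D / (q * (1 - q)) *
        (r[i] * (q_case - q) - s[i] * (q_ctrl - q))
  }
  unname(total)
}

#' Bias of the control-based marker allele frequency estimator
#'
#' The marker allele frequency among controls is
#' `p' = p + D * ((f2 - f1) * q + (f3 - f2) * (1 - q)) / (1 - pi)`;
#' using controls to estimate `p` therefore carries a bias `|p' - p|` that
#' vanishes with `D` and stays below 0.05 whenever the prevalence is below
#' 10%.
#'
#' @param params A [pop_params()] object.
#' @param pen A [penetrance()] object.
#' @return List with `p_prime` and `bias`.
#' @export
control_freq_bias <- function(params, pen) {
  stopifnot(inherits(params, "pop_params"))
  f <- unclass(penetrance(pen))
  q <- params$q
  pi_ <- prevalence(f, q)
  if (pi_ >= 1) stop("prevalence is 1: no controls exist")
  p_prime <- unname(params$p +
    params$D * ((f[2] - f[1]) * q + (f[3] - f[2]) * (1 - q)) / (1 - pi_))
  list(p_prime = p_prime, bias = abs(p_prime - params$p))
}
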