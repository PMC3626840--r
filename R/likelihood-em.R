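# Method 1: EM estimation of (q, D) given the marker allele frequency and a
# fixed penetrance triplet, and the 2-df (2k-df across cohorts)
# likelihood-ratio association test.
#
# The disease genotypes are latent.  The E-step computes the posterior
# weights w (cases) and v (controls) of the disease genotypes given each
# marker genotype; the M-step maximises the weighted objective
# sum_ij c_ij log g_ij (c_ij = n1j w_ij + n2j v_ij) over the feasible
# (q, D) region.  Internally the M-step works in the haplotype-conditional
# parametrisation Q = Pr(M | A haplotype) = p + D/q, R = Pr(M | a
# haplotype) = p - D/(1-q): the objective is concave in each of Q and R,
# the per-coordinate score equation is a quadratic solved in closed form,
# and among its roots the feasible one with the highest objective is kept.
# D = 0 corresponds to Q = R = p, where the objective collapses to the
# Hardy-Weinberg multinomial and is independent of q.

# log with 0*log(0) = 0 handled by clamping: weights/counts of exactly zero
# multiply a large-but-finite negative number, contributing zero.
.clog <- function(x) log(pmax(x, 1e-320))

# Marker-genotype probabilities among cases and controls, vectorised over
# (q, D) for fixed p and penetrance.
.cc_marginals <- function(p, q, D, f) {
  n <- max(length(q), length(D))
  q <- rep_len(q, n); D <- rep_len(D, n)
  Q <- p + D / q
  R <- p - D / (1 - q)
  ok <- q > 0 & q < 1 &
    Q >= -1e-12 & Q <= 1 + 1e-12 & R >= -1e-12 & R <= 1 + 1e-12
  Q <- pmin(pmax(Q, 0), 1); R <- pmin(pmax(R, 0), 1)
  g1 <- cbind(Q^2, 2 * Q * (1 - Q), (1 - Q)^2)
  g2 <- cbind(Q * R, Q + R - 2 * Q * R, (1 - Q) * (1 - R))
  g3 <- cbind(R^2, 2 * R * (1 - R), (1 - R)^2)
  w2 <- q^2; w1 <- 2 * q * (1 - q); w0 <- (1 - q)^2
  pi_ <- f[1] * w2 + f[2] * w1 + f[3] * w0
  case <- (f[1] * w2 * g1 + f[2] * w1 * g2 + f[3] * w0 * g3) / pi_
  ctrl <- ((1 - f[1]) * w2 * g1 + (1 - f[2]) * w1 * g2 +
             (1 - f[3]) * w0 * g3) / (1 - pi_)
  list(case = case, control = ctrl, pi = pi_, ok = ok)
}

# Marginal observed-data log-likelihood, vectorised over (q, D).
.obs_ll <- function(p, q, D, f, n1, n2) {
  m <- .cc_marginals(p, q, D, f)
  ll <- .clog(m$case) %*% n1 + .clog(m$control) %*% n2
  ll <- as.numeric(ll)
  impossible <- ((m$case <= 0) %*% (n1 > 0) + (m$control <= 0) %*% (n2 > 0)) > 0
  ll[!m$ok | as.vector(impossible) | m$pi <= 0 | m$pi >= 1] <- -Inf
  ll
}

#' Log-likelihood under no linkage disequilibrium
#'
#' With `D = 0` the marker carries no information on disease status and the
#' likelihood collapses to a Hardy-Weinberg multinomial on the pooled
#' sample:
#' `(n11+n21) log(p^2) + (n12+n22) log(2p(1-p)) + (n13+n23) log((1-p)^2)`,
#' with `0 * log(0) = 0`.  It is maximised at [null_mle_p()].
#'
#' @param p Marker allele frequency.
#' @param counts A [genotype_counts()] table.
#' @return Log-likelihood value.
#' @export
null_loglik <- function(p, counts) {
  counts <- as_genotype_counts(counts)
  nj <- colSums(counts)
  probs <- hwe_probs(p)
  if (any(nj > 0 & probs <= 0)) return(-Inf)
  sum(nj * .clog(probs) * (nj > 0))
}

#' Marginal observed-data log-likelihood of a case-control genotype table
#'
#' `sum_j n1j log Pr(Y = j | case) + n2j log Pr(Y = j | control)`, where
#' the arm-specific marker distributions are penetrance-weighted mixtures
#' over the latent disease genotypes.  Returns `-Inf` (never an error)
#' when a genotype with positive count has zero predicted probability.  At
#' `D = 0` it coincides with [null_loglik()].  Used for diagnostics and as
#' an independent check of the fitting machinery; note that the
#' association statistic of [lr_test()] is built on the weighted EM
#' objective (see [em_fit()]), not on this marginal likelihood.
#'
#' @param p,q,D Model parameters.
#' @param pen A [penetrance()] object.
#' @param counts A [genotype_counts()] table.
#' @return Log-likelihood value (scalar).
#' @export
observed_loglik <- function(p, q, D, pen, counts) {
  counts <- as_genotype_counts(counts)
  f <- unclass(penetrance(pen))
  .obs_ll(p, q, D, f, counts[1, ], counts[2, ])[1]
}

#' E-step objective of the EM algorithm
#'
#' The weighted complete-data term
#' `sum_ij (n1j * w[i,j] + n2j * v[i,j]) * log g[i,j](p, q, D)` evaluated
#' at fixed posterior weights: the objective the M-step maximises over
#' `(q, D)`.  Cells with zero weight contribute zero; a zero `g` cell
#' carrying positive weight and count yields `-Inf`.
#'
#' @param q,D Parameters at which the conditional table `g` is evaluated.
#' @param w,v 3x3 posterior-weight matrices from [posterior_weights()].
#' @param counts A [genotype_counts()] table.
#' @param p Marker allele frequency.
#' @return Scalar objective value.
#' @export
expected_loglik <- function(q, D, w, v, counts, p) {
  counts <- as_genotype_counts(counts)
  cij <- sweep(w, 2, counts[1, ], "*") + sweep(v, 2, counts[2, ], "*")
  cij[is.na(cij)] <- 0
  g <- marker_given_disease(pop_params(p, q, D))
  val <- sum(cij * .clog(g))
  if (any(cij > 0 & g <= 0)) -Inf else val
}

# The weighted objective in (Q, R) coordinates for fixed weights, with the
# weight matrix flattened row-wise: cv = (c11..c13, c21..c23, c31..c33).
.G_QR <- function(Q, R, cv) {
  g <- c(Q * Q, 2 * Q * (1 - Q), (1 - Q) * (1 - Q),
         Q * R, Q + R - 2 * Q * R, (1 - Q) * (1 - R),
         R * R, 2 * R * (1 - R), (1 - R) * (1 - R))
  sum(cv * log(pmax(g, 1e-320)))
}

# Exact maximisation of .G_QR over one coordinate on [lo, hi] with the
# other held fixed.  The objective is a sum of logs of affine functions of
# the coordinate, hence concave; the score equation
#   A/x - B/(1-x) + c22*k/(other + k*x) = 0,  k = 1 - 2*other,
# is quadratic.  Candidate maximisers are its real roots inside [lo, hi]
# plus the endpoints; the feasible candidate with the highest objective
# wins.
.coord_max <- function(other, A, B, c22, lo, hi, gfun) {
  k <- 1 - 2 * other
  a2 <- -k * (A + B + c22)
  a1 <- A * (k - other) - B * other + c22 * k
  a0 <- A * other
  roots <- if (abs(a2) > 1e-14) {
    disc <- a1 * a1 - 4 * a2 * a0
    if (disc < 0) numeric(0)
    else (-a1 + c(-1, 1) * sqrt(disc)) / (2 * a2)
  } else if (abs(a1) > 1e-14) -a0 / a1 else numeric(0)
  best_x <- lo; best_v <- gfun(lo)
  v <- gfun(hi)
  if (v > best_v) { best_v <- v; best_x <- hi }
  for (x in roots) {
    if (x > lo && x < hi) {
      v <- gfun(x)
      if (v > best_v) { best_v <- v; best_x <- x }
    }
  }
  best_x
}

# One full M-step: coordinate-ascent sweeps to joint stationarity on both
# sign branches of D (Q >= p >= R and Q <= p <= R), keeping the branch
# with the higher objective.  Returns Q, R and the objective value.
.mstep_QR <- function(p, cv, Q0, R0, sweeps = 30L) {
  A_Q <- 2 * cv[1] + cv[2] + cv[4]
  B_Q <- cv[2] + 2 * cv[3] + cv[6]
  A_R <- 2 * cv[7] + cv[8] + cv[4]
  B_R <- cv[8] + 2 * cv[9] + cv[6]
  c22 <- cv[5]
  run_branch <- function(Qlo, Qhi, Rlo, Rhi, Q, R) {
    Q <- min(max(Q, Qlo), Qhi)
    R <- min(max(R, Rlo), Rhi)
    # seed with a coarse scan of the branch diagonal: pure coordinate
    # ascent can be trapped at the D = 0 corner (Q = R = p), where moving
    # either coordinate alone decreases the objective although moving
    # both helps
    ts <- seq(0.05, 0.95, by = 0.06)
    diagQ <- Qlo + ts * (Qhi - Qlo)
    diagR <- Rhi - ts * (Rhi - Rlo)
    dv <- vapply(seq_along(ts),
                 function(i) .G_QR(diagQ[i], diagR[i], cv), numeric(1))
    i <- which.max(dv)
    if (length(i) && is.finite(dv[i]) && dv[i] > .G_QR(Q, R, cv)) {
      Q <- diagQ[i]; R <- diagR[i]
    }
    val <- .G_QR(Q, R, cv)
    for (s in seq_len(sweeps)) {
      Q <- .coord_max(R, A_Q, B_Q, c22, Qlo, Qhi,
                      function(x) .G_QR(x, R, cv))
      R <- .coord_max(Q, A_R, B_R, c22, Rlo, Rhi,
                      function(x) .G_QR(Q, x, cv))
      val_new <- .G_QR(Q, R, cv)
      if (!is.finite(val_new) || val_new - val < 1e-11) {
        val <- max(val, val_new, na.rm = TRUE); break
      }
      val <- val_new
    }
    list(Q = Q, R = R, value = val)
  }
  pos <- run_branch(p, 1, 0, p, max(Q0, p), min(R0, p))
  neg <- run_branch(0, p, p, 1, min(Q0, p), max(R0, p))
  if (pos$value >= neg$value) pos else neg
}

# (Q, R) -> (q, D); at Q = R = p the LD is zero and q is unidentified, in
# which case the supplied fallback q is kept.
.QR_to_qD <- function(p, Q, R, q_fallback = 0.5) {
  if (abs(Q - R) < 1e-10) return(c(q = q_fallback, D = 0))
  q <- (p - R) / (Q - R)
  q <- min(max(q, 1e-12), 1 - 1e-12)
  c(q = q, D = q * (Q - p))
}

#' EM estimation of the LD coefficient and disease allele frequency
#'
#' Fits `(q, D)` for a fixed marker allele frequency `p` and penetrance
#' triplet by EM over the latent disease genotypes.  The E-step computes
#' the posterior weights [posterior_weights()]; the M-step maximises the
#' weighted objective [expected_loglik()] exactly, coordinate-wise in the
#' haplotype-conditional parametrisation (see the package vignette), with
#' the feasible root of highest objective selected.  Iteration stops when
#' the objective changes by less than `tol`.  Multiple starting points
#' guard against dependence on the initial guess; the fit with the highest
#' final objective is returned.
#'
#' @param counts A [genotype_counts()] table; both arms must be non-empty.
#' @param pen A [penetrance()] object or preset name.
#' @param p Marker allele frequency in (0, 1); default
#'   [estimate_p_from_controls()].  For diseases of non-negligible
#'   prevalence the control-based estimate is biased (see
#'   [control_freq_bias()]) and an external estimate should be supplied.
#' @param init Optional `c(q0, D0)` starting point, used in place of the
#'   default start `(0.5, 0.25 * D_max)`.
#' @param tol Convergence tolerance on the change in objective (default
#'   1e-8).
#' @param max_iter Maximum EM iterations per start (default 500).
#' @param extra_starts Run the additional restarts at `q0 = 0.25, 0.75`
#'   with `D0` of both signs (default `TRUE`).
#' @param engine `"cpp"` (default, compiled fast path) or `"R"` (reference
#'   implementation).  Both perform the identical algorithm and are
#'   cross-checked in the test suite.
#' @return An object of class `em_result`: `q_hat`, `D_hat`, `p_used`,
#'   `loglik` (the EM objective at convergence), `marginal_loglik`
#'   ([observed_loglik()] at the estimate, for diagnostics),
#'   `loglik_trace` (per-iteration objective values), `iterations`,
#'   `converged`, `boundary` (whether `D_hat` sits at a feasibility
#'   bound).
#' @export
em_fit <- function(counts, pen = penetrance("additive"), p = NULL,
                   init = NULL, tol = 1e-8, max_iter = 500L,
                   extra_starts = TRUE, engine = c("cpp", "R")) {
  counts <- as_genotype_counts(counts)
  engine <- match.arg(engine)
  n1 <- counts[1, ]; n2 <- counts[2, ]
  if (sum(n1) == 0 || sum(n2) == 0)
    stop("both a case arm and a control arm are required")
  if (is.null(p)) p <- estimate_p_from_controls(counts)
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("'p' must lie strictly inside (0, 1); supply an external estimate")
  f <- unclass(penetrance(pen))

  # the start set is symmetric in the sign of D so that relabelling the
  # marker alleles (which maps D to -D) explores mirrored basins
  starts <- if (is.null(init)) {
    b <- ld_bounds(p, 0.5)
    list(c(0.5, 0.25 * b[2]), c(0.5, 0.25 * b[1]))
  } else list(init)
  if (extra_starts) {
    for (q0 in c(0.25, 0.75)) {
      b <- ld_bounds(p, q0)
      starts <- c(starts, list(c(q0, 0.25 * b[2]), c(q0, 0.25 * b[1])))
    }
  }

  res <- if (engine == "cpp") {
    .em_fit_engine_cpp(n1, n2, f, p, do.call(rbind, starts), tol,
                       as.integer(max_iter))
  } else {
    .em_fit_r(n1, n2, f, p, starts, tol, max_iter)
  }
  # Root-selection rule: admissible solutions have 0 < q < 1 strictly.  A
  # fixed point with q at the edge is degenerate (all mass on one latent
  # disease genotype, the marker distribution refitted freely) and is
  # discarded; when no admissible solution remains, the no-LD model is
  # retained (D = 0, objective equal to the closed-form null value, which
  # is always a feasible candidate).  The same floor applies to any
  # solution whose objective falls below the null value.
  # The inadmissible fixed point is recognisable exactly: with all latent
  # mass on one disease genotype the M-step refits the marker frequency
  # freely and the objective equals the pooled Hardy-Weinberg fit
  # null_loglik(null_mle_p).  Edge-q solutions that exceed that benchmark
  # carry genuine case-control information (e.g. under strongly
  # mis-specified penetrance) and are kept.
  nll <- null_loglik(p, counts)
  degenerate <- (res$q_hat <= 0.01 || res$q_hat >= 0.99) &&
    res$loglik <= null_loglik(null_mle_p(counts), counts) + 0.01
  if (res$loglik < nll || degenerate) {
    res$D_hat <- 0
    res$loglik <- nll
    res$loglik_trace <- c(res$loglik_trace, nll)
    res$converged <- TRUE
  }
  bD <- ld_bounds(p, res$q_hat)
  structure(list(
    q_hat = res$q_hat, D_hat = res$D_hat, p_used = p,
    loglik = res$loglik,
    marginal_loglik = .obs_ll(p, res$q_hat, res$D_hat, f, n1, n2),
    loglik_trace = res$loglik_trace, iterations = res$iterations,
    converged = res$converged,
    boundary = min(res$D_hat - bD[1], bD[2] - res$D_hat) < 1e-6),
    class = "em_result")
}

# Reference implementation of the EM engine (see also src/em_fit.cpp).
.em_fit_r <- function(n1, n2, f, p, starts, tol, max_iter) {
  # E-step: flattened weighted-count vector cv = (c11..c13, ..., c33) with
  # c_ij = n1j * w_ij + n2j * v_ij; written inline for speed (it sits in
  # the innermost loop of power studies).  With strict = FALSE an
  # infeasible point (a marker genotype of zero probability carrying
  # observed counts) yields NULL instead of an error, so that trial
  # points during backtracking are simply rejected.
  estep_cv <- function(hQ, hR, strict = TRUE) {
    # hQ, hR are the disease-allele frequencies on M- and m-bearing
    # haplotypes (q + D/p and q - D/(1-p))
    h <- matrix(c(hQ * hQ, 2 * hQ * (1 - hQ), (1 - hQ) * (1 - hQ),
                  hQ * hR, hQ + hR - 2 * hQ * hR, (1 - hQ) * (1 - hR),
                  hR * hR, 2 * hR * (1 - hR), (1 - hR) * (1 - hR)),
                3, 3)  # h[i, j] = Pr(disease genotype i | marker genotype j)
    fh <- f * h
    cfh <- (1 - f) * h
    dw <- .colSums(fh, 3, 3)
    dv <- .colSums(cfh, 3, 3)
    geno <- c("MM", "Mm", "mm")
    if (any(dw <= 0 & n1 > 0)) {
      if (!strict) return(NULL)
      stop(sprintf(
        "marker genotype %s has zero probability among cases but positive count",
        paste(geno[dw <= 0 & n1 > 0], collapse = ", ")))
    }
    if (any(dv <= 0 & n2 > 0)) {
      if (!strict) return(NULL)
      stop(sprintf(
        "marker genotype %s has zero probability among controls but positive count",
        paste(geno[dv <= 0 & n2 > 0], collapse = ", ")))
    }
    aw <- ifelse(dw > 0, n1 / dw, 0)
    av <- ifelse(dv > 0, n2 / dv, 0)
    cij <- fh * rep(aw, each = 3) + cfh * rep(av, each = 3)
    as.vector(t(cij))
  }

  # disease-allele-given-marker-haplotype frequencies and q implied by a
  # point in (Q, R) space; q_fb is used on the D = 0 ridge where q is
  # unidentified
  hq_of <- function(Q, R, q_fb) {
    if (abs(Q - R) < 1e-10) return(c(q = q_fb, hQ = q_fb, hR = q_fb))
    q <- min(max((p - R) / (Q - R), 0), 1)
    c(q = q,
      hQ = min(max(q * Q / p, 0), 1),
      hR = min(max(q * (1 - Q) / (1 - p), 0), 1))
  }

  best <- NULL
  best_interior <- NULL
  for (st in starts) {
    q_fb <- min(max(st[1], 1e-6), 1 - 1e-6)
    b <- ld_bounds(p, q_fb)
    Dc <- min(max(st[2], b[1]), b[2])
    Qc <- p + Dc / q_fb; Rc <- p - Dc / (1 - q_fb)
    hp <- hq_of(Qc, Rc, q_fb)
    cv <- estep_cv(hp["hQ"], hp["hR"])
    ll <- .G_QR(Qc, Rc, cv)
    trace <- ll
    ll_prev2 <- NA_real_
    checkpoint <- ll
    alpha <- 1  # damping factor; halved when the iteration cycles
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      m <- .mstep_QR(p, cv, Qc, Rc)
      # fixed-point step (damped if needed); an infeasible trial point is
      # pulled back towards the incumbent until feasible
      step <- alpha
      cvt <- NULL
      for (h in 1:8) {
        Qt <- Qc + step * (m$Q - Qc)
        Rt <- Rc + step * (m$R - Rc)
        hp <- hq_of(Qt, Rt, q_fb)
        cvt <- estep_cv(hp["hQ"], hp["hR"], strict = FALSE)
        if (!is.null(cvt)) break
        step <- step / 2
      }
      if (is.null(cvt)) {
        # boxed in on the feasibility boundary: the incumbent is the
        # constrained fixed point
        converged <- TRUE
        break
      }
      llt <- .G_QR(Qt, Rt, cvt)
      q_fb <- unname(hp["q"])
      Qc <- Qt; Rc <- Rt; cv <- cvt
      trace <- c(trace, llt)
      # stop when the objective plateaus (the convergence monitor of the
      # underlying algorithm); cycle damping below guards the rare
      # oscillating trajectories
      if (abs(llt - ll) < tol) {
        converged <- TRUE
        ll <- llt
        break
      }
      if (alpha == 1 && is.finite(ll_prev2) &&
          abs(llt - ll_prev2) < 1e-9)
        alpha <- 0.5  # period-2 oscillation: damp the iteration
      ll_prev2 <- ll
      ll <- llt
      if (it %% 40L == 0L) {
        # longer-period cycling: progressively damp when a whole window
        # has made no net progress
        if (abs(ll - checkpoint) < 1e-7 && alpha > 1 / 16) alpha <- alpha / 2
        checkpoint <- ll
      }
    }
    q_hat <- min(max(q_fb, 1e-12), 1 - 1e-12)
    D_hat <- q_hat * (Qc - p)
    bq <- ld_bounds(p, q_hat)
    D_hat <- min(max(D_hat, bq[1]), bq[2])
    sol <- list(q_hat = q_hat, D_hat = unname(D_hat), loglik = ll,
                loglik_trace = trace, iterations = it,
                converged = converged)
    if (is.null(best) || ll > best$loglik) best <- sol
    # solutions with q at the edge of (0, 1) are degenerate (the marker
    # distribution is fitted with a single latent class); keep the best
    # interior solution preferentially, as in the root-selection rule
    if (q_hat > 0.01 && q_hat < 0.99 &&
        (is.null(best_interior) || ll > best_interior$loglik))
      best_interior <- sol
  }
  if (!is.null(best_interior)) best_interior else best
}

#' @export
print.em_result <- function(x, ...) {
  cat(sprintf(
    "EM fit: q_hat = %.4f, D_hat = %.4f (p = %.4f), objective = %.4f\n",
    x$q_hat, x$D_hat, x$p_used, x$loglik))
  cat(sprintf("  %d iterations, converged: %s%s\n", x$iterations,
              x$converged, if (x$boundary) ", D at feasibility bound" else ""))
  invisible(x)
}

new_assoc_result <- function(method, statistic, df, estimates = NULL,
                             cohort_count = 1L, testable = TRUE,
                             negative_lr = FALSE) {
  structure(list(
    method = method,
    statistic = statistic,
    df = df,
    p_value = if (testable) stats::pchisq(statistic, df, lower.tail = FALSE)
              else 1,
    estimates = estimates,
    cohort_count = cohort_count,
    testable = testable,
    negative_lr = negative_lr), class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %d, p = %.4g (%d cohort%s)%s\n",
              x$method, x$statistic, x$df, x$p_value, x$cohort_count,
              if (x$cohort_count > 1) "s" else "",
              if (!x$testable) " [not testable]" else ""))
  invisible(x)
}

#' Likelihood-ratio test for linkage disequilibrium (Method 1)
#'
#' Tests `D = 0` with `LR = 2 * (L(p_hat, q_hat, D_hat) - L(p_hat, q,
#' D = 0))`, referred to a chi-square distribution with 2 degrees of
#' freedom.  The same `p_hat` (estimated from controls, or supplied
#' externally) enters both terms; under `D = 0` the likelihood collapses
#' to the closed form [null_loglik()], independent of `q`, which makes the
#' statistic non-negative by construction.  A numerically negative value
#' (possible only through M-step failure) is clipped at zero and flagged
#' in `negative_lr`.
#'
#' @param counts A [genotype_counts()] table.
#' @param pen A [penetrance()] object or preset name.
#' @param p_source `"controls"` (default) or `"external"`.
#' @param p External marker allele frequency (required for
#'   `p_source = "external"`).
#' @param ... Passed on to [em_fit()].
#' @return An `assoc_result` with `method = "M1"`, `df = 2`, and the
#'   [em_fit()] result in `$estimates`.
#' @export
lr_test <- function(counts, pen = penetrance("additive"),
                    p_source = c("controls", "external"), p = NULL, ...) {
  counts <- as_genotype_counts(counts)
  p_source <- match.arg(p_source)
  p_alt <- if (p_source == "external") {
    if (is.null(p)) stop("p_source = 'external' requires 'p'")
    p
  } else estimate_p_from_controls(counts)
  fit <- em_fit(counts, pen = pen, p = p_alt, ...)
  stat <- 2 * (fit$loglik - null_loglik(p_alt, counts))
  neg <- stat < -1e-6
  stat <- max(stat, 0)
  new_assoc_result("M1", stat, 2L, estimates = fit, negative_lr = neg)
}

#' Multi-cohort likelihood-ratio test (Method 1 across k cohorts)
#'
#' The joint log-likelihood of independent cohorts is the sum of the
#' per-cohort log-likelihoods, so the LR statistic for "no LD in any
#' cohort" is the sum of the per-cohort LR statistics, referred to a
#' chi-square distribution with `2k` degrees of freedom.  Each cohort's
#' marker allele frequency is estimated from its own controls (or taken
#' from `p`), and its `(q, D)` are fitted separately.
#'
#' @param cohorts A list of [cohort_sample()] objects (or count tables).
#' @param pen A [penetrance()] object or preset name.
#' @param p Optional vector of external marker allele frequencies, one per
#'   cohort (default: each cohort's controls).
#' @param ... Passed on to [em_fit()].
#' @return An `assoc_result` with `method = "M1"`, `df = 2k`, and the list
#'   of per-cohort [em_fit()] results in `$estimates`.
#' @export
multi_cohort_lr_test <- function(cohorts, pen = penetrance("additive"),
                                 p = NULL, ...) {
  cohorts <- as_cohort_list(cohorts)
  if (!is.null(p) && length(p) != length(cohorts))
    stop("'p' must have one entry per cohort")
  fits <- vector("list", length(cohorts))
  stat <- 0
  neg <- FALSE
  for (i in seq_along(cohorts)) {
    res <- tryCatch(
      if (is.null(p)) lr_test(cohorts[[i]]$counts, pen = pen, ...)
      else lr_test(cohorts[[i]]$counts, pen = pen,
                   p_source = "external", p = p[i], ...),
      error = function(e)
        stop(sprintf("cohort '%s': %s", cohorts[[i]]$id,
                     conditionMessage(e)), call. = FALSE))
    stat <- stat + res$statistic
    neg <- neg || res$negative_lr
    fits[[i]] <- res$estimates
  }
  names(fits) <- vapply(cohorts, `[[`, character(1), "id")
  new_assoc_result("M1", stat, 2L * length(cohorts), estimates = fits,
                   cohort_count = length(cohorts), negative_lr = neg)
}
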