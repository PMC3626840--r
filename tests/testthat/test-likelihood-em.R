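# EM estimation and the likelihood-ratio association test.

test_that("allele-frequency estimators follow their closed forms", {
  expect_equal(estimate_p_from_controls(
    genotype_counts(c(1, 1, 1), c(100, 200, 100))), 0.5)
  expect_equal(estimate_p_from_controls(
    genotype_counts(c(1, 1, 1), c(50, 0, 0))), 1.0)
  expect_equal(estimate_p_from_controls(
    genotype_counts(c(1, 1, 1), c(30, 50, 20))), 0.55)
  expect_error(estimate_p_from_controls(genotype_counts(c(5, 5, 5), c(0, 0, 0))),
               "no controls")
  expect_equal(null_mle_p(genotype_counts(c(10, 20, 10), c(30, 40, 30))), 0.5)
  expect_equal(null_mle_p(genotype_counts(c(7, 0, 0), c(3, 0, 0))), 1.0)
  # identical case/control distributions: pooled = per-arm frequency
  cnt <- genotype_counts(c(30, 50, 20), c(30, 50, 20))
  expect_equal(null_mle_p(cnt), 0.55)
})

test_that("null_loglik is the HWE multinomial and peaks at null_mle_p", {
  cnt <- genotype_counts(c(1, 2, 1), c(1, 2, 1))
  expect_equal(null_loglik(0.5, cnt), 2 * log(0.25) + 4 * log(0.5) + 2 * log(0.25))
  expect_equal(null_loglik(0.3, genotype_counts(c(0, 0, 0), c(0, 0, 0))), 0)
  # numeric-optimisation oracle
  set.seed(5)
  for (i in 1:10) {
    cnt <- rand_counts(80, 120)
    opt <- stats::optimize(function(p) null_loglik(p, cnt), c(1e-6, 1 - 1e-6),
                           maximum = TRUE, tol = 1e-10)
    expect_equal(opt$maximum, null_mle_p(cnt), tolerance = 1e-5)
  }
  # degenerate p only allowed when the matching counts vanish
  expect_equal(null_loglik(1, genotype_counts(c(5, 0, 0), c(5, 0, 0))), 0)
  expect_equal(null_loglik(1, genotype_counts(c(5, 1, 0), c(5, 0, 0))), -Inf)
})

test_that("observed_loglik collapses to null_loglik at D = 0 and handles zeros", {
  pen <- penetrance("additive")
  set.seed(6)
  for (i in 1:10) {
    cnt <- rand_counts()
    p <- runif(1, 0.2, 0.8)
    expect_equal(observed_loglik(p, runif(1, 0.1, 0.9), 0, pen, cnt),
                 null_loglik(p, cnt), tolerance = 1e-10)
  }
  # zero predicted probability with positive count: -Inf, not an error
  cnt <- genotype_counts(c(10, 10, 10), c(10, 10, 10))
  expect_identical(observed_loglik(0.5, 0.5, 0.25, pen, cnt), -Inf)
})

test_that("expected_loglik matches an explicit double loop", {
  pen <- penetrance("additive")
  set.seed(8)
  for (i in 1:10) {
    par <- rand_params()
    cnt <- rand_counts()
    wv <- posterior_weights(par, pen)
    g <- marker_given_disease(par)
    manual <- 0
    for (i2 in 1:3) for (j in 1:3)
      manual <- manual +
        (cnt[1, j] * wv$w[i2, j] + cnt[2, j] * wv$v[i2, j]) * log(g[i2, j])
    expect_equal(expected_loglik(par$q, par$D, wv$w, wv$v, cnt, par$p),
                 manual, tolerance = 1e-9)
  }
})

test_that("the two EM engines agree", {
  pen <- penetrance("additive")
  set.seed(9)
  for (i in 1:25) {
    cnt <- rand_counts(150, 150)
    p <- runif(1, 0.2, 0.8)
    a <- em_fit(cnt, pen, p = p)
    b <- em_fit(cnt, pen, p = p, engine = "R")
    # traces may differ when two starts tie at the optimum; the selected
    # optimum must not
    expect_equal(a$loglik, b$loglik, tolerance = 1e-7)
    expect_equal(a$D_hat, b$D_hat, tolerance = 1e-4)
  }
})

test_that("EM converges to a feasible fixed point above the null floor", {
  # the fixed point maximises the weighted objective given its own
  # weights over a region containing D = 0, where the objective equals
  # the closed-form null log-likelihood; hence loglik >= null_loglik and
  # the LR statistic is non-negative.  (The trace of the fixed-point
  # iteration is not monotone in general: started above the fixed point
  # it legitimately descends towards it.)
  pen_modes <- c("additive", "dominant", "recessive")
  set.seed(10)
  for (i in 1:200) {
    cnt <- rand_counts(sample(30:250, 1), sample(30:250, 1))
    p <- runif(1, 0.15, 0.85)
    fit <- em_fit(cnt, penetrance(sample(pen_modes, 1)), p = p)
    expect_true(fit$converged)
    expect_gte(fit$loglik, null_loglik(p, cnt) - 1e-6)
    expect_true(fit$q_hat > 0 && fit$q_hat < 1)
    b <- ld_bounds(fit$p_used, fit$q_hat)
    expect_true(fit$D_hat >= b[1] - 1e-9 && fit$D_hat <= b[2] + 1e-9)
  }
})

test_that("EM fixed point maximises its own M-step objective (grid oracle)", {
  # at convergence, (q_hat, D_hat) must maximise expected_loglik evaluated
  # at the converged posterior weights, over the interior feasible
  # rectangle (solutions with q at the edge of (0, 1) are rejected by the
  # root-selection rule, so the oracle is restricted accordingly); data
  # are drawn from the model so that interior optima exist
  pen <- penetrance("additive")
  set.seed(11)
  n_checked <- 0L
  for (i in 1:40) {
    par <- rand_params(d_frac = runif(1, -0.9, 0.9))
    cnt <- sample_counts(par, pen, 120, 120)
    p <- par$p
    fit <- em_fit(cnt, pen, p = p)
    if (fit$q_hat < 0.02 || fit$q_hat > 0.98) next  # degenerate outcome
    n_checked <- n_checked + 1L
    wv <- posterior_weights(pop_params(p, fit$q_hat, fit$D_hat), pen)
    w <- wv$w; v <- wv$v
    w[is.na(w)] <- 0; v[is.na(v)] <- 0
    qs <- seq(0.02, 0.98, by = 0.002)
    best <- c(-Inf, NA, NA)
    for (q in qs) {
      b <- ld_bounds(p, q)
      Ds <- seq(b[1], b[2], length.out = 201)
      cij <- sweep(w, 2, cnt[1, ], "*") + sweep(v, 2, cnt[2, ], "*")
      Q <- p + Ds / q; R <- p - Ds / (1 - q)
      vals <- cij[1, 1] * log(pmax(Q^2, 1e-320)) +
        cij[1, 2] * log(pmax(2 * Q * (1 - Q), 1e-320)) +
        cij[1, 3] * log(pmax((1 - Q)^2, 1e-320)) +
        cij[2, 1] * log(pmax(Q * R, 1e-320)) +
        cij[2, 2] * log(pmax(Q + R - 2 * Q * R, 1e-320)) +
        cij[2, 3] * log(pmax((1 - Q) * (1 - R), 1e-320)) +
        cij[3, 1] * log(pmax(R^2, 1e-320)) +
        cij[3, 2] * log(pmax(2 * R * (1 - R), 1e-320)) +
        cij[3, 3] * log(pmax((1 - R)^2, 1e-320))
      k <- which.max(vals)
      if (vals[k] > best[1]) best <- c(vals[k], q, Ds[k])
    }
    expect_lt(abs(fit$D_hat - best[3]), 0.011)
    fit_ll <- expected_loglik(fit$q_hat, fit$D_hat, w, v, cnt, p)
    expect_gte(fit_ll, best[1] - 0.02)
  }
  expect_gte(n_checked, 28L)  # the oracle must actually have run
})

test_that("EM recovers the generating parameters at the large-sample limit", {
  # expected counts of the additive p = q = 0.5, D = 0.15 population
  cnt <- genotype_counts(c(80, 100, 20), c(20, 100, 80))
  fit <- em_fit(cnt, penetrance("additive"), p = 0.5)
  expect_equal(fit$q_hat, 0.5, tolerance = 1e-6)
  expect_equal(fit$D_hat, 0.15, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("allele relabelling negates D_hat and preserves the LR", {
  pen <- penetrance("additive")
  set.seed(12)
  for (i in 1:20) {
    cnt <- rand_counts(150, 150)
    p <- runif(1, 0.2, 0.8)
    a <- lr_test(cnt, pen, p_source = "external", p = p)
    flipped <- genotype_counts(rev(cnt[1, ]), rev(cnt[2, ]))
    b <- lr_test(flipped, pen, p_source = "external", p = 1 - p)
    expect_equal(a$estimates$D_hat, -b$estimates$D_hat, tolerance = 1e-5)
    expect_equal(a$statistic, b$statistic, tolerance = 1e-6)
  }
})

test_that("lr_test is calibrated to zero on null-shaped data", {
  # identical case and control tables in exact HWE carry no signal: the
  # fixed point sits at D = 0 where the objective equals the null value
  cnt <- genotype_counts(c(50, 100, 50), c(50, 100, 50))
  res <- lr_test(cnt)
  expect_lt(res$statistic, 1e-4)
  expect_gt(res$p_value, 0.9999)
  expect_equal(res$df, 2L)
  expect_false(res$negative_lr)
  # statistic is non-negative by construction
  set.seed(13)
  for (i in 1:30) {
    res <- lr_test(rand_counts(100, 100), p_source = "external",
                   p = runif(1, 0.2, 0.8))
    expect_gte(res$statistic, 0)
    expect_false(res$negative_lr)
  }
})

test_that("lr_test argument handling", {
  cnt <- genotype_counts(c(30, 50, 20), c(20, 50, 30))
  expect_error(lr_test(cnt, p_source = "external"), "requires 'p'")
  expect_error(em_fit(genotype_counts(c(0, 0, 0), c(10, 10, 10))),
               "case arm and a control arm")
  expect_error(em_fit(cnt, p = 1.2), "inside \\(0, 1\\)")
})

test_that("multi-cohort LR test is additive over cohorts", {
  pen <- penetrance("additive")
  cnt <- genotype_counts(c(60, 100, 40), c(40, 100, 60))
  single <- lr_test(cnt, pen)
  one <- multi_cohort_lr_test(list(cohort_sample(cnt, "a")), pen)
  expect_equal(one$statistic, single$statistic)
  expect_equal(one$df, 2L)
  two <- multi_cohort_lr_test(list(cohort_sample(cnt, "a"),
                                   cohort_sample(cnt, "b")), pen)
  expect_equal(two$statistic, 2 * single$statistic, tolerance = 1e-9)
  expect_equal(two$df, 4L)
  expect_error(
    multi_cohort_lr_test(list(cohort_sample(cnt, "ok"),
                              list(id = "broken",
                                   counts = genotype_counts(c(1, 1, 1),
                                                            c(0, 0, 0))))),
    "broken")
})
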