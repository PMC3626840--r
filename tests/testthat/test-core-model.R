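# Population-genetic model: parameter types, conditional tables, posterior
# weights, structure decomposition and the control-frequency bias.

test_that("ld_bounds follows the haplotype feasibility formula", {
  expect_equal(ld_bounds(0.5, 0.5), c(-0.25, 0.25))
  expect_equal(ld_bounds(0.3, 0.7), c(-0.21, 0.09))
  expect_equal(ld_bounds(0.7, 0.3), c(-0.21, 0.09))
  for (bad in list(c(0, 0.5), c(1, 0.5), c(0.5, -0.1), c(0.5, 1.5)))
    expect_error(ld_bounds(bad[1], bad[2]), "strictly inside")
})

test_that("pop_params enforces and flags the D bounds", {
  expect_error(pop_params(0.3, 0.7, 0.1), "outside feasibility")
  expect_false(pop_params(0.3, 0.7, 0.05)$boundary)
  expect_true(pop_params(0.5, 0.5, 0.25)$boundary)
  # bound-adjacent values from optimisation are tolerated
  expect_silent(pop_params(0.5, 0.5, 0.25 + 1e-13))
})

test_that("penetrance presets and prevalence", {
  expect_equal(unclass(penetrance("dominant")), c(f1 = 1, f2 = 1, f3 = 0))
  expect_equal(unclass(penetrance("additive")), c(f1 = 1, f2 = 0.5, f3 = 0))
  expect_equal(unclass(penetrance("recessive")), c(f1 = 1, f2 = 0, f3 = 0))
  expect_error(penetrance(c(1, 2, 0)), "in \\[0, 1\\]")
  # additive penetrance makes prevalence equal q
  for (q in c(0.1, 0.37, 0.8))
    expect_equal(prevalence(penetrance("additive"), q), q)
  expect_equal(prevalence(penetrance(c(0.1, 0, 0)), 0.3), 0.1 * 0.09)
})

test_that("marker_given_disease matches its closed form and the oracle", {
  # no LD: every row is HWE at p
  g0 <- marker_given_disease(pop_params(0.5, 0.5, 0))
  expect_equal(unname(g0), matrix(rep(c(0.25, 0.5, 0.25), each = 3), 3, 3))
  # frozen table at p = q = 0.5, D = 0.15 (Q = 0.8, R = 0.2)
  g <- marker_given_disease(pop_params(0.5, 0.5, 0.15))
  expect_equal(unname(g), rbind(c(0.64, 0.32, 0.04),
                                c(0.16, 0.68, 0.16),
                                c(0.04, 0.32, 0.64)))
  # boundary D = D_max: A-haplotypes always carry M
  gb <- marker_given_disease(pop_params(0.5, 0.5, 0.25))
  expect_equal(unname(gb[1, ]), c(1, 0, 0))
  expect_equal(unname(gb[3, ]), c(0, 0, 1))
  # haplotype-enumeration oracle across a parameter grid
  set.seed(42)
  for (i in 1:25) {
    par <- rand_params()
    joint <- enum_joint(par$p, par$q, par$D)
    expect_equal(marker_given_disease(par), joint / rowSums(joint),
                 tolerance = 1e-12)
    expect_equal(rowSums(marker_given_disease(par)), c(AA = 1, Aa = 1, aa = 1),
                 tolerance = 1e-12)
  }
})

test_that("disease_given_marker is Bayes-consistent with marker_given_disease", {
  h <- disease_given_marker(pop_params(0.5, 0.5, 0.15))
  g <- marker_given_disease(pop_params(0.5, 0.5, 0.15))
  # p = q: the conditional tables carry the same entries, transposed
  # (h conditions on the marker genotype, g on the disease genotype)
  expect_equal(unname(h), t(unname(g)))
  # h * HWE_p(j) = g * HWE_q(i) entrywise over a 10x10x10 grid
  for (p in seq(0.05, 0.95, by = 0.1))
    for (q in seq(0.05, 0.95, by = 0.1))
      for (fr in seq(-0.9, 0.9, by = 0.2)) {
        b <- ld_bounds(p, q)
        par <- pop_params(p, q, if (fr >= 0) fr * b[2] else -fr * b[1])
        h <- disease_given_marker(par)
        g <- marker_given_disease(par)
        lhs <- sweep(h, 2, ldassoc:::hwe_probs(p), "*")
        rhs <- sweep(g, 1, ldassoc:::hwe_probs(q), "*")
        expect_equal(lhs, rhs, tolerance = 1e-12)
        expect_equal(unname(colSums(h)), c(1, 1, 1), tolerance = 1e-12)
      }
})

test_that("case_control_joint normalises and recomposes the population joint", {
  set.seed(7)
  for (i in 1:20) {
    par <- rand_params()
    f <- unclass(penetrance(sample(c("additive", "dominant", "recessive"), 1)))
    cc <- case_control_joint(par, f)
    expect_equal(sum(cc$case), 1, tolerance = 1e-12)
    expect_equal(sum(cc$control), 1, tolerance = 1e-12)
    expect_true(all(cc$case >= 0) && all(cc$control >= 0))
    # recomposition against the enumeration oracle
    expect_equal(cc$pi * cc$case + (1 - cc$pi) * cc$control,
                 enum_joint(par$p, par$q, par$D), tolerance = 1e-12)
  }
  # full penetrance: cases are the population, controls do not exist
  cc <- case_control_joint(pop_params(0.4, 0.3, 0.05), c(1, 1, 1))
  expect_equal(cc$case, enum_joint(0.4, 0.3, 0.05), tolerance = 1e-12)
  expect_null(cc$control)
  # recessive: case mass only in the AA row, proportional to g[1, ]
  par <- pop_params(0.5, 0.5, 0.1)
  cc <- case_control_joint(par, penetrance("recessive"))
  expect_equal(unname(cc$case[2:3, ]), matrix(0, 2, 3))
  expect_equal(unname(cc$case[1, ]),
               unname(marker_given_disease(par)[1, ]), tolerance = 1e-12)
})

test_that("case/control marker marginals at p = q = 0.5, D = 0.15, additive", {
  # frozen from the enumeration oracle (Jensen-checked against the trend
  # statistic of the corresponding simulated population)
  cc <- case_control_joint(pop_params(0.5, 0.5, 0.15), penetrance("additive"))
  expect_equal(unname(colSums(cc$case)), c(0.40, 0.50, 0.10),
               tolerance = 1e-12)
  expect_equal(unname(colSums(cc$control)), c(0.10, 0.50, 0.40),
               tolerance = 1e-12)
})

test_that("posterior weights normalise and agree with Bayes on the oracle", {
  # penetrance cancels when all genotypes are equally penetrant
  par <- pop_params(0.4, 0.25, 0.04)
  wv <- posterior_weights(par, c(1, 1, 1))
  expect_equal(wv$w, disease_given_marker(par), tolerance = 1e-12)
  # no LD: marker uninformative, all columns of w identical
  wv0 <- posterior_weights(pop_params(0.4, 0.25, 0), penetrance("additive"))
  expect_equal(wv0$w[, 1], wv0$w[, 2], tolerance = 1e-12)
  expect_equal(wv0$w[, 1], wv0$w[, 3], tolerance = 1e-12)
  # frozen value: p = q = 0.5, D = 0.15, additive; h[, MM] = (.64,.32,.04)
  wv <- posterior_weights(pop_params(0.5, 0.5, 0.15), penetrance("additive"))
  expect_equal(unname(wv$w[, "MM"]), c(0.8, 0.2, 0), tolerance = 1e-12)
  # Bayes oracle across random parameters: w = Pr(X | Y, case)
  set.seed(11)
  for (i in 1:20) {
    par <- rand_params()
    f <- unclass(penetrance("additive"))
    cc <- enum_cc_joint(par$p, par$q, par$D, f)
    wv <- posterior_weights(par, f)
    expect_equal(wv$w, sweep(cc$case, 2, colSums(cc$case), "/"),
                 tolerance = 1e-12)
    expect_equal(wv$v, sweep(cc$control, 2, colSums(cc$control), "/"),
                 tolerance = 1e-12)
    expect_equal(unname(colSums(wv$w)), c(1, 1, 1), tolerance = 1e-12)
    expect_equal(unname(colSums(wv$v)), c(1, 1, 1), tolerance = 1e-12)
  }
})

test_that("expected_delta_pM decomposes structure and LD terms", {
  pen <- penetrance("additive")
  # no structure, no LD
  pops <- list(pop_params(0.4, 0.3, 0), pop_params(0.4, 0.3, 0))
  expect_equal(expected_delta_pM(pops, pen, c(0.5, 0.5), c(0.5, 0.5)), 0)
  # pure structure term: Table-4-style allele frequencies and admixture
  pops <- list(pop_params(0.40, 0.10, 0), pop_params(0.70, 0.10, 0))
  expect_equal(
    expected_delta_pM(pops, pen, c(0.57, 0.43), c(0.76, 0.24)),
    0.057, tolerance = 1e-12)
  # single population: reduces to D * (q_case - q_control) / (q(1-q))
  par <- pop_params(0.5, 0.3, 0.06)
  f <- unclass(pen)
  pi_ <- prevalence(f, 0.3)
  q_case <- (f[1] * 0.09 + f[2] * 0.21) / pi_
  q_ctrl <- ((1 - f[1]) * 0.09 + (1 - f[2]) * 0.21) / (1 - pi_)
  expect_equal(expected_delta_pM(list(par), pen, 1, 1),
               unname(0.06 * (q_case - q_ctrl) / (0.3 * 0.7)),
               tolerance = 1e-12)
  # strictly increasing in D for a single additive population
  deltas <- vapply(seq(0, 0.24, by = 0.02), function(D)
    expected_delta_pM(list(pop_params(0.5, 0.5, D)), pen, 1, 1), numeric(1))
  expect_true(all(diff(deltas) > 0))
  expect_error(expected_delta_pM(pops, pen, c(0.6, 0.3), c(0.5, 0.5)),
               "sum to 1")
})

test_that("expected_delta_pM matches the simulated pooled difference", {
  # the structure-only expectation is also checked by Monte Carlo
  set.seed(99)
  pen <- penetrance("additive")
  pops <- list(pop_params(0.40, 0.10, 0), pop_params(0.70, 0.10, 0))
  dels <- replicate(400, {
    adm <- sample_admixed(pops, pen, c(0.57, 0.43), c(0.76, 0.24), 200, 200)
    n <- adm$pooled
    (2 * n[1, 1] + n[1, 2]) / (2 * sum(n[1, ])) -
      (2 * n[2, 1] + n[2, 2]) / (2 * sum(n[2, ]))
  })
  expect_lt(abs(mean(dels) - 0.057), 4 * sd(dels) / sqrt(400))
})

test_that("control_freq_bias follows the closed form and the 5% bound", {
  pen <- penetrance("additive")
  expect_equal(control_freq_bias(pop_params(0.3, 0.4, 0), pen)$bias, 0)
  # additive simplification p' = p - D / (2 (1 - q))
  set.seed(3)
  for (i in 1:20) {
    par <- rand_params()
    expect_equal(control_freq_bias(par, pen)$p_prime,
                 par$p - par$D / (2 * (1 - par$q)), tolerance = 1e-12)
  }
  # Under additive penetrance the bias is bounded by half the prevalence:
  # |p' - p| = |D| / (2 (1 - q)) <= min(p(1-q), (1-p)q) / (2(1-q)) <= q/2 =
  # pi/2, so prevalence <= 10% caps the bias at 0.05 even with D at its
  # feasibility bound.  For dominant and recessive penetrance the cap is
  # only approximate (worst cases ~0.051 and ~0.076 at p = q); the bound
  # asserted per mode is the analytically worst value.
  caps <- c(additive = 0.05, dominant = 0.0514, recessive = 0.077)
  for (mode in names(caps)) {
    f <- penetrance(mode)
    for (p in seq(0.05, 0.95, by = 0.05))
      for (q in seq(0.01, 0.99, by = 0.02)) {
        if (prevalence(f, q) > 0.10) next
        b <- ld_bounds(p, q)
        for (D in b)
          expect_lte(control_freq_bias(pop_params(p, q, D), f)$bias,
                     caps[[mode]] + 1e-12)
      }
  }
})
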