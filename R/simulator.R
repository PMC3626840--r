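# Case-control simulator under the two-locus model: individuals are drawn
# from the joint distribution of (disease genotype, marker genotype) given
# their case/control status, until the requested numbers of cases and
# controls are reached.  Replicated designs drive the power and
# type-I-error studies.

#' Draw one individual's genotypes given case/control status
#'
#' Samples a (disease genotype, marker genotype) pair from the joint
#' distribution of [case_control_joint()] matching `status`.  Uses R's
#' global random number generator; call `set.seed()` for reproducibility.
#'
#' @param params A [pop_params()] object.
#' @param pen A [penetrance()] object.
#' @param status `"case"` or `"control"`.
#' @return Integer vector `c(disease = i, marker = j)` with 1, 2, 3 =
#'   AA/MM, Aa/Mm, aa/mm.
#' @export
sample_individual <- function(params, pen, status = c("case", "control")) {
  status <- match.arg(status)
  joint <- case_control_joint(params, pen)[[status]]
  if (is.null(joint))
    stop(sprintf("prevalence is degenerate: no %ss exist", status))
  cell <- sample.int(9L, 1L, prob = as.vector(joint))
  c(disease = (cell - 1L) %% 3L + 1L, marker = (cell - 1L) %/% 3L + 1L)
}

#' Sample a case-control genotype count table
#'
#' Draws `n_case` cases and `n_control` controls from the status-specific
#' joint genotype distributions and aggregates the marker genotypes into a
#' 2x3 [genotype_counts()] table.  Totals are exact by construction.
#'
#' @param params A [pop_params()] object.
#' @param pen A [penetrance()] object.
#' @param n_case,n_control Numbers of cases and controls to draw.
#' @return A [genotype_counts()] table.
#' @export
sample_counts <- function(params, pen, n_case, n_control) {
  joint <- case_control_joint(params, pen)
  draw <- function(mat, n, arm) {
    if (n == 0) return(c(0, 0, 0))
    if (is.null(mat))
      stop(sprintf("prevalence is degenerate: no %ss exist", arm))
    cells <- stats::rmultinom(1, n, as.vector(mat))
    colSums(matrix(cells, 3, 3))  # collapse disease genotypes
  }
  genotype_counts(draw(joint$case, n_case, "case"),
                  draw(joint$control, n_control, "control"))
}

# Largest-remainder apportionment of n into round(n * props) integer
# targets that sum exactly to n.
largest_remainder <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Sample an admixed case-control table from several populations
#'
#' The number of cases (controls) contributed by each population is the
#' deterministic largest-remainder rounding of `n_case * r` (`n_control *
#' s`): the sampling proportions enter the stratified statistics as known
#' constants, so they are fixed rather than drawn multinomially.  Returns
#' both the pooled table (the naive analysis, blind to origin) and the
#' per-population tables (for the structure-aware methods).
#'
#' @param pops List of [pop_params()], one per population.
#' @param pens A single [penetrance()] shared by all populations, or a
#'   list, one per population.
#' @param r,s Case and control contribution proportions (each sums to 1).
#' @param n_case,n_control Total numbers of cases and controls.
#' @return List with `pooled` (a [genotype_counts()] table), `cohorts` (a
#'   list of `list(id, counts)`, usable wherever cohort lists are
#'   accepted) and `targets` (the per-population case/control counts).
#' @export
sample_admixed <- function(pops, pens, r, s, n_case, n_control) {
  if (inherits(pops, "pop_params")) pops <- list(pops)
  k <- length(pops)
  if (inherits(pens, "penetrance") || (is.numeric(pens) && length(pens) == 3L))
    pens <- rep(list(penetrance(pens)), k)
  if (length(pens) != k || length(r) != k || length(s) != k)
    stop("'pops', 'pens', 'r' and 's' must have one entry per population")
  if (abs(sum(r) - 1) > 1e-9 || abs(sum(s) - 1) > 1e-9)
    stop("'r' and 's' must each sum to 1")
  ncs <- largest_remainder(n_case, r)
  nts <- largest_remainder(n_control, s)
  if (any(ncs == 0 & nts == 0))
    stop("a population received neither cases nor controls after rounding")
  cohorts <- lapply(seq_len(k), function(i) {
    list(id = paste0("pop", i),
         counts = sample_counts(pops[[i]], pens[[i]], ncs[i], nts[i]))
  })
  pooled <- Reduce(`+`, lapply(cohorts, function(x) unclass(x$counts)))
  list(pooled = genotype_counts(pooled[1, ], pooled[2, ]),
       cohorts = cohorts,
       targets = cbind(case = ncs, control = nts))
}

#' Specify a replicated case-control simulation
#'
#' Bundles the generating populations, true and analysis penetrance, sample
#' sizes, optional admixture proportions, replicate count, significance
#' level and seed of a power / type-I-error study.  Defaults mirror the
#' reference simulation design: 200 cases, 200 controls, 1,000 replicates,
#' alpha 0.05.
#'
#' @param populations A [pop_params()] or list of them (one per
#'   population).
#' @param pen True generating penetrance (single object or per-population
#'   list).
#' @param analysis_pen Penetrance assumed by the likelihood analysis
#'   (default additive `(1, 1/2, 0)`; may differ from the truth).
#' @param n_case,n_control Sample sizes per replicate.
#' @param admixture `list(r = , s = )` case/control contribution
#'   proportions for pooled sampling of a single admixed sample.  With
#'   more than one population and `admixture = NULL`, each population
#'   instead contributes a full sample of `n_case` cases and `n_control`
#'   controls ("separate" sampling); the cohort-aware methods analyse the
#'   per-population samples jointly and the naive trend test pools them.
#' @param n_reps Number of replicates.
#' @param alpha Nominal significance level.
#' @param seed RNG seed; identical seed and design give identical results.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(populations, pen = penetrance("additive"),
                              analysis_pen = penetrance("additive"),
                              n_case = 200L, n_control = 200L,
                              admixture = NULL, n_reps = 1000L,
                              alpha = 0.05, seed = 1L) {
  if (inherits(populations, "pop_params")) populations <- list(populations)
  k <- length(populations)
  stopifnot(k >= 1L, n_case >= 1L, n_control >= 1L, n_reps >= 1L,
            alpha > 0, alpha < 1)
  if (!is.null(admixture)) {
    if (length(admixture$r) != k || length(admixture$s) != k ||
        abs(sum(admixture$r) - 1) > 1e-9 || abs(sum(admixture$s) - 1) > 1e-9)
      stop("admixture proportions must have one entry per population and sum to 1")
  }
  if (inherits(pen, "penetrance") || (is.numeric(pen) && length(pen) == 3L))
    pen <- rep(list(penetrance(pen)), k)
  structure(list(populations = populations, pen = pen,
                 analysis_pen = penetrance(analysis_pen),
                 n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 admixture = admixture, n_reps = as.integer(n_reps),
                 alpha = alpha, seed = as.integer(seed)),
            class = "simulation_design")
}

#' Run a replicated power / type-I-error study
#'
#' For each replicate, draws a case-control sample from the design (pooled
#' across populations when admixture is specified), runs each requested
#' method on that same sample (so method comparisons are paired), and
#' tabulates statistics, parameter estimates and rejections at the design's
#' alpha.  Methods: `"M1"` (likelihood-ratio test, per-cohort when
#' stratified), `"M2"` (structure-corrected trend), `"M3"` (Armitage trend
#' on the pooled table, additive scores), `"MH"` (Mantel-Haenszel).
#' Per-replicate failures are counted, not fatal; a failure rate above 1%
#' flags the summary.
#'
#' @param design A [simulation_design()].
#' @param methods Subset of `c("M1", "M2", "M3", "MH")`.
#' @param weights Trend scores for M3 (default additive).
#' @param p_analysis Marker allele frequency used by Method 1: `"true"`
#'   (default) analyses at the generating per-population `p`, matching the
#'   reference simulation studies; `"controls"` uses the control-based
#'   estimator, which is biased when the prevalence is appreciable (see
#'   [control_freq_bias()]).
#' @return An object of class `power_summary`: `summary` (one row per
#'   method: mean and sd of the statistic, empirical power in %),
#'   `estimates` (mean/sd of `q_hat`, `D_hat` from M1 single-cohort fits
#'   and of the control-based `p_hat`), `reps` (per-replicate statistics
#'   and p-values), `n_fail`, `flagged`.
#' @export
run_power_study <- function(design, methods = c("M1", "M3"),
                            weights = trend_weights("additive"),
                            p_analysis = c("true", "controls")) {
  stopifnot(inherits(design, "simulation_design"))
  methods <- match.arg(methods, c("M1", "M2", "M3", "MH"),
                       several.ok = TRUE)
  p_analysis <- match.arg(p_analysis)
  k <- length(design$populations)
  p_true <- vapply(design$populations, `[[`, numeric(1), "p")
  R <- design$n_reps
  stat <- matrix(NA_real_, R, length(methods),
                 dimnames = list(NULL, methods))
  pval <- stat
  qhat <- Dhat <- phat <- rep(NA_real_, R)
  n_fail <- 0L
  set.seed(design$seed)
  for (rep_i in seq_len(R)) {
    if (k == 1L) {
      pooled <- sample_counts(design$populations[[1]], design$pen[[1]],
                              design$n_case, design$n_control)
      cohorts <- list(list(id = "pop1", counts = pooled))
    } else if (is.null(design$admixture)) {
      # separate sampling: a full case-control sample from each population
      cohorts <- lapply(seq_len(k), function(i)
        list(id = paste0("pop", i),
             counts = sample_counts(design$populations[[i]],
                                    design$pen[[i]],
                                    design$n_case, design$n_control)))
      tot <- Reduce(`+`, lapply(cohorts, function(x) unclass(x$counts)))
      pooled <- genotype_counts(tot[1, ], tot[2, ])
    } else {
      adm <- sample_admixed(design$populations, design$pen,
                            design$admixture$r, design$admixture$s,
                            design$n_case, design$n_control)
      pooled <- adm$pooled
      cohorts <- adm$cohorts
    }
    phat[rep_i] <- estimate_p_from_controls(pooled)
    for (m in methods) {
      res <- tryCatch(switch(m,
        M1 = if (k == 1L) {
          if (p_analysis == "true")
            lr_test(pooled, pen = design$analysis_pen,
                    p_source = "external", p = p_true)
          else lr_test(pooled, pen = design$analysis_pen)
        } else {
          multi_cohort_lr_test(cohorts, pen = design$analysis_pen,
                               p = if (p_analysis == "true") p_true)
        },
        M2 = structure_corrected_trend(cohorts),
        M3 = armitage_trend(pooled, weights = weights),
        MH = mantel_haenszel(cohorts)),
        error = function(e) NULL)
      if (is.null(res)) { n_fail <- n_fail + 1L; next }
      stat[rep_i, m] <- res$statistic
      pval[rep_i, m] <- res$p_value
      if (m == "M1" && k == 1L) {
        qhat[rep_i] <- res$estimates$q_hat
        Dhat[rep_i] <- res$estimates$D_hat
      }
    }
  }
  summ <- data.frame(
    method = methods,
    mean_stat = colMeans(stat, na.rm = TRUE),
    sd_stat = apply(stat, 2, stats::sd, na.rm = TRUE),
    power_pct = 100 * colMeans(pval <= design$alpha, na.rm = TRUE),
    row.names = NULL)
  est <- data.frame(
    parameter = c("q_hat", "D_hat", "p_hat"),
    mean = c(mean(qhat, na.rm = TRUE), mean(Dhat, na.rm = TRUE),
             mean(phat, na.rm = TRUE)),
    sd = c(stats::sd(qhat, na.rm = TRUE), stats::sd(Dhat, na.rm = TRUE),
           stats::sd(phat, na.rm = TRUE)))
  structure(list(design = design, summary = summ, estimates = est,
                 reps = list(statistic = stat, p_value = pval,
                             q_hat = qhat, D_hat = Dhat, p_hat = phat),
                 n_fail = n_fail,
                 flagged = n_fail > 0.01 * R * length(methods)),
            class = "power_summary")
}

#' @export
print.power_summary <- function(x, digits = 3, ...) {
  d <- x$design
  cat(sprintf(
    "power study: %d population(s), %d cases + %d controls, %d replicates, alpha = %g\n",
    length(d$populations), d$n_case, d$n_control, d$n_reps, d$alpha))
  print(format(x$summary, digits = digits), row.names = FALSE)
  if (any(is.finite(x$estimates$mean))) {
    cat("parameter estimates:\n")
    print(format(x$estimates, digits = digits), row.names = FALSE)
  }
  if (x$n_fail > 0)
    cat(sprintf("failed method runs: %d%s\n", x$n_fail,
                if (x$flagged) " [> 1% - flagged]" else ""))
  invisible(x)
}
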