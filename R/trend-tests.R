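# Comparator statistics: the Armitage trend test (Method 3), its additive
# allelic form with a correction for departure from HWE, the
# structure-corrected trend test (Method 2) and the Mantel-Haenszel
# statistic.  All are 1-df chi-square tests built on marker allele (or
# genotype-score) frequency differences between cases and controls.

#' Per-genotype trend scores
#'
#' Scores `x = (x1, x2, x3)` for genotypes MM, Mm, mm.  Presets follow the
#' inheritance mode of the counted allele M: `"dominant"` (1, 1, 0),
#' `"recessive"` (1, 0, 0), `"additive"` (2, 1, 0).  The test statistic is
#' invariant to affine rescaling of the scores.
#'
#' @param x Preset name or numeric length-3 vector (not all equal).
#' @return Class `trend_weights` numeric vector.
#' @export
trend_weights <- function(x = c("additive", "dominant", "recessive")) {
  if (is.character(x)) {
    x <- switch(match.arg(x),
                dominant = c(1, 1, 0),
                recessive = c(1, 0, 0),
                additive = c(2, 1, 0))
  }
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)) ||
      diff(range(x)) == 0)
    stop("trend scores must be three finite numbers, not all equal")
  structure(as.numeric(x), names = c("MM", "Mm", "mm"),
            class = "trend_weights")
}

.not_testable <- function(method, df = 1L, cohort_count = 1L)
  new_assoc_result(method, 0, df, cohort_count = cohort_count,
                   testable = FALSE)

#' Armitage trend test (Method 3)
#'
#' The 1-df chi-square trend statistic
#' `Y^2 = n * (n * sum_j n1j xj - n1. * sum_j n.j xj)^2 /
#'        (n1. * n2. * (n * sum_j n.j xj^2 - (sum_j n.j xj)^2))`.
#' A monomorphic marker (zero pooled score variance) is reported as not
#' testable with statistic 0 and p-value 1 rather than `NaN`, so genome
#' scans never abort mid-chromosome.
#'
#' @param counts A [genotype_counts()] table.
#' @param weights A [trend_weights()] object or preset name (default
#'   additive, `(2, 1, 0)`).
#' @return An `assoc_result` with `method = "M3"`, `df = 1`.
#' @export
armitage_trend <- function(counts, weights = trend_weights("additive")) {
  counts <- as_genotype_counts(counts)
  x <- unclass(trend_weights(weights))
  n1j <- counts[1, ]; nj <- colSums(counts)
  n <- sum(nj); n1 <- sum(n1j); n2 <- n - n1
  if (n1 == 0 || n2 == 0) stop("both cases and controls are required")
  denom <- n1 * n2 * (n * sum(nj * x^2) - sum(nj * x)^2)
  if (denom <= 0) return(.not_testable("M3"))
  stat <- n * (n * sum(n1j * x) - n1 * sum(nj * x))^2 / denom
  new_assoc_result("M3", stat, 1L)
}

#' Armitage trend test, additive allelic form with HWE correction
#'
#' Algebraically identical to [armitage_trend()] with additive scores
#' `(2, 1, 0)`:
#' `Y^2 = (pM_case - pM_control)^2 /
#'        ((pM (1 - pM) + (pMM - pM^2)) * (1/(2 n1.) + 1/(2 n2.)))`,
#' where `pM` and `pMM` are the pooled allele and MM-genotype frequencies.
#' The term `pMM - pM^2` corrects the variance for departure from HWE in
#' the pooled sample (e.g. under population structure).
#'
#' @param counts A [genotype_counts()] table.
#' @return An `assoc_result` with `method = "M3"`, `df = 1`.
#' @export
armitage_additive_allelic <- function(counts) {
  counts <- as_genotype_counts(counts)
  n1 <- sum(counts[1, ]); n2 <- sum(counts[2, ]); n <- n1 + n2
  if (n1 == 0 || n2 == 0) stop("both cases and controls are required")
  pM <- (2 * counts[1, 1] + counts[1, 2] +
           2 * counts[2, 1] + counts[2, 2]) / (2 * n)
  pMM <- (counts[1, 1] + counts[2, 1]) / n
  p_case <- (2 * counts[1, 1] + counts[1, 2]) / (2 * n1)
  p_ctrl <- (2 * counts[2, 1] + counts[2, 2]) / (2 * n2)
  denom <- (pM * (1 - pM) + (pMM - pM^2)) * (1 / (2 * n1) + 1 / (2 * n2))
  if (denom <= 0) return(.not_testable("M3"))
  new_assoc_result("M3", (p_case - p_ctrl)^2 / denom, 1L)
}

# Pooled case-minus-control marker allele frequency difference across
# cohorts (allele counting on the pooled sample).
.pooled_delta_pM <- function(cohorts) {
  tot <- Reduce(`+`, lapply(cohorts, function(x) unclass(x$counts)))
  n1 <- sum(tot[1, ]); n2 <- sum(tot[2, ])
  (2 * tot[1, 1] + tot[1, 2]) / (2 * n1) -
    (2 * tot[2, 1] + tot[2, 2]) / (2 * n2)
}

#' Structure-corrected trend test (Method 2)
#'
#' Removes the population-structure term `sum_i (r_i - s_i) * pM_i` from
#' the pooled case-control allele frequency difference and standardises by
#' its null sampling variance:
#' `chi2_G = (delta_pM - sum_i (r_i - s_i) pM_i)^2 /
#'   sum_i 0.5 pM_i (1 - pM_i) (r_i^2/n_case_i + s_i^2/n_ctrl_i +
#'   (r_i - s_i)^2/n_i)`.
#' Case/control shares `r_i`, `s_i` and the per-cohort allele frequencies
#' `pM_i` (pooled cases + controls of cohort i, consistent with the null)
#' are computed from the counts.
#'
#' @param cohorts A list of [cohort_sample()] objects (or count tables).
#' @return An `assoc_result` with `method = "M2"`, `df = 1`.
#' @export
structure_corrected_trend <- function(cohorts) {
  cohorts <- as_cohort_list(cohorts)
  sh <- cohort_shares(cohorts)
  num <- .pooled_delta_pM(cohorts) - sum((sh$r - sh$s) * sh$pM)
  den <- sum(0.5 * sh$pM * (1 - sh$pM) *
               (sh$r^2 / sh$n_case + sh$s^2 / sh$n_control +
                  (sh$r - sh$s)^2 / sh$n))
  if (den <= 0) return(.not_testable("M2", cohort_count = length(cohorts)))
  new_assoc_result("M2", num^2 / den, 1L, cohort_count = length(cohorts))
}

#' Mantel-Haenszel test for stratified case-control samples
#'
#' Shares its numerator with [structure_corrected_trend()]; the variance is
#' the Mantel-Haenszel form
#' `sum_i 0.5 n^2 r_i s_i / n_i * pM_i (1 - pM_i) / (N_case * N_control)`,
#' where `N_case`, `N_control` and `n` are the totals over cohorts.  With a
#' single cohort it coincides with [structure_corrected_trend()].
#'
#' @param cohorts A list of [cohort_sample()] objects (or count tables).
#' @return An `assoc_result` with `method = "MH"`, `df = 1`.
#' @export
mantel_haenszel <- function(cohorts) {
  cohorts <- as_cohort_list(cohorts)
  sh <- cohort_shares(cohorts)
  Ncase <- sum(sh$n_case); Nctrl <- sum(sh$n_control)
  n <- Ncase + Nctrl
  num <- .pooled_delta_pM(cohorts) - sum((sh$r - sh$s) * sh$pM)
  den <- sum(0.5 * n^2 * sh$r * sh$s / sh$n * sh$pM * (1 - sh$pM)) /
    (Ncase * Nctrl)
  if (den <= 0) return(.not_testable("MH", cohort_count = length(cohorts)))
  new_assoc_result("MH", num^2 / den, 1L, cohort_count = length(cohorts))
}
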