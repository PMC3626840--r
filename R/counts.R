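#' Case-control genotype count table
#'
#' The observed data for one SNP: a 2x3 table of genotype counts,
#' `n[1, ] = (n11, n12, n13)` for cases and `n[2, ] = (n21, n22, n23)` for
#' controls, with columns MM, Mm, mm (M the counted marker allele).
#'
#' @param case,control Length-3 non-negative integer vectors of counts for
#'   genotypes MM, Mm, mm.
#' @return An object of class `genotype_counts` (2x3 integer matrix).
#' @examples
#' genotype_counts(c(30, 50, 20), c(20, 50, 30))
#' @export
genotype_counts <- function(case, control) {
  n <- rbind(case = as.numeric(case), control = as.numeric(control))
  if (ncol(n) != 3L || any(!is.finite(n)) || any(n < 0) ||
      any(abs(n - round(n)) > 1e-8))
    stop("counts must be two length-3 vectors of non-negative integers")
  n <- round(n)
  colnames(n) <- c("MM", "Mm", "mm")
  structure(n, class = c("genotype_counts", "matrix"))
}

as_genotype_counts <- function(x) {
  if (inherits(x, "genotype_counts")) return(x)
  if (is.matrix(x) && all(dim(x) == c(2L, 3L)))
    return(genotype_counts(x[1, ], x[2, ]))
  if (is.numeric(x) && length(x) == 6L)  # (n11, n12, n13, n21, n22, n23)
    return(genotype_counts(x[1:3], x[4:6]))
  stop("cannot interpret 'counts' as a 2x3 case-control genotype table")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat("case-control genotype counts (", sum(x), " individuals)\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Marker allele frequency estimated from controls
#'
#' `p_hat = (n21 + 0.5 * n22) / n2.` where `n2.` is the number of controls.
#' Controls approximate a random population sample with respect to the
#' marker when the disease prevalence is low.
#'
#' @param counts A [genotype_counts()] table.
#' @return Estimated frequency of allele M, in [0, 1].
#' @export
estimate_p_from_controls <- function(counts) {
  counts <- as_genotype_counts(counts)
  n2 <- sum(counts[2, ])
  if (n2 == 0)
    stop("no controls: supply an externally estimated marker allele frequency")
  (counts[2, 1] + 0.5 * counts[2, 2]) / n2
}

#' Maximum-likelihood marker allele frequency under no LD
#'
#' Under `D = 0` cases and controls are exchangeable with respect to the
#' marker and the MLE of `p` is the pooled allele-count estimator
#' `(2*n11 + 2*n21 + n12 + n22) / (2n)`.
#'
#' @param counts A [genotype_counts()] table.
#' @return Pooled allele frequency estimate.
#' @export
null_mle_p <- function(counts) {
  counts <- as_genotype_counts(counts)
  n <- sum(counts)
  if (n == 0) stop("empty count table")
  (2 * counts[1, 1] + 2 * counts[2, 1] + counts[1, 2] + counts[2, 2]) / (2 * n)
}

#' One cohort's contribution to a stratified analysis
#'
#' Wraps a [genotype_counts()] table with a cohort label.  Case/control
#' shares (`r_i`, `s_i`) are always derived from the counts by the
#' stratified tests, never supplied by the user.
#'
#' @param counts A [genotype_counts()] table.
#' @param id Cohort label.
#' @return An object of class `cohort_sample`.
#' @export
cohort_sample <- function(counts, id = "cohort1") {
  counts <- as_genotype_counts(counts)
  if (sum(counts[1, ]) == 0 || sum(counts[2, ]) == 0)
    stop(sprintf("cohort '%s' needs at least one case and one control", id))
  structure(list(id = as.character(id), counts = counts),
            class = "cohort_sample")
}

as_cohort_list <- function(cohorts) {
  if (inherits(cohorts, "cohort_sample")) return(list(cohorts))
  if (inherits(cohorts, "genotype_counts") || is.matrix(cohorts) ||
      (is.numeric(cohorts) && length(cohorts) == 6L))
    return(list(cohort_sample(as_genotype_counts(cohorts))))
  lapply(seq_along(cohorts), function(i) {
    x <- cohorts[[i]]
    if (inherits(x, "cohort_sample")) x
    else if (is.list(x) && !is.null(x$counts))
      cohort_sample(x$counts,
                    id = if (is.null(x$id)) paste0("cohort", i) else x$id)
    else cohort_sample(as_genotype_counts(x), id = paste0("cohort", i))
  })
}

# Shares and per-cohort summaries used by the stratified statistics.
cohort_shares <- function(cohorts) {
  cases <- vapply(cohorts, function(x) sum(x$counts[1, ]), numeric(1))
  ctrls <- vapply(cohorts, function(x) sum(x$counts[2, ]), numeric(1))
  pM <- vapply(cohorts, function(x) {
    n <- x$counts
    (2 * (n[1, 1] + n[2, 1]) + n[1, 2] + n[2, 2]) / (2 * sum(n))
  }, numeric(1))
  list(r = cases / sum(cases), s = ctrls / sum(ctrls),
       n_case = cases, n_control = ctrls, n = cases + ctrls, pM = pM)
}
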