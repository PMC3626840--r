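# File I/O, QC filtering, per-SNP scans, Bonferroni thresholds and
# bootstrap posterior probabilities.
#
# Two plain-text input formats are supported:
#  * a genotype matrix TSV: sample_id, status (case|control), cohort, then
#    one column per SNP coded 0/1/2 = copies of allele M (NA = missing);
#  * a counts TSV: snp_id, cohort, n11, n12, n13, n21, n22, n23 (cases then
#    controls, genotypes MM/Mm/mm).

new_scan_dataset <- function(snps, cohort_ids, provenance = list()) {
  stopifnot(!anyDuplicated(names(snps)))
  structure(list(snps = snps, cohort_ids = cohort_ids,
                 provenance = provenance), class = "scan_dataset")
}

#' @export
print.scan_dataset <- function(x, ...) {
  cat(sprintf("scan_dataset: %d SNP(s), %d cohort(s) [%s]\n",
              length(x$snps), length(x$cohort_ids),
              paste(x$cohort_ids, collapse = ", ")))
  invisible(x)
}

#' Read a 0/1/2 genotype matrix and aggregate it to count tables
#'
#' Expects a TSV with columns `sample_id`, `status` (`case`/`control`),
#' `cohort`, then one column per SNP with 0/1/2 = copies of allele M and
#' `NA` for missing.  Genotypes are aggregated to per-SNP, per-cohort 2x3
#' count tables; per-SNP call rates are recorded for QC.
#'
#' @param path Path to the TSV file.
#' @return A `scan_dataset`: per SNP a list of per-cohort
#'   [genotype_counts()] plus `call_rate`.
#' @export
read_genotype_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""))
  need <- c("sample_id", "status", "cohort")
  if (!all(need %in% names(dt)))
    stop("genotype matrix needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(dt$status), c("case", "control"))
  if (length(bad))
    stop("unknown status value(s): ", paste(bad, collapse = ", "))
  snp_cols <- setdiff(names(dt), need)
  if (!length(snp_cols)) stop("no SNP columns found")
  cohort_ids <- sort(unique(as.character(dt$cohort)))
  is_case <- dt$status == "case"
  snps <- lapply(snp_cols, function(snp) {
    g <- dt[[snp]]
    if (!all(g %in% c(0, 1, 2) | is.na(g))) {
      row <- which(!(g %in% c(0, 1, 2) | is.na(g)))[1]
      stop(sprintf("invalid genotype code at row %d, column '%s' (must be 0/1/2/NA)",
                   row, snp))
    }
    per_cohort <- lapply(cohort_ids, function(co) {
      inco <- dt$cohort == co & !is.na(g)
      cnt <- function(arm) c(sum(g[inco & arm] == 2), sum(g[inco & arm] == 1),
                             sum(g[inco & arm] == 0))
      genotype_counts(cnt(is_case), cnt(!is_case))
    })
    names(per_cohort) <- cohort_ids
    list(cohorts = per_cohort, call_rate = mean(!is.na(g)))
  })
  names(snps) <- snp_cols
  new_scan_dataset(snps, cohort_ids,
                   list(source = path, n_samples = nrow(dt)))
}

#' Read a per-SNP count table TSV
#'
#' Columns: `snp_id`, `cohort`, `n11`, `n12`, `n13` (case MM/Mm/mm),
#' `n21`, `n22`, `n23` (control MM/Mm/mm); one row per SNP x cohort.
#'
#' @param path Path to the TSV file.
#' @return A `scan_dataset` (call rates set to 1, genotype-level
#'   missingness being unknown).
#' @export
read_counts_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("snp_id", "cohort", "n11", "n12", "n13", "n21", "n22", "n23")
  if (!all(need %in% names(dt)))
    stop("counts file needs columns: ", paste(need, collapse = ", "))
  cohort_ids <- sort(unique(as.character(dt$cohort)))
  ids <- unique(as.character(dt$snp_id))
  snps <- lapply(ids, function(id) {
    rows <- dt[dt$snp_id == id, ]
    per_cohort <- lapply(cohort_ids, function(co) {
      r <- rows[rows$cohort == co, ]
      if (nrow(r) == 0) genotype_counts(c(0, 0, 0), c(0, 0, 0))
      else genotype_counts(c(r$n11[1], r$n12[1], r$n13[1]),
                           c(r$n21[1], r$n22[1], r$n23[1]))
    })
    names(per_cohort) <- cohort_ids
    list(cohorts = per_cohort, call_rate = 1)
  })
  names(snps) <- ids
  new_scan_dataset(snps, cohort_ids, list(source = path))
}

pooled_counts <- function(snp)
  genotype_counts(Reduce(`+`, lapply(snp$cohorts, function(x) x[1, ])),
                  Reduce(`+`, lapply(snp$cohorts, function(x) x[2, ])))

#' QC thresholds
#'
#' Defaults: call rate >= 0.95, minor allele frequency >= 0.05, no
#' departure from HWE in pooled controls at p > 0.01, and at least 5
#' individuals per genotype class within each of the (pooled) case and
#' control arms.
#'
#' @param min_call_rate,min_maf,hwe_alpha,min_genotype_count Thresholds.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, min_maf = 0.05,
                          hwe_alpha = 0.01, min_genotype_count = 5) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 0.5,
            hwe_alpha > 0, hwe_alpha < 1, min_genotype_count >= 0)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_alpha = hwe_alpha,
                 min_genotype_count = min_genotype_count),
            class = "qc_thresholds")
}

#' Chi-square test for Hardy-Weinberg equilibrium
#'
#' 1-df goodness-of-fit of genotype counts `(nMM, nMm, nmm)` against HWE
#' proportions at the sample allele frequency.
#'
#' @param counts Length-3 vector of genotype counts.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
hwe_test <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(counts < 0)) stop("need 3 genotype counts")
  n <- sum(counts)
  if (n == 0) stop("empty genotype table")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  e <- n * hwe_probs(p)
  if (p == 0 || p == 1)
    return(list(statistic = 0, df = 1L, p_value = 1))
  stat <- sum((counts - e)^2 / e)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

#' Filter SNPs on call rate, MAF, HWE and minimum genotype counts
#'
#' Applies, in order: call rate; pooled minor allele frequency; HWE
#' chi-square in pooled controls (dropped when `p <= hwe_alpha`); and the
#' minimum-count rule (every genotype class needs at least
#' `min_genotype_count` individuals within the pooled case arm and within
#' the pooled control arm).  Each dropped SNP carries its first failing
#' reason.
#'
#' @param dataset A `scan_dataset`.
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `kept` (a filtered `scan_dataset`) and `dropped` (a
#'   data frame of `snp_id`, `reason`).
#' @export
qc_filter <- function(dataset, thresholds = qc_thresholds()) {
  stopifnot(inherits(dataset, "scan_dataset"),
            inherits(thresholds, "qc_thresholds"))
  reason <- vapply(dataset$snps, function(snp) {
    if (snp$call_rate < thresholds$min_call_rate) return("call_rate")
    pooled <- pooled_counts(snp)
    n <- sum(pooled)
    if (n == 0) return("call_rate")
    pM <- (2 * sum(pooled[, 1]) + sum(pooled[, 2])) / (2 * n)
    if (min(pM, 1 - pM) < thresholds$min_maf) return("maf")
    if (hwe_test(pooled[2, ])$p_value <= thresholds$hwe_alpha) return("hwe")
    if (any(pooled < thresholds$min_genotype_count))
      return("min_genotype_count")
    NA_character_
  }, character(1))
  drop <- !is.na(reason)
  list(kept = new_scan_dataset(dataset$snps[!drop], dataset$cohort_ids,
                               dataset$provenance),
       dropped = data.frame(snp_id = names(dataset$snps)[drop],
                            reason = reason[drop], row.names = NULL))
}

.run_method <- function(m, snp, pen) {
  cohorts <- Filter(function(x) sum(x[1, ]) > 0 || sum(x[2, ]) > 0,
                    snp$cohorts)
  cohort_list <- lapply(names(cohorts), function(id)
    cohort_sample(cohorts[[id]], id = id))
  switch(m,
         M1 = multi_cohort_lr_test(cohort_list, pen = pen),
         M2 = structure_corrected_trend(cohort_list),
         M3 = armitage_trend(pooled_counts(snp)),
         MH = mantel_haenszel(cohort_list))
}

#' Per-SNP association scan across methods
#'
#' Runs the requested methods on every SNP.  The likelihood-ratio test,
#' the structure-corrected trend test and the Mantel-Haenszel test consume
#' the per-cohort tables; the Armitage trend test runs on pooled counts
#' (the naive analysis).  Significance is declared at the Bonferroni
#' threshold `alpha / M`, with `M` the number of scanned SNPs.
#' Per-SNP failures are recorded in the `error` column and the scan
#' continues.
#'
#' @param dataset A `scan_dataset` (apply [qc_filter()] first).
#' @param methods Subset of `c("M1", "M2", "M3", "MH")`.
#' @param pen A [penetrance()] object or preset name (Method 1).
#' @param alpha Family-wise error rate for the Bonferroni correction.
#' @return A data frame of class `scan_result`, one row per SNP x method:
#'   `snp_id`, `method`, `statistic`, `df`, `p_value`, `significant`,
#'   `q_hat`, `D_hat` (single-cohort M1 fits only), `error`; the
#'   per-test threshold is attached as attribute `threshold`.
#' @export
ld_scan <- function(dataset, methods = c("M1", "M2", "M3", "MH"),
                    pen = penetrance("additive"), alpha = 0.05) {
  stopifnot(inherits(dataset, "scan_dataset"))
  methods <- match.arg(methods, c("M1", "M2", "M3", "MH"), several.ok = TRUE)
  M <- length(dataset$snps)
  if (M == 0) {
    out <- data.frame(snp_id = character(), method = character(),
                      statistic = numeric(), df = integer(),
                      p_value = numeric(), significant = logical(),
                      q_hat = numeric(), D_hat = numeric(),
                      error = character())
    attr(out, "threshold") <- numeric(0)
    class(out) <- c("scan_result", class(out))
    return(out)
  }
  threshold <- alpha / M
  rows <- vector("list", M * length(methods))
  idx <- 0L
  for (id in names(dataset$snps)) {
    snp <- dataset$snps[[id]]
    for (m in methods) {
      idx <- idx + 1L
      res <- tryCatch(.run_method(m, snp, pen), error = identity)
      if (inherits(res, "error")) {
        rows[[idx]] <- data.frame(
          snp_id = id, method = m, statistic = NA_real_, df = NA_integer_,
          p_value = NA_real_, significant = NA, q_hat = NA_real_,
          D_hat = NA_real_, error = conditionMessage(res))
      } else {
        est <- res$estimates
        single <- m == "M1" && res$cohort_count == 1L
        rows[[idx]] <- data.frame(
          snp_id = id, method = m, statistic = res$statistic,
          df = res$df, p_value = res$p_value,
          significant = res$p_value <= threshold,
          q_hat = if (single) est[[1]]$q_hat else NA_real_,
          D_hat = if (single) est[[1]]$D_hat else NA_real_,
          error = NA_character_)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  class(out) <- c("scan_result", class(out))
  out
}

#' Bootstrap posterior probability of detection
#'
#' Resamples individuals with replacement within each cohort x case/control
#' stratum (multinomial resampling of the count table, preserving stratum
#' sizes exactly), recomputes the chosen method's p-value, and returns the
#' percentage of resamples in which the SNP is detected at the given
#' threshold.
#'
#' @param dataset A `scan_dataset`.
#' @param snp SNP identifier.
#' @param method One of `"M1"`, `"M2"`, `"M3"`, `"MH"`.
#' @param threshold Detection p-value threshold (e.g. the Bonferroni
#'   threshold of the original scan).
#' @param B Number of bootstrap replicates (default 1000).
#' @param pen A [penetrance()] object or preset name (Method 1).
#' @param seed Optional RNG seed.
#' @return Bootstrap posterior probability in percent.
#' @export
bootstrap_bpp <- function(dataset, snp, method = "M1", threshold,
                          B = 1000L, pen = penetrance("additive"),
                          seed = NULL) {
  stopifnot(inherits(dataset, "scan_dataset"))
  if (B < 1) stop("'B' must be at least 1")
  if (!snp %in% names(dataset$snps)) stop("unknown SNP: ", snp)
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  obs <- dataset$snps[[snp]]
  hits <- 0L
  for (b in seq_len(B)) {
    boot <- obs
    boot$cohorts <- lapply(obs$cohorts, function(tab) {
      resample_arm <- function(row) {
        n <- sum(row)
        if (n == 0) return(c(0, 0, 0))
        as.vector(stats::rmultinom(1, n, row / n))
      }
      genotype_counts(resample_arm(tab[1, ]), resample_arm(tab[2, ]))
    })
    res <- tryCatch(.run_method(method, boot, pen), error = identity)
    if (!inherits(res, "error") && res$p_value <= threshold)
      hits <- hits + 1L
  }
  100 * hits / B
}

#' Write scan results / count tables as TSV
#'
#' Tab-separated with a header row; p-values in scientific notation with 4
#' significant digits (e.g. `1.118e-07`).  Column order is as documented
#' in [ld_scan()] and [read_counts_tsv()] respectively.
#'
#' @param results A `scan_result` data frame.
#' @param dataset A `scan_dataset`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  out <- as.data.frame(results)
  out$p_value <- ifelse(is.na(out$p_value), NA, sprintf("%.3e", out$p_value))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_results_tsv
#' @export
write_counts_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "scan_dataset"))
  rows <- list(); idx <- 0L
  for (id in names(dataset$snps)) {
    for (co in names(dataset$snps[[id]]$cohorts)) {
      n <- dataset$snps[[id]]$cohorts[[co]]
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        snp_id = id, cohort = co,
        n11 = n[1, 1], n12 = n[1, 2], n13 = n[1, 3],
        n21 = n[2, 1], n22 = n[2, 2], n23 = n[2, 3])
    }
  }
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t", quote = FALSE)
  invisible(path)
}
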