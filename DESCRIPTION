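Package: ldassoc
Title: Likelihood-Based Linkage-Disequilibrium Association Tests for
    Case-Control Samples
Version: 0.1.0
Authors@R:
    person("ldassoc", "maintainers", email = "ldassoc@example.org",
           role = c("aut", "cre"))
Description: Estimates the coefficient of linkage disequilibrium (D) between
    a genotyped marker and a putative disease locus, together with the
    disease-allele frequency (q), from 2x3 case-control genotype count
    tables under an explicit population-genetic model with fixed penetrance.
    Estimation treats the unobserved disease genotypes as missing data and
    maximises the likelihood by an EM algorithm; association is tested by a
    2-df likelihood-ratio test that extends additively to multiple cohorts
    (2k df) and is thereby robust to known population structure.  Comparator
    statistics (Armitage trend test, a structure-corrected trend test, and
    the Mantel-Haenszel test), a case-control simulator for power and
    type-I-error studies, QC filtering, genome-scan drivers, bootstrap
    posterior probabilities and a command-line interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
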