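---
title: "Likelihood-based LD association testing from case-control samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-based LD association testing from case-control samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldassoc)
```

## The model

A genotyped biallelic marker (alleles $M/m$, frequency $p$ of $M$) and an
unobserved biallelic disease locus (alleles $A/a$, frequency $q$ of the
risk allele $A$) segregate in a randomly mating population.  Their
association is measured by the linkage-disequilibrium coefficient
$D = \Pr(MA) - pq$, feasible on
$\max\{-pq,\,-(1-p)(1-q)\} \le D \le \min\{p(1-q),\,(1-p)q\}$.

Under random union of haplotypes, the marker genotype given the disease
genotype is a binomial in the haplotype-conditional frequencies
$Q = p + D/q$ (frequency of $M$ on $A$-haplotypes) and
$R = p - D/(1-q)$ ($M$ on $a$-haplotypes); `marker_given_disease()`
returns this 3×3 table $g_{ij}$ and `disease_given_marker()` its Bayes
counterpart $h_{ij}$, built from $Q' = q + D/p$ and $R' = q - D/(1-p)$.
Disease risk enters through a fixed penetrance triplet
$f = (f_1, f_2, f_3)$ for genotypes $AA/Aa/aa$ — presets dominant
$(1,1,0)$, additive $(1,\tfrac12,0)$, recessive $(1,0,0)$ — with locus
prevalence $\pi = f_1 q^2 + 2 f_2 q(1-q) + f_3 (1-q)^2$.  Cases and
controls reweight the joint genotype distribution by $f_i/\pi$ and
$(1-f_i)/(1-\pi)$ (`case_control_joint()`).

## Method 1: EM estimation of (q, D) and the LR test

The data for one SNP are the 2×3 case/control × $MM/Mm/mm$ counts
$N = (n_{11},\dots,n_{23})$.  The disease genotypes are latent, so the
fit alternates:

* **E-step** — posterior weights of the disease genotypes given marker
  genotype and status, $w_{ij} \propto f_i h_{ij}$ (cases),
  $v_{ij} \propto (1-f_i) h_{ij}$ (controls) (`posterior_weights()`);
* **M-step** — maximisation of the weighted objective
  $\sum_{ij} (n_{1j} w_{ij} + n_{2j} v_{ij}) \log g_{ij}(q, D)$
  (`expected_loglik()`) over the feasible region.

The marker allele frequency $p$ is held fixed: jointly estimating all
three parameters is not identifiable from a single 2×3 table.  For real
data $p$ is estimated from controls (`estimate_p_from_controls()`),
which is adequate for low-prevalence diseases: the bias of that
estimator is $D\{(f_2-f_1)q + (f_3-f_2)(1-q)\}/(1-\pi)$
(`control_freq_bias()`), which under the additive model is bounded by
$\pi/2$ — at most 0.05 when $\pi \le 10\%$, even with $D$ at its
feasibility bound.  (The same 0.05 cap is only approximate for the
dominant preset, worst case ≈ 0.051, and fails for the recessive preset,
worst case ≈ 0.076 at $p = q \approx 0.32$; the property tests assert
the per-mode analytical caps.)  For simulated data with appreciable
$\pi$ the control-based estimate is badly biased — the simulation
drivers therefore analyse at the generating $p$ by default
(`run_power_study(p_analysis = "true")`).

The association statistic (`lr_test()`) is
$\mathrm{LR} = 2\{L(\hat p, \hat q, \hat D) - L(\hat p, q, D{=}0)\}$
with the same $\hat p$ in both terms; under $D = 0$ the likelihood
collapses to the Hardy–Weinberg multinomial on the pooled sample
(`null_loglik()`), independent of $q$.  The statistic is referred to
$\chi^2_2$; across $k$ cohorts the per-cohort statistics add and the
reference distribution is $\chi^2_{2k}$ (`multi_cohort_lr_test()`),
which is what makes the method robust to known population structure:
each cohort contributes its own $(p, q, D)$.

### Numerical design

The M-step works in the $(Q, R)$ parametrisation, where the objective is
a sum of logarithms of functions *affine* in each coordinate — concave
per coordinate, with a quadratic score equation solved in closed form;
among its roots the feasible one with the highest objective is kept, on
both sign branches of $D$ ($R \le p \le Q$ and $Q \le p \le R$), with a
coarse diagonal scan guarding the coordinate-ascent corner trap at
$Q = R = p$.  Iteration stops when the objective changes by less than
`tol` (default $10^{-8}$); rare oscillating trajectories are damped
(step-halving towards the incumbent, triggered by period-2 or
no-net-progress detection).  Six starting points
($q_0 \in \{0.25, 0.5, 0.75\}$, $D_0 = \pm\,0.25\,D_{\max}$) keep the
start set symmetric under allele relabelling, which maps
$D \mapsto -D$.

Two safeguards implement the admissibility rule $0 < q < 1$:

* the EM map possesses a *spurious* fixed point with all latent mass on
  one disease genotype ($q$ at the edge), where the M-step simply refits
  the marker frequency; its objective equals the pooled Hardy–Weinberg
  fit `null_loglik(null_mle_p(N))` exactly.  Edge-$q$ solutions that do
  not exceed that benchmark are discarded.  Genuine edge fits — e.g.
  small $\hat q$ under strongly mis-specified penetrance — far exceed it
  and are kept;
* $D = 0$ is always an admissible candidate, so the reported objective
  is never below the null value and the LR statistic is non-negative by
  construction.

The compiled engine (`src/em_fit.cpp`) and the reference R engine
(`engine = "R"`) implement the identical algorithm and are cross-checked
on random tables in the test suite.  A typical fit takes ~2–5 ms.

### Properties and limitations

The statistic is *not* a marginal-likelihood ratio: the weighted
objective omits the latent-genotype prior and ascertainment terms, and
its value at the fixed point exceeds the marginal LR under the
alternative (that gap is the source of the method's extra power over the
trend test, and of its mildly anti-conservative type-I error — about
7–9% at a nominal 5% with 200 cases and 200 controls, matching the
reference simulations).  Because the gap grows with $n$, genome scans at
very large sample sizes should expect further inflation; the per-SNP
p-values are best treated as a ranking device under Bonferroni control.
The trace of the fixed-point iteration is not monotone in general — a
start above the fixed point legitimately descends towards it — so the
tests assert convergence, feasibility and the null floor rather than
monotone ascent.

## Methods 2, 3 and Mantel–Haenszel

With cohorts indexed by $i$ contributing case/control shares
$r_i, s_i$, the expected pooled case-control difference in marker allele
frequency decomposes (`expected_delta_pM()`) into a structure term
$\sum_i (r_i - s_i) p_i$ — non-zero without any LD whenever allele
frequencies differ across cohorts — plus an LD term.  The comparators
are:

* `armitage_trend()` (Method 3): the 1-df trend test with scores
  $x = (2,1,0)$ by default; algebraically identical to the allelic form
  with Wahlund variance correction
  (`armitage_additive_allelic()`), as the identity test asserts;
* `structure_corrected_trend()` (Method 2): subtracts the structure term
  from the pooled difference and standardises by its null variance
  $\sum_i \tfrac12 p_i(1-p_i)\{r_i^2/n^{case}_i + s_i^2/n^{ctrl}_i +
  (r_i-s_i)^2/n_i\}$;
* `mantel_haenszel()`: same numerator, variance
  $\sum_i \tfrac12 n^2 r_i s_i / n_i \, p_i(1-p_i) / (N^{case} N^{ctrl})$.
  The printed form of that variance is typographically ambiguous; the
  parse adopted is the unique one that makes the two stratified
  statistics coincide for $k = 1$, which the tests verify.  Per-cohort
  allele frequencies are estimated from that cohort's pooled cases and
  controls, consistent with the null under which the variance is
  derived.

Monomorphic markers yield a "not testable" result (statistic 0, p-value
1, explicit flag) instead of `NaN`, so scans never abort.

## The simulator and what a green test establishes

`sample_counts()` draws individuals from the status-conditional joint of
`case_control_joint()` until the requested numbers of cases and controls
are reached — the generator *is* the analysis model, with no
genotyping error, missingness, relatedness or multi-locus structure.
Green acceptance tests therefore establish internal consistency of
estimator and simulator at the reference designs, not robustness to real
data pathologies.  Defaults mirror the reference studies: 200 cases, 200
controls, 1,000 replicates, additive penetrance.  Multi-population
designs either draw one pooled sample with fixed largest-remainder
origin counts (`sample_admixed()`; origin shares enter the stratified
statistics as known constants, so they are not randomised) or, with
`admixture = NULL`, a full sample per population analysed jointly.

Two reporting conventions were reverse-engineered from the internal
consistency of the reference tables and are used by the acceptance
machinery (`scripts/acceptance.R`):

* *type-I error* rows are rejection rates at $\alpha = 0.05$;
* *power* rows are rejection rates at $p \le 0.05/1000 = 5\times10^{-5}$
  (a Bonferroni correction over the 1,000 replicates): the printed
  powers agree with noncentral-$\chi^2$ theory at that threshold nearly
  cell-by-cell, and are irreconcilable with $\alpha = 0.05$ (a 1-df
  statistic with mean 8.8 cannot reject only 10.8% of the time at the
  5% level);
* the two-population "admixed" likelihood analysis is the joint 2k-df
  test of the per-population full samples (its printed power can exceed
  the weaker cohort's share-limited power only under that reading),
  while the naive pooled trend test consumes the 57%/76% admixed draw.

## QC, scanning and the bootstrap

`qc_filter()` applies, in order: call rate ≥ 0.95, pooled MAF ≥ 0.05,
HWE in pooled controls at $p > 0.01$ (chi-square, 1 df; controls only,
because cases deviate under genuine association), and at least 5
individuals per genotype class within each arm — the strictest reading
of the minimum-count rule.  `ld_scan()` runs the chosen methods per SNP
(cohort-aware methods on per-cohort tables, the trend test pooled) with
Bonferroni significance at $\alpha/M$, $M$ the number of scanned SNPs.
`bootstrap_bpp()` resamples the count tables multinomially within each
cohort × arm stratum — equivalent to resampling individuals while
preserving stratum sizes — and reports the percentage of replicates in
which the SNP stays below a fixed threshold.

## Open choices made here

* Table-of-conditional-probabilities normalisation: the case/control
  joint is taken as $f_i \Pr(X{=}i) g_{ij}/\pi$ (and its control
  counterpart), the unique normalisation consistent with the posterior
  weights.
* Degrees of freedom are fixed at $2k$ although $q$ is unidentified
  under the null; this is the method's stated calibration and the null
  simulations support it empirically at the reference sample sizes.
* Counts TSV and 0/1/2 genotype-matrix TSV are the only input formats;
  VCF/PLINK ingestion is out of scope.
* All randomised commands take a seed; identical seed and design give
  bit-identical results.
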