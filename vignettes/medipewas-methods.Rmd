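---
title: "Methods: twin-based MeDIP-seq EWAS of pain sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-based MeDIP-seq EWAS of pain sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipewas)
library(dplyr)
```

## The design medipewas implements

medipewas implements a two-cohort epigenome-wide association design for a
quantitative trait measured together with MeDIP-seq DNA methylation in whole
blood. The motivating setting is heat-pain sensitivity: a discovery cohort of
25 monozygotic (MZ) twin pairs selected to be discordant by at least 2 °C in
heat pain suprathreshold (HPST), and a second cohort of 50 unrelated
individuals with an unselected HPST distribution. Because MZ co-twins share
genotype, age and much early environment, within-pair contrasts isolate
non-genetic methylation–trait covariation, while the unrelated cohort
contributes an independent replication arm; the two are combined by
fixed-effect meta-analysis and judged against a permutation null.

Everything runs at desk scale on synthetic cohorts produced by the package's
own generator, so every stage — quantification, the two EWAS models,
permutation FDR, meta-analysis, and the follow-up analyses — is exercised and
tested end to end.

## Methylation quantification (RMQ)

Aligned MeDIP fragments (or single-end reads extended by 175 bp in the 3'
direction, giving 225-bp fragments for 50-bp reads) are reduced to per-base
coverage and summed in 1-kb bins that overlap by 500 bp, tiled from position
0 of each chromosome with 0-based half-open coordinates. The
**relative methylation quantification (RMQ)** score of a bin is

\[ \mathrm{RMQ}_{bs} \;=\; \frac{\sum_{\text{bp} \in b} \text{coverage}_s(\text{bp})}{N_s} \times 10^6, \]

where \(N_s\) is the sample's total autosomal post-QC read count. The
\(10^6\) constant is a reads-per-million-style convenience; every
association statistic downstream is invariant to it because scores are
normalized per bin first. A fragment overlapping two bins contributes its
overlap to both; coverage is computed with `IRanges` run-length encodings,
and `compute_rmq()` is pinned against a literal per-base-pair counting
oracle in the tests. Bins enter association analysis only if their scores
have positive variance and at least 10% of samples are non-zero
(`filter_bins()`; both thresholds inclusive). Alignment QC is an upstream
contract: the package consumes post-QC fragments and the read-count
denominator as data, and counts read pairs once for paired-end input.

## The two association models

Scores are normalized per bin across samples before regression. The default
is the rank-based inverse-normal transform \(\Phi^{-1}((r - 0.5)/n)\) with
average ranks for ties — coverage scores are right-skewed and zero-inflated,
and the rank transform makes the per-bin Gaussian working assumptions
reasonable; a plain z-score and no transform are available switches.

**Twin cohort.** `fit_twin_ewas()` fits, per bin, the linear mixed model
\(y = \beta_0 + \beta\,\mathrm{HPST} + a_{\text{family}} + e\) with a random
family intercept. For families of size at most two the model admits an exact
orthogonal decomposition into scaled pair sums and differences, which makes
the covariance diagonal given the intraclass correlation
\(\rho = \sigma_a^2/(\sigma_a^2 + \sigma_e^2)\). The fitter profiles the
REML criterion over a \(\rho\) grid for all bins simultaneously (dense
matrix algebra rather than one optimiser call per bin), then computes GLS
estimates at each bin's optimum. An exact per-bin optimiser
(`method = "exact"`) is retained for small target sets; the test suite pins
it against `lme4::lmer(REML = TRUE)`, which maximises the same likelihood.

**Inference.** Wald tests with a plain normal reference are visibly
anti-conservative in this design: at 25 pairs the estimated variance ratio
is noisy, and plugging it into the GLS variance understates the sampling
variance of \(\hat\beta\) (empirically ~6.9% of null bins at nominal
p < 0.05). medipewas therefore reports Kenward–Roger small-sample
inference: the GLS variance is inflated by the classical KR correction for
estimated variance components, and the reference is a t distribution with
Satterthwaite-type degrees of freedom. For this two-variance-component
model both corrections are scalar functions of \(\rho\) and the design, so
they are computed once per profiled \(\rho\) value and shared across bins.
With them, null p-values are uniform (the suite checks Kolmogorov–Smirnov
uniformity on ~10,000 null bins). When every family has size one the
corrections vanish and the fit collapses exactly to OLS with its t test.

**Unrelated cohort.** `fit_unrelated_ewas()` is vectorised OLS of
normalized RMQ on the trait, optionally with covariates (e.g. age) and up to
three methylation principal components computed once from the normalized
retained matrix. P-values are exact t tests, pinned in the tests to
`lm()` output.

## Permutation FDR

Genome-wide significance is judged against a permutation null
(`permute_phenotypes()`, `estimate_fdr()`, `meta_permutation()`), with 20
replicates by default. In the twin cohort the permutation preserves family
structure: the two co-twin HPST values move as a unit — value-pairs are
shuffled across families and the within-pair assignment is randomized. The
scheme choice is genuinely open (one could also swap only within pairs);
moving pairs as units preserves both the within-pair difference distribution
and the between-family exchangeability, and a `free` scheme is the option
used for the unrelated cohort. At each threshold \(t\) on the grid of
distinct observed p-values,

\[ \widehat{\mathrm{FDR}}(t) = \frac{\#\{p_{\text{perm}} \le t\}/R}{\#\{p_{\text{obs}} \le t\}}, \]

with 0/0 defined as 0. The raw ratio need not be monotone, so it is
monotonized by a running minimum toward smaller p before the threshold (the
largest p with FDR at or below the target) is read off. The estimator is
pinned against a brute-force recount oracle, is invariant to duplicating
the replicate set, and for the meta-analysis threshold each permutation
replicate pair is meta-analysed with exactly the observed-data procedure,
heterogeneity filter included.

## Meta-analysis and heterogeneity

`meta_analyse()` combines the two cohorts per bin by inverse-variance
fixed-effect meta-analysis (\(w_i = 1/se_i^2\)), with Cochran's Q, its
chi-square p (1 df for two cohorts), and \(I^2 = \max(0, (Q - (k-1))/Q)\).
Bins with strong heterogeneity (\(p_Q \le 0.01\) or \(I^2 \ge 0.8\)) are
excluded from ranking and from permutation counting alike. A
DerSimonian–Laird random-effects variant is provided for sensitivity
analysis; when \(Q \le k-1\) it equals the fixed-effect result exactly.
The scalar operations are cross-checked against `metafor` in the tests,
and the bundled nine-DMR reference table shows the expected behaviour of
round-tripping printed two-decimal inputs: seven of nine rows reproduce the
published MA beta at two decimals, and the two that miss do so by exactly
one unit in the second decimal, the footprint of input rounding (their MA
p-values are likewise not reproducible from rounded inputs, which is why the
package pins only the betas).

## Twin concordance and follow-up analyses

* `per_bin_icc()` — one-way ANOVA ICC(1,1), \((MSB - MSW)/(MSB + MSW)\) for
  pairs of two. The ICC flavour is a documented choice; the estimator is
  pinned to an `aov()` oracle.
* `within_pair_association()` — co-twin differences (higher-HPST twin minus
  lower, a pure reporting convention that cancels in correlations) with
  Pearson/Spearman correlations and an adjusted difference regression.
* `meqtl_scan()` — additive dosage model within ±50 kb of a bin, minor
  allele frequency ≥ 0.05, nominal p per SNP, best SNP flagged per bin.
* `wbc_association()` — the twin mixed model with a white-blood-cell
  subtype proportion as the fixed effect, Bonferroni-corrected across the
  target DMRs (0.05/9 = 0.0056 at the nine-DMR default).
* `classify_longitudinal()` — percent change between timepoints uses the
  timepoint-1 value as denominator (undefined at zero baselines, which are
  flagged); the stable/variable boundary at 30% is assigned to stable, both
  documented choices the data cannot decide. The susceptibility contrast
  (rank-sum on |ΔHPST|) requires at least 6 variable-class samples.
* `tissue_sharing()` — blood–brain sharing under the lenient (any brain
  region within 10% of the blood level) and strict (mean difference within
  10%) criteria; scale-invariant by construction.
* `platform_direction_validation()` — a gene validates when any assigned
  array CpG matches the DMR's direction at nominal p < 0.05; the weak-p
  cut is configurable since no principled value exists.

## What the generator emulates — and what it does not

`simulate_pain_study()` reproduces the statistical structure the analyses
assume: discordant pair HPSTs (pair means Normal(47, 1.5) °C, within-pair
deviations of the same scale, rejection-sampled to at least 2 °C apart —
the marginal moments are a configurable stand-in, since only the
variance/discordance structure matters to the statistics), per-bin RMQ with
a family variance fraction (default 0.4) and planted DMR slopes
(standardized effect 0.3, 70% negative to mirror the predominance of
hypermethylation at low pain thresholds), cis-meQTL dosage shifts, ASM
skew shared within co-twin pairs, a second timepoint with
stable/variable regions split 75/25, white-cell proportions, and a blood
plus seven-brain-region panel. Methylation is simulated directly on the RMQ
scale (truncated at zero, as RMQ is a coverage sum) except for the
fragment-level sampler used to test quantification; the toy genome default
is 2 chromosomes × 2.5 Mb, about 10,000 overlapping bins.

Deliberately not emulated: sequencing error, alignment artefacts, CpG
density bias, batch structure, and cell-composition confounding of the
trait itself. Passing tests therefore demonstrate the statistical machinery
is correct under its stated assumptions, not that real MeDIP-seq data meet
those assumptions.

## Numerical choices and problem sizes

The \(\rho\) profile grid has 67 points on [0, 0.99]; the exact optimiser
tolerance is 1e-9. Zero-variance bins are flagged `degenerate` rather than
dropped silently. The test suite runs the full pipeline at the reference
study size (10,000 bins, 100 samples, 20 permutation replicates) across 20
master seeds for the FDR calibration check, and uses 200 planted DMR bins
and 40 meQTL SNPs for the coverage checks — sizes chosen so Monte-Carlo
error is small relative to the tolerances asserted.

All randomness flows from explicit seeds (`sim_config(seed = )`, the
pipeline's master seed); reruns are byte-identical. Outputs are tibbles,
plain TSV/BED/YAML on disk, and the package's functions are the interface —
analyses compose with the pipe, and `run_pain_pipeline()` plays the
orchestrating role a shell entry point would otherwise have.

## Known limitations

* The pair mixed model supports families of size one or two; larger
  families would need a general LMM and are rejected explicitly.
* The KR/Satterthwaite corrections assume Gaussian working residuals after
  normalization; heavy contamination would call for the permutation
  thresholds (which remain valid regardless) rather than nominal p-values.
* Genome-scale findings of the motivating design (specific DMRs, the
  10^-11-scale thresholds, genome-wide ICC means) depend on real cohorts
  and are out of reach of desk-scale synthetic data; the package pins the
  self-contained worked examples and the statistical properties instead.
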