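---
title: "Methods: pan-cancer integrin screening, driver attribution and survival modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-cancer integrin screening, driver attribution and survival modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(integrinscape)
```

`integrinscape` screens the 30 integrin subunit genes (ITGs) across
tumor/normal cohorts for dysregulation, attributes it to copy-number or
DNA-methylation mechanisms, summarizes the mutation landscape, screens
overall survival, and fits per-cancer Cox risk models. This vignette is
the package's account of the statistical procedures, the choices behind
them, and what the bundled synthetic cohorts can and cannot demonstrate.

## Differential expression and enrichment

Tumor-versus-normal comparisons use the two-sided Mann–Whitney
(Wilcoxon rank-sum) test on log2 expression. A rank test was chosen
because bulk expression distributions are heavy-tailed and the test is
invariant to monotone normalization choices. Fold change is defined on
the log2 scale as `mean(tumor) − mean(normal)`. A call requires both
conditions — BH FDR below `fdr_threshold` (default 0.05) *and*
`|log2FC| ≥ log2fc_threshold` (default 1, i.e. two-fold) — so a tiny but
consistent shift, or a large but noisy one, stays "ns". Both thresholds
are configurable because differential-expression conventions vary across
cohorts and platforms. FDR is adjusted across the gene panel within one
cancer type (`stats::p.adjust(method = "BH")`), mirroring the per-cancer
screening design.

Gene-set enrichment uses the classic weighted Kolmogorov–Smirnov running
sum: genes are ranked by the signal-to-noise ratio
(difference of group means over the sum of group standard deviations,
each standard deviation floored at 10% of the group mean's magnitude, a
standard stabilization for near-constant genes), hits increment the sum
by `|s|^w` normalized over hits (weight exponent `w = 1` by default),
misses decrement by `1/(N − Nh)`. The enrichment score is the signed
maximum deviation of the running sum. Significance comes from phenotype
label permutation (default 1000 permutations) with the add-one p-value
convention `(1 + #{|ES*| ≥ |ES|})/(1 + n_perm)`, so p is never 0; the
normalized score divides by the mean |ES*| of matching sign. A gene set
equal to the whole universe is rejected because the miss penalty is then
undefined.

Cross-cancer connectivity is the matrix of Jaccard indices between
per-cancer up- (or down-) regulated sets, defined as 0 when both sets are
empty, clustered by average-linkage hierarchical clustering on the
distance `1 − J`. Average linkage with input-order tie-breaking keeps the
leaf order deterministic.

## Driver attribution

A gene's dysregulation is attributed to copy number when three criteria
hold simultaneously in the tumor samples: (1) more than 40% of tumors
altered in the call direction (CNV > 0.1 for gain, < −0.1 for loss) with
fewer than 40% altered the opposite way; (2) |mean tumor CNV| > 0.1; and
(3) Pearson correlation between CNV and expression above 0.3 at BH
FDR < 0.05. Methylation-driven calls require |Δβ| > 0.05 with a
Mann–Whitney differential-methylation FDR < 0.05, and a β–expression
Pearson correlation below −0.3 at FDR < 0.05; Δβ > 0 (tumor
hypermethylation) implies expected downregulation, Δβ < 0
(hypomethylation) expected upregulation. All comparisons are strict
inequalities. The gain and loss branches are mutually exclusive by
construction (their >40%/<40% fraction requirements cannot co-fire).

Design points worth making explicit:

- Correlations are computed on tumor samples only — CNV exists only for
  tumors, and the methylation–expression coupling of interest is the
  within-tumor one.
- The FDR scope is the tested gene panel within one cancer type,
  separately per omic layer, because the screen is run per cancer.
- Driver calling is independent of the differential-expression call;
  `driver_summary()` annotates, rather than enforces, whether a call is
  concordant with dysregulation (gain/hypomethylation with "up",
  loss/hypermethylation with "down").
- Gene-level CNV is accepted as any continuous per-gene value
  (segment-mean-like or GISTIC-style); the criteria only assume the
  0.1 threshold is meaningful on that scale.

## Mutation landscape

Only protein-altering MAF classes are kept (missense, nonsense, nonstop,
frameshift and in-frame indels, splice site, translation start site);
Silent and non-coding classes are dropped, and unrecognized classes are
dropped with a warning (the allowlist is configurable). Single-nucleotide
substitutions collapse to the six pyrimidine-reference categories by
complementing purine-reference pairs, which makes the spectrum invariant
to strand flips; indels and multi-nucleotide records count toward
mutation rates but not the spectrum. Rates use the number of samples
*with mutation data* as denominator — mutation calls exist only for
sequenced samples, which may be fewer than the expression columns — and a
record naming a sample outside that denominator is an error rather than a
silent inflation. The cohort rate counts samples with at least one panel
gene mutated, so one sample with three mutated ITGs contributes once.

## Survival screening

Each horizon (total, 10-year, 5-year) applies administrative censoring:
events after the horizon become censored at the horizon, and an event
exactly at the horizon stays an event (closed-interval convention —
stated because the boundary case is otherwise ambiguous). Time is in
months.

The cutpoint scan considers every distinct expression value whose induced
low group (expression ≤ cut) holds between 10% and 90% of the samples —
the reading of the "10th to 90th percentile" rule that guarantees
non-degenerate groups — and scores each split by the two-group log-rank
test (hypergeometric mean and variance at each distinct event time,
chi-square with 1 df). The minimum-p cut is selected; exact p ties break
toward the cut closest to the median expression, then toward the smaller
cut. The hazard ratio of high versus low expression at the selected cut
comes from a univariate Cox fit with Efron tie handling. HR > 1 with
five-year p < 0.05 labels the gene "poor", 0 < HR < 1 with p < 0.05
"favorable"; the total and 10-year calls are annotation. When one group
has no events the HR is reported as a 0/∞ sentinel and the label is
forced to "ns"; a large but estimable HR (monotone likelihood with events
in both groups) keeps its label.

No multiple-testing correction is applied across the scanned cutpoints.
This matches the screening procedure the pipeline models, but it means
the scan's p-values are anti-conservative by construction. Rather than
hide that, the package characterizes it: under a pure null with 200
tumors and 200 null genes, the fraction of genes reaching p < 0.05
is roughly 0.35–0.45 — several times the nominal level. Treat the scan as
a ranking/screening device; confirmatory claims need independent data or
a selection-aware correction.

`prognostic_dysregulated()` intersects genes with a non-"ns"
differential-expression direction and a non-"ns" prognosis label in the
same cancer, flagging concordance (up∧poor or down∧favorable).

## Cox risk models

`fit_cox()` maximizes the Efron-tied partial likelihood by
Newton–Raphson with step-halving; convergence requires the largest
coefficient change to fall below 1e-8 within 100 iterations, and
non-convergence is reported, never silently accepted. Rank-deficient
covariate matrices raise an error naming the offending columns (no silent
dropping), and |β| > 15 is treated as monotone likelihood: the
coefficient is capped with a warning. Gene expression is z-scored within
the cohort before fitting so coefficients are per-SD and comparable;
T/N/M staging indexes enter as ordinal codes (T1–T4 → 1–4, N0–N3 → 0–3,
M0/M1 → 0/1), and samples missing any requested covariate are excluded.

The risk score is the linear predictor. The cohort splits at the median
score (configurable percentile); groups are compared by Kaplan–Meier
curves and the log-rank test. The 5-year AUC uses concordant-pair
counting with half credit for ties (equivalently Mann–Whitney U over
positive–negative pairs), with outcome defined as: death on or before 60
months = positive, followed beyond 60 months = negative, censored before
60 months = indeterminable and excluded. Time-dependent ROC estimators
that model the censoring distribution are a deliberate non-goal; the
exclusion rule is simple, stated, and unbiased when censoring is
independent of the score.

## The synthetic cohort generator

The generator emulates the statistical structure of TCGA-style inputs so
every stage can be tested against a known truth table:

- **Expression**: Gaussian on the log2 scale around per-gene baselines
  drawn from U(5, 10), residual sd 1 by default; planted shifts are added
  to tumor samples.
- **CNV**: non-driver genes draw N(0, 0.05) noise; a planted driver
  alters a configured fraction of tumors at N(±magnitude, 0.1) and adds
  `coupling_strength × CNV` to tumor expression. The internal helpers
  `coupling_for_r()` / `planted_cnv_sd()` / `planted_beta_sd()` convert a
  target CNV–expression (or β–expression) correlation into the coupling
  coefficient via the attenuation formula
  `c = r/√(1−r²) · σ_noise/σ_x`, so "planted at r ≈ 0.7" is a
  closed-form choice, not a tuned one.
- **Methylation**: β-values are logit-normal (sd 0.25 on the logit
  scale) around baselines in U(0.25, 0.75), which respects the [0, 1]
  support; a driver shifts the tumor mean by Δβ and couples negatively
  to expression.
- **Survival**: Weibull proportional hazards (default scale 60 months,
  shape 1.2 — median survival near 4.5 years with mildly increasing
  hazard, a realistic registry profile) with linear predictor
  Σ effect × z(expression); censoring is independent exponential,
  truncated administratively at 120 months, with the exponential rate
  solved numerically (integration + root finding) so the *overall*
  censored fraction matches `censoring_rate` (default 0.3). The solution
  ignores the linear-predictor variance, so heavily planted cohorts can
  deviate by a few percent.
- **Mutations**: Bernoulli per gene per tumor sample (default 0.03),
  emitted as minimal MAF records with a class mix of 55% missense, 20%
  silent, 10% nonsense, 10% frameshift, 5% splice site — enough to
  exercise the nonsynonymous filter and the spectrum.
- **Clinical**: T/N/M drawn from fixed multinomials, stage derived from
  them, gender balanced, age ~ N(65, 10).
- **Seeds**: one integer per cohort; per-omic substreams derive from
  fixed offsets plus a cancer-code hash, so identical configurations are
  bit-identical, cohorts with equal seeds but different codes are
  independent, and `generate_pan_cancer()` output is invariant to
  configuration order.

What the generator does *not* emulate: batch effects, tumor purity,
probe-level methylation structure, genomic coordinates, copy-number
segmentation artifacts, or correlated gene–gene co-regulation beyond the
planted couplings. Passing tests therefore demonstrate that the
*procedures* are implemented correctly and calibrated under clean
conditions — not that real TCGA cohorts would yield any particular gene
list.

## Numerical conventions and degenerate inputs

- Enrichment score ties: when the positive and negative running-sum
  extremes agree in magnitude within a relative 1e-9, the extreme
  reached earlier in the ranked list is taken. Without this rule the
  result of a structurally symmetric profile depends on last-bit
  accumulation order.
- BH adjustment delegates to `stats::p.adjust`; q-values are returned in
  input order and never fall below the raw p.
- Zero-variance genes: the co-expression matrix sets their rows/columns
  to missing with a warning; the signal-to-noise ranking floors the
  group sd; `pearson_with_p()` errors on zero variance rather than
  returning NaN.
- All-identical expression in the cutpoint scan, no admissible cut, or
  no events after horizon censoring yield an "ns" call with a warning,
  not an error, so one degenerate gene cannot abort a screen.
- Log-rank with zero total events is an error (the test is undefined);
  zero between-group variance returns NA.
- Matrices round-trip through the tab-separated writers at 15
  significant digits, lossless well past 12.

## Test and verification sizes

The suite verifies the core statistics against independently coded
references: the log-rank test against `survival::survdiff` on 100 random
tied datasets (agreement to 1e-8), the cutpoint scan against exhaustive
brute force over all admissible splits on 50 datasets, the enrichment
score against a prefix-sum oracle for all sets of size ≤ 3 over universes
of size ≤ 10, BH against brute-force step-up on 1000 random vectors
(machine precision), and `fit_cox` against `survival::coxph` and Wald
coverage of planted log-hazards (0.7, −0.4) at n = 1000 over 100
replicates. Recovery and calibration use synthetic cohorts of 200 tumors
/ 100 normals with 200 genes (drivers), 500 null genes × 10 seeds (null
calibration), and a bundled three-cancer configuration of 60 tumors / 25
normals per cancer for end-to-end determinism. These sizes were chosen to
give stable pass/fail behaviour at desk scale while keeping the default
test run fast.

## Known limitations

- The min-p scan's p-values are selection-inflated (documented above);
  the package reports them as the screening procedure defines them.
- The risk model uses all dysregulated prognosis-related genes by
  default; no variable selection or penalization is performed, and
  heavily collinear gene sets will error rather than fit.
- Clinical associations are univariable by design (no stage-adjusted age
  effects); age is treated continuously unless an explicit cut is given.
- The enrichment module ships no curated signatures; gene sets are
  supplied by the user (GMT input is supported).
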