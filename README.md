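# integrinscape

Pan-cancer multi-omics characterization of the integrin subunit genes
(ITGs): a reusable, tested R pipeline for screening where, how and with
what clinical consequence the 30 ITGs (18 alpha-family genes such as
ITGA11 and ITGAV, 12 beta-family genes including ITGB1BP1/2, ITGB3BP and
ITGBL1) are dysregulated across tumor cohorts.

Integrins transduce adhesion and mechanotransduction signals and are
recurrently altered in cancer, but most studies look at one gene in one
cancer type. `integrinscape` operationalizes the pan-cancer view: given
per-cancer tumor/normal cohorts (log2 expression, gene-level copy number,
methylation beta-values, MAF mutations, survival and staging data) it runs
the full screening cascade and, because real multi-omics downloads are
bulky and access-controlled, ships a synthetic cohort generator with
machine-readable truth tables so every stage is testable offline.

## What the pipeline computes

- **Differential expression** — per gene, two-sided Mann–Whitney of tumor
  vs normal log2 expression with Benjamini–Hochberg FDR across the panel;
  a gene is called up/down only when FDR < 0.05 *and* |log2FC| ≥ 1.
  Gene-set enrichment uses the weighted Kolmogorov–Smirnov running-sum
  statistic with signal-to-noise ranking and phenotype permutation.
  Cross-cancer connectivity is the Jaccard matrix J(A,B) = |A∩B|/|A∪B| of
  dysregulated sets, clustered by average linkage on 1 − J.
- **Driver attribution** — a dysregulated gene is *CNV-driven* when
  (1) >40% of tumors have CNV > 0.1 (gain) with <40% altered the opposite
  way, (2) |mean tumor CNV| > 0.1, and (3) Pearson r(CNV, expression) >
  0.3 at BH FDR < 0.05; *methylation-driven* when |Δβ| = |mean tumor β −
  mean normal β| > 0.05 with Mann–Whitney FDR < 0.05 and r(β, expression)
  < −0.3 at FDR < 0.05 (hypermethylation → expected downregulation,
  hypomethylation → upregulation).
- **Mutation landscape** — nonsynonymous-only filtering (Silent and
  non-coding classes excluded), per-gene and cohort mutation rates, the
  six-category substitution spectrum (C>A, C>G, C>T, T>A, T>C, T>G in the
  pyrimidine-reference frame), and normal / wild-type / mutant expression
  comparisons.
- **Survival screening** — for each gene and horizon (total, 10-year,
  5-year with administrative censoring), the minimum-log-rank-p expression
  cutpoint scan over splits whose low group holds 10–90% of samples;
  HR > 1 with 5-year p < 0.05 labels a gene poor-prognosis, 0 < HR < 1
  favorable. Genes both dysregulated and prognostic are intersected.
- **Risk models** — multivariate Cox (Newton–Raphson, Efron ties) over
  standardized expression of the prognostic dysregulated genes plus
  ordinal T/N/M indexes; median risk-score split, Kaplan–Meier/log-rank
  comparison, and 5-year ROC AUC.
- **Clinical associations** — Spearman correlation with ordinal stage and
  age, rank-biserial effect for gender, BH per covariate per cancer.

## Worked example

```r
library(integrinscape)

cfg <- cohort_config("STAD", n_tumor = 100, n_normal = 40, seed = 7,
                     planted_up = c(ITGA11 = 2),
                     planted_prognostic = c(ITGA11 = 0.8))
g  <- generate_cohort(cfg)
de <- differential_expression(g$cohort)
subset(de, direction != "ns")
#>     gene cancer_code log2fc  p_value      fdr direction
#> 3 ITGA11        STAD   1.69 7.71e-11 2.31e-09        up

sv <- survival_screen(g$cohort, genes = "ITGA11")
sv[, c("gene", "horizon", "cut_percentile", "hr", "logrank_p", "label")]
#>     gene horizon cut_percentile   hr logrank_p label
#> 1 ITGA11   total           0.81 6.19  1.09e-10  poor
#> 2 ITGA11    10yr           0.81 6.19  1.09e-10  poor
#> 3 ITGA11     5yr           0.81 6.19  1.09e-10  poor

pg <- prognostic_dysregulated(de, sv)
rmod <- build_risk_model(g$cohort, pg$gene)
rmod$summary
#>   cancer_code covariate coefficient    se        p
#> 1        STAD    ITGA11      0.8929 0.154 6.22e-09
#> 2        STAD   t_index     -0.0715 0.123 5.60e-01
#> 3        STAD   n_index      0.0607 0.134 6.50e-01
#> 4        STAD   m_index     -0.2608 0.433 5.46e-01
```

The planted ITGA11 signal is recovered end to end: upregulated (log2FC
1.69, FDR 2×10⁻⁹), poor prognosis at every horizon (HR 6.2 at the scanned
cutpoint, the 81st expression percentile), and the dominant covariate in
the risk model (KM log-rank p = 9.3×10⁻⁸ between median-split risk groups,
5-year AUC = 0.80). For a full multi-cancer run, assemble a
`run_config()` of several `cohort_config()`s (or directories of cohort
files) and call `run_pan_cancer()`; `inst/scripts/run-pan-cancer.R` wraps
the same entry point for shell use.

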