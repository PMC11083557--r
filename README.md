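# methylquad

Integrative DNA-methylation / expression analysis for nominating
subtype-specific, prognosis-associated genes — the workflow used to find
markers of the ATP1A1-in-TNBC kind: score methylation over gene-linked
regions from enrichment-sequencing counts, call hyper-/hypomethylated
genes per tumor subtype against matched normals, partition calls by
CpG-island and promoter/gene-body context, intersect with expression into
four quadrant groups, screen candidates for subtype specificity, and
stratify survival by a composite methylation-expression risk rule. A
percent-methylation calibration module for MS-HRM melting curves covers
the validation assay, and a synthetic-cohort generator with planted truth
makes the whole pipeline testable end to end without any downloads.

Audience: computational biologists working with capture-based methylomes
(MBD-seq / MeDIP-seq style ROI counts) plus matched expression and
clinical follow-up.

## The method in brief

* **Scoring.** Counts over promoter (−2000/+500 bp around the TSS) and
  CDS regions become absolute methylation scores
  `ams = RPKM / (CpG weight relative to the cohort median)`, then each
  sample is min-max scaled to [0, 1].
* **Differential methylation.** Per subtype and region,
  `Δ = mean(tumor) − mean(normal)` on the scaled score with a paired
  t-test; *hyper* if `Δ > 0.2` and `p < 0.05`, *hypo* if `Δ < −0.2`
  (thresholds configurable; BH q-values reported, strict-FDR gate
  available).
* **Integration.** Genes with `|log2FC| ≥ log2(1.2)` in expression join
  the quadrants hypo_up / hypo_down / hyper_up / hyper_down;
  subtype-specific sets are exact set algebra over per-subtype calls;
  candidates are ranked by the product of median methylation and
  expression margins versus all other subtypes (signs must match).
* **Survival.** Median splits on marker methylation and expression feed a
  composite rule (e.g. hypomethylated AND highly expressed = high risk);
  groups are compared with from-scratch Kaplan-Meier and log-rank
  (Mantel-Haenszel) machinery, plus an optimal-cutoff scan whose
  minimum-p is always accompanied by a permutation-adjusted p.
* **MS-HRM.** Melting-peak areas (trapezoidal AUC over temperature
  windows) calibrate percent methylation by linear regression against
  0/50/100% standards.

## Worked example

```r
library(methylquad)

cfg <- pipeline_config(simulation = sim_config(seed = 1), out_dir = "demo_run")
res <- run_pipeline(cfg)
#> inputs: simulated cohort with 1000 features x 80 samples
#> roi_annotation: 1000 regions (668 CGI)
#> differential_methylation [LumA]: 13 hyper / 20 hypo
#> differential_methylation [LumB]: 13 hyper / 20 hypo
#> differential_methylation [HER2]: 15 hyper / 18 hypo
#> differential_methylation [TNBC]: 14 hyper / 19 hypo
#> integration: 19 quadrant genes, 19 passing candidates
#> survival_analysis: log-rank p = 2.794e-09 (high risk n=80)
```

Each subtype shows ~30 called genes: the 35 planted per subtype (15
hyper, 15 hypo, 5 shared hypo) minus a few whose scaled delta lands just
under the 0.2 threshold, plus the occasional raw-p false positive. The
candidate table ranks quadrant genes by their subtype-specificity
margins in the tumor samples:

```r
head(res$candidates[res$candidates$passes, ], 3)
#> # A tibble: 3 × 6
#>   gene_id quadrant   meth_margin expr_margin passes score
#> 1 g0257   hyper_down       0.157       -1.85 TRUE   0.291
#> 2 g0236   hypo_up         -0.157        1.49 TRUE   0.235
#> 3 g0200   hyper_down       0.138       -1.65 TRUE   0.228
res$truth$marker$gene_id
#> [1] "g0236"
```

The planted prognostic marker (`g0236`, hypomethylated and upregulated
specifically in TNBC) passes the screen as the top hypo_up candidate. Its
composite risk rule separates the simulated clinical cohort sharply:

```r
res$survival$logrank
#> <logrank_test> chi-square = 35.3221 on 1 df, p = 2.794e-09
glance(res$survival$km$high_risk)$median_survival  # 5.83
glance(res$survival$km$low_risk)$median_survival   # 14.2
res$survival$cutoff
#> <cutoff_scan> cutoff = 6.604; uncorrected p = 1.71e-07; permutation-adjusted p = 0.004975
```

High-risk subjects (marker hypomethylated and highly expressed) reach
median survival at 5.8 time units versus 14.2 for everyone else — the
planted hazard ratio of 3 at work. Every table is also written under
`demo_run/` with an MD5 manifest; rerunning the same config reproduces
the checksums bit-exactly.

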