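# icbmm

Multimodal integration of cytotoxic T-cell and tumor genomic features for
modeling immunotherapy response in non-small cell lung cancer (NSCLC).

## What this package is for

Response to PD-1/PD-L1 immune checkpoint blockade (ICB) in metastatic NSCLC
is highly variable, and the standard tumor-intrinsic biomarkers — PD-L1
staining and tumor mutational burden (TMB) — are individually weak. A
complementary tumor-extrinsic signal is the infiltration of clonally
expanded cytotoxic CD4+ and CD8+ T cells, measurable in bulk RNA through a
25-gene cytotoxic program. `icbmm` is aimed at computational
immuno-oncologists who want a tested, end-to-end implementation of that
integrative analysis:

- **Single-cell stage** — QC (cells with < 200 or > 2500 detected genes, or
  > 6% / > 20% mitochondrial counts for immune/tumor fractions, removed;
  genes in < 3 cells removed), 10,000-count normalization, CLR protein
  normalization, CD4/CD8 compartment gating, one-vs-rest Wilcoxon rank-sum
  differential expression with Bonferroni correction, and top-25 gene
  signatures.
- **TCR repertoire** — clonotype calling on paired TRA/TRB CDR3 strings,
  expansion statistics, Shannon entropy `H = −Σ p_i ln p_i` with
  Hutcheson's variance
  `Var(H) = (Σ p_i ln²p_i − (Σ p_i ln p_i)²)/N + (S−1)/(2N²)`,
  Hutcheson's t-test `t = (H₁−H₂)/√(V₁+V₂)`, and directed clone-sharing
  graphs with quantile pruning.
- **Genomic features** — TMB = passing non-silent somatic coding variants
  per megabase (strict > 100× / > 5% AF for panels, > 30× / > 10% for WES),
  binarized at ≥ 10 mut/Mb; HLA class I LOH called from allele-specific
  coverage against the purity mixture expectation
  `f_loss = (1−p)/((1−p)·2 + p·(C−1))`; PD-L1 TPS categories.
- **Survival** — Kaplan–Meier, k-group log-rank, and a Newton–Raphson Cox
  fitter with Breslow tie handling and ridge penalty, written in-package
  and cross-checked against the `survival` package in the tests.
- **The multimodal (MM) score** — ridge Cox models (`alpha = 1`) on
  (standardized cytotoxic score, TMB ≥ 10) over 100 random 75/25 shuffles;
  each patient's MM score is the mean out-of-fold linear predictor,
  median-split into high/low risk groups and evaluated against time to
  progression (TTP).

The motivating patient data are access-restricted, so the package ships a
first-class synthetic-data module (`sim_config()`, `generate_*()`) that
produces every input — single-cell counts, chain records, variant tables,
HLA coverage profiles, survival cohorts — with the statistical structure
the analysis assumes, including planted ground truth for recovery testing.

## Worked example

```r
library(icbmm)

cfg <- sim_config(seed = 42, n_patients = 123)   # cohort-scale defaults
co  <- generate_cohort(cfg)                       # planted beta_cs = -0.7, beta_tmb = -0.5
cohort <- co$cohort
cohort$cs <- cytotoxic_score(co$expr, standardize = FALSE)

mm <- mm_train(cohort, n_shuffles = 100, ridge_alpha = 1, seed = 42)
mm
#> <mm_result> 123 patients, 100 shuffles (+0 extra, 0 redrawn), cutoff -0.2572
#> high  low
#>   62   61

rec <- data.frame(patient_id = cohort$patient_id,
                  time = cohort$time_days, event = cohort$event)
rep <- mm_stratify_report(mm, rec)
#> log-rank chisq = 26.27 (p = 2.96e-07)
#> HR (high vs low) = 2.80 [1.86, 4.21]
#> median TTP: high 156 days, low 458 days
```

The high-MM group progresses much faster (median TTP 156 vs 458 days,
hazard ratio 2.8): the ensemble recovers the planted protective effects of
cytotoxic expression and high TMB and converts them into a risk
stratification, exactly the behavior expected when both features carry
signal.

The repertoire stage on the synthetic single-cell data shows the
clonal-expansion contrast the cytotoxic clusters are built with:

```r
sc   <- generate_sc_dataset(sim_config(seed = 42, n_cells = 1000))
clon <- call_clonotypes(sc$chains,
                        cell_meta = sc$truth[, c("cell_id", "cluster", "compartment")])
cd8  <- clon[clon$compartment == "CD8", ]
cyto <- cd8$cluster %in% c("CD8_GZMB", "CD8_GZMK")
hutcheson_t_test(as.integer(table(cd8$clone_id[cyto])),
                 as.integer(table(cd8$clone_id[!cyto])))
#> Hutcheson t = -7.14 (df = 437.5, p = 3.88e-12)
```

The negative t says the cytotoxic CD8 repertoire has significantly lower
Shannon diversity — it is dominated by expanded clones — than the
non-cytotoxic CD8 cells.

`run_pipeline(pipeline_config(out_dir, seed))` executes every stage in
order on synthetic inputs and writes plain-text outputs plus a manifest of
MD5 checksums; two runs with the same seed are byte-identical.

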