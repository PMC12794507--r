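# scmodules

Cross-batch discovery and validation of gene **activity modules** in
single-cell transcriptomics.

## The problem

Single-cell RNA-seq of circulating immune cells mostly reveals *identity*
programs — gene sets that mark a cell type. Rarer and more interesting are
*activity* programs: co-expressed gene sets (early-activation transcription
factors, homing receptors, stress-response genes) whose per-cell intensity
varies across **all** cell types and tracks disease state. A module that is
independently rediscovered in every experimental batch — with no cross-batch
integration step that could manufacture shared structure — is strong
evidence of a real program. `scmodules` implements that discovery strategy
and the statistics used to validate such a module, plus a synthetic-data
generator with a ground-truth channel so the whole pipeline is testable
without any external data.

## What it computes

- **Per-batch program discovery** — overdispersed-gene selection by a
  robust CV² = a₁/μ + α₀ gamma fit with a scaled chi-square deviation test,
  then consensus non-negative matrix factorization: the variance-scaled
  matrix is factored `V (cells×genes) ≈ U·S` by multiplicative updates
  (Frobenius objective) over many seeded replicates; pooled replicate
  spectra are density-filtered, k-means-clustered, and summarized by
  component-wise medians. *Stability* (mean silhouette) and *error*
  (Frobenius residual) guide the choice of K.
- **Cross-batch consensus** — programs matched across batches by Jaccard
  distance between top-N gene lists (hierarchical clustering, average
  linkage); only clusters covering all batches are retained; the module
  gene set is the cross-batch intersection of top-N lists, with a scree
  table (N vs intersection size) to pick N.
- **Module scoring** — per cell, the Mann–Whitney U construction on
  within-cell expression ranks: `U' = Rs − n(n+1)/2`,
  `score = 1 − U'/(n·rmax)` in [0,1] (rank cap `rmax`, average ties); per
  bulk sample, the mean of cross-sample z-scores of the module genes.
- **Validation battery** — random-gene correlation nulls; longitudinal
  trend regression (score ~ time per cell type × condition); permutation
  resampling robustness (200 cells/group × 5000 repetitions, Wilcoxon +
  Benjamini–Hochberg); two-sample Kolmogorov–Smirnov; quartile (25%/75%)
  stratification; a pseudo-replicate gradient gene scan.
- **Annotation statistics** — Fisher exact enrichment (cross-product OR),
  hypergeometric over-representation with BH, gene–disease-association
  permutation tests.
- **Ligand–receptor pairing** — top-50%-expressed, differentially
  expressed tissue ligands joined to per-cell-type receptors via a
  user-supplied interaction table (cytokine category filter).
- **Disease classification** — module genes vs CV²-selected control
  features, ridge logistic regression under repeated stratified
  cross-validation, F1 and Cohen's κ.

## Worked example

Simulate a 3-batch cohort with a planted activity module, rediscover the
module per batch, match it across batches, and test its longitudinal trend:

```r
library(scmodules)

cfg <- cohort_config(n_genes = 400, n_celltypes = 3, n_identity_genes = 25,
                     n_module_genes = 30, n_cells_per_type_per_donor = 25,
                     seed = 1)
cohort <- generate_cohort(cfg)
#> <synthetic_cohort> 400 genes x 1350 cells, 3 batches, module of 24 genes

dcfg <- discovery_config(n_top_genes = 250, n_replicates = 12, k_range = 4:4,
                         max_iter = 100, tol = 2e-4, seed = 2)
programs <- lapply(c("B1","B2","B3"), function(b) {
  batch <- subset_counts(cohort$counts, cells = cohort$counts$cell_meta$batch == b)
  top <- select_overdispersed(batch, 250)
  consensus_nmf(subset_counts(batch, genes = top$genes$genes), K = 4, config = dcfg)
})
names(programs) <- c("B1","B2","B3")
programs$B1
#> <program_set> K = 4 over 250 genes x 450 cells; stability 0.877, error 298.911

clusters <- match_programs(programs, consensus_config(top_n = 45))
length(clusters)            # program clusters represented in all 3 batches
#> [1] 4
best <- clusters[[4]]
#> <consensus_cluster> 3 programs over batches {B1,B2,B3}; intersection 24 genes
jaccard(best$gene_set, cohort$truth$module_genes)
#> [1] 1

scores <- ucell_score(cohort$counts, best$gene_set, rmax = 300)
trends <- trend_regression(scores, cohort$counts$cell_meta)
head(trends[order(trends$beta), ], 4)
#>   cell_type condition    beta       p   n
#> 3       CT2 rejection -0.0649 1.5e-09 225
#> 1       CT1 rejection -0.0601 9.4e-09 225
#> 5       CT3 rejection -0.0600 2.9e-08 225
#> 6       CT3    stable -0.0013 8.9e-01 225
```

Reading the output: all four per-batch programs (3 identity + 1 activity)
match across batches; the activity cluster's cross-batch intersection
recovers the planted 24-gene truth module exactly (Jaccard 1). Its
rank-based module score declines over the three timepoints in every cell
type of the rejection condition (β ≈ −0.06 per timepoint, p < 1e-7) and is
flat in stable donors — the planted trend (activity falling to 0.6× at
later timepoints in rejection) recovered from raw counts.

An end-to-end orchestration of all stages from one YAML config is available
via `run_pipeline()` (see `inst/scripts/scmodules.R` for the command-line
wrapper), and the methods vignette
(`vignettes/activity-module-discovery.Rmd`) documents the model, the
tunable parameters and the design choices.

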