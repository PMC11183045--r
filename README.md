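# regulonDCM

Discovering disease-responsive gene-regulatory networks (regulons) in
dilated cardiomyopathy (DCM) from single-cell and bulk transcriptomes.

A regulon is a transcription factor (TF) together with the target genes it
activates, written `TF(+)`. This package implements, as tested and
reusable R functions, an integrative workflow for finding regulons whose
activity responds to disease and the hub targets they share:

```
single-cell counts ──QC/normalize/cluster/annotate──► cell types
        │
        ├─► metacells (group-pure over-clustering, >10-cell filter)
        │        └─► TF→target importances ──motif pruning──► RegulonSet
        │
        └─► AUCell-style activity (RAS matrix, cells × regulons)
                 ├─► CSI modules (regulon co-specificity clustering)
                 └─► REML variance decomposition (cell type + group)
                          └─► knee-rule selection of responsive regulons
                                   └─► bulk validation ×2 cohorts
                                       (moderated-t DE, ssGSEA, Wilcoxon)
                                            └─► hub targets + ROC/bootstrap
```

The statistics at its core, all implemented in this package:

* **AUCell-style activity**: for each cell, the score of a target set is
  the normalized area under the target-recovery curve over the top 5% of
  the cell's expression ranking — a rank statistic in [0, 1], invariant
  to monotone transforms of expression.
* **Connection specificity index**:
  `CSI(A,B) = #{C ∉ {A,B} : PCC(A,C) ≤ PCC(A,B) and PCC(B,C) ≤ PCC(A,B)} / (N−2)`,
  a specificity-sharpened association used to cluster regulons into
  modules (average-linkage on Euclidean distances between CSI rows).
* **Variance decomposition**: per regulon, activity is fitted by REML as
  `y = μ + a_celltype + b_group + e` with random intercepts; the
  estimates `(σ²_ct, σ²_grp, σ²_e)` are normalized to proportions. Within
  each module, regulons are sorted by the group proportion and the
  leading run of normalized-curve segments steeper than −1 (the knee
  rule) defines the disease-responsive set.
* **Bulk validation**: an empirical-Bayes moderated t (method-of-moments
  prior on log variances) with `|log2FC| > 0.5`, FDR < 0.05 filters;
  ssGSEA (rank-weight walk, α = 0.25) of regulon target sets; Wilcoxon
  group comparison; cross-cohort intersection of direction-consistent
  regulons; targets appearing in ≥ 2 of them that are DE in every cohort
  are the hub targets, with Mann–Whitney AUC and stratified bootstrap
  CIs.

A first-class synthetic-data generator (`simulateTruth()`,
`simulateSingleCell()`, `simulateBulk()`, `simulateMotifTable()`) plants
known regulons, group effects, composition shifts and hub targets, so the
whole pipeline is testable end to end. See the methods vignette
(`vignettes/regulon-discovery.Rmd`) for models, parameter defaults and
design decisions.

## Worked example

```r
library(regulonDCM)

cfg <- defaultPipelineConfig(seed = 1L)   # reference synthetic conditions
res <- runFullPipeline(cfg)

res$regulons
#> RegulonSet with 40 regulons
#>   sizes: min 11 / median 25 / max 32 targets
#>   names: TF01(+), TF02(+), TF03(+), TF04(+), TF05(+) ...

head(res$vardecomp[order(-res$vardecomp$p_group),
     c("regulon", "p_celltype", "p_group", "p_resid", "module", "selected")])
#>    regulon p_celltype p_group p_resid module selected
#> 31 TF40(+)     0.0744  0.5201   0.405     M1     TRUE
#> 28 TF37(+)     0.1851  0.4490   0.366     M1     TRUE
#> 16 TF21(+)     0.1571  0.3870   0.456     M1     TRUE
#> 17 TF22(+)     0.1346  0.3802   0.485     M1    FALSE
#> 21 TF29(+)     0.2892  0.3409   0.370     M1    FALSE
#> 5  TF05(+)     0.0343  0.0306   0.935     M1    FALSE

res$hub_report$hubs
#> [1] "G0022" "G0276" "G0434" "G0961" "G1438" "G1545" "G1720" "G1753"
res$truth$hub_targets
#> [1] "G0022" "G0276" "G0961" "G1438" "G1545" "G1720" "G1753" "G1796" "G1926"
res$roc[["G0022"]][c("auc", "ci_low", "ci_high")]
#> $auc 1  $ci_low 1  $ci_high 1
```

Reading this run: from 3,000 simulated cells the pipeline retains 86
metacells, assembles 40 of the 50 planted regulons, and selects three
regulons whose activity variance is dominated by the disease group — all
three are truly responsive (the knee rule stops at the near-tie between
`TF21(+)` at 0.387 and `TF22(+)` at 0.380, so two weaker responsive
regulons are missed). Their shared targets that are differentially
expressed in both synthetic bulk cohorts recover 7 of the 9 planted hub
targets with one extra, and each recovered hub separates the groups with
AUC ≈ 1 in the 102-sample cohort. The planted cardiomyocyte composition
shift (59.2% of Normal cells vs 36.3% of DCM cells) is re-estimated from
the annotated cells as 60.3% vs 37.9%.

Every stage is also available as a standalone function
(`qcFilter()`, `clusterCells()`, `aggregateMetacells()`,
`inferImportance()`, `assembleRegulons()`, `rasMatrix()`, `csiMatrix()`,
`decomposeAll()`, `deModerated()`, `ssgseaScore()`, `hubTargets()`,
`rocBootstrapCI()`, `oraTest()`, ...), with on-disk interchange through
MTX, GMT, TSV and YAML readers/writers (`readCellMatrixMTX()`,
`readGMT()`, `readRegulonTable()`, `loadConfig()`).

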