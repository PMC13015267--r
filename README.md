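# bafdep

Chromatin accessibility at most cis-regulatory elements (cREs) depends on the
activity of BAF (mammalian SWI/SNF) chromatin remodeling complexes: acute
pharmacologic BAF inhibition causes rapid, widespread — but highly variable —
loss of ATAC-seq signal, concentrated at enhancers and strongest at "primed"
enhancers (H3K4me1+/H3K27ac−). `bafdep` is an R package for quantifying and
predicting this *BAF-dependence*. It is aimed at epigenomics analysts who have
peak-level ATAC-seq counts under a global-loss perturbation, a compendium of
TF/histone ChIP-seq peak sets, and (optionally) promoter-capture Hi-C links,
and who want to ask: **which regions lose accessibility, which chromatin
features predict the loss, and which genes are wired to the affected
elements?**

## What it implements

- **Interval core** — tibble-based genomic intervals (BED-convention 0-based
  half-open), overlap queries backed by `GenomicRanges`, largest-overlap
  assignment against chromatin-state segmentations, BED/narrowPeak readers
  and writers.
- **cRE annotation** — the TSS + ChIP-overlap decision tree: promoters
  (TSS-proximal ∧ H3K4me3), active enhancers (distal ∧ H3K4me1 ∧ H3K27ac),
  poised (H3K27me3 instead), primed (H3K4me1 only), CTCF-bound, unclassified;
  plus super-enhancer flags against the union of two reference sets.
- **Differential accessibility under global signal loss** — total-count
  normalization is invalid when most of the genome loses signal, so size
  factors are computed from ATAC counts at promoters of expression-invariant
  genes (FDR > 0.2 and < 20% change): `s_j ∝ Σ_{p ∈ invariant promoters}
  K_{pj}`, rescaled to geometric mean 1. Testing is negative-binomial
  (variance `μ + φμ²`) with a Cox–Reid-adjusted mean–dispersion trend,
  moderated per-feature dispersions, likelihood-ratio p-values, and BH FDR.
  Calls use FDR < 0.05 with |log2FC| > 1 (accessibility) or ≥ log2 1.5
  (expression).
- **Feature-importance framework** — binary peak × feature overlap matrix;
  FRiP-based selection among replicate ChIP experiments; class-balanced
  (undersampled) 70:15:15 split; random-forest grid search over
  `n_estimators ∈ {50,100,200,300}`, `max_depth ∈ {∞,10,20}`,
  `min_samples_leaf ∈ {1,2}`; accuracy/TPR/FPR/ROC/AUROC on the held-out
  test set; MDI and 10-repeat permutation importances; ridge regression
  (`β = (XᵀX + αI)⁻¹Xᵀy`, α = 1) averaged over ten 70% bootstrap subsets,
  ranking features from "predicts retained accessibility" (top 15) to
  "predicts loss" (bottom 15).
- **Tissue specificity** — the tau index on log2(TPM+1) medians,
  `τ = Σᵢ(1 − x̂ᵢ)/(n − 1)`, restriction at τ ≥ 0.8, and Fisher-exact
  enrichment of restricted expression among top model features.
- **Stimulus linking** — inducible gene/cRE sets at two timepoints,
  promoter-capture Hi-C link enrichment (matched vs mismatched stimulus
  pairs), per-gene median linked-cRE effects correlated with expression
  changes, distance-decile comparisons, covariate-stratified Wilcoxon
  contrasts with a max-Bonferroni summary, and the stimulus/response
  gene-set NES test.
- **Synthetic-data generator** — a fully seeded simulator with planted
  ground truth (cRE classes, per-feature effects, NB counts with depth
  factors, invariant genes, tissue regimes, coupled gene–cRE links) so
  every stage is testable without external downloads.

## Worked example

```r
library(bafdep)

res <- run_pipeline(run_config(seed = 1))
r <- res$results

# How much of the genome lost accessibility, and where?
table(r$atac_diff$call, r$annotation$cre_class)
mean(r$atac_diff$call == "down")
#> [1] 0.418

glance(r$rf)
#> # A tibble: 1 x 9
#>   accuracy auroc   tpr    fpr    tp    tn    fp    fn n_test
#>      <dbl> <dbl> <dbl>  <dbl> <int> <int> <int> <int>  <int>
#> 1    0.915 0.942 0.928 0.0984   168   165    18    13    364

head(r$ridge$bottom_features, 5)   # features that best predict loss
#> [1] "h3k4me1" "TF002"   "TF005"   "TF001"   "TF004"

r$link_enrichment[, c("gene_stimulus", "cre_stimulus", "odds_ratio")]
#>   gene_stimulus cre_stimulus odds_ratio
#> 1         stimA        stimA      7.22
#> 2         stimA        stimB      0.322
#> 3         stimB        stimA      0.253
#> 4         stimB        stimB      8.95
```

At the default study conditions (5,000 peaks, 55 TF features of which 5 drive
loss), 41.8% of peaks are called significantly lost; the random-forest
classifier separates BAF-dependent from -independent elements at AUROC 0.94
on held-out peaks; all five planted drivers rank in the ridge bottom-15 and
the MDI top-10; matched-stimulus gene–cRE link enrichment (OR ≈ 8.1) far
exceeds mismatched pairs (OR ≈ 0.29); and per-gene median linked-cRE
accessibility changes correlate with expression changes (r ≈ 0.36).

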