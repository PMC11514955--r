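# imgene

Spatial immunogenomic analysis of pathologic lymph-node (pN) metastasis in
lung adenocarcinoma primary tumors.

Whether a resected LUAD has spread to regional lymph nodes is a dominant
prognostic factor that is only confirmed after surgery. This package is for
computational oncologists who want to analyze — or prototype against — the
two preoperative modalities that together predict nodal stage from the
primary tumor itself: targeted-panel sequencing and multiplex
immunohistochemistry (mIHC) single-cell imaging. It implements the full
pipeline as reusable, tested R functions, plus a synthetic cohort generator
that plants the published effect sizes so every stage runs end-to-end
without patient data.

## What it computes

**Panel genomics** — per-patient mutation count; tumor mutational burden
`TMB = (nonsynonymous SNVs + indels) / 1.21 Mb`; intratumor heterogeneity
`MATH = 100 · 1.4826 · MAD(VAF) / median(VAF)`; per-gene group comparisons
(Fisher + Benjamini–Hochberg at q < 0.1); co-occurrence / mutual
exclusivity; oncogenic-pathway and OncoKB-style actionability summaries;
caliper propensity matching.

**Phenotyping** — `asinh(x/1)` transform, per-marker z-scoring, PCA with
iterative per-batch-per-cluster centroid correction, and deterministic
marker gating into 9 metaclusters (epithelial ± PD-L1, CD4 T, CD8 T, Treg,
macrophage ± PD-L1, other immune, other).

**Spatial analysis** — per-ROI Delaunay graphs; 4 µm interaction partners;
20-nearest-neighbour composition windows; K-means cellular neighbourhoods
(k = 10) with functional annotation; within-ROI label-permutation
interaction/avoidance tests (`z = (obs − null mean)/null SD`); Voronoi
topology maps with exact area conservation.

**TIME subtyping** — consensus non-negative matrix factorization (rank 2,
50 runs, multiplicative updates), consensus-matrix clustering with
silhouette quality, ROI-to-patient majority integration, and subtype
associations with nodal status, composition and mutations.

**ImGene predictor** — per-block top-10 feature selection, SVMs tuned by
leave-one-out cross-validation, min-max score calibration, logistic
integration `Pr = logistic(Z)`, `Z = 3.51 + β_Im·Im + β_Gene·Gene`, and
evaluation (AUC/F1/accuracy) against both monomodal baselines.

## Worked example

```r
library(imgene)
run <- run_pipeline(sim_config(), seed = 1, n_perm = 200)
print(run)
```

```
Pipeline run (seed 1)
Synthetic cohort: 257 patients (53 pN+), 92 imaged (586 ROIs, 46711 cells), 1093 alterations
genomics: genes at q<0.1:  
phenotype: macrophage 7.1% vs 4.6% (p=5.02e-05); Treg 0.85% vs 0.43% (p=6.63e-05)
subtype: silhouette 0.773, pN association p=0.000296
imgene: AUC 0.689 | F1 0.714 | accuracy 0.733 (cutoff 0.573)
```

Reading the output: the generator planted macrophage fractions of 7.1% vs
4.8% and Treg fractions of 0.85% vs 0.29% of total cells — the phenotype
stage recovers both with Mann–Whitney p < 10⁻⁴. The consensus-NMF stage
finds the two planted TIME archetypes (consensus silhouette 0.77) and
their coupling to nodal status (Fisher p ≈ 3×10⁻⁴). The empty q < 0.1
gene list is honest behavior: the planted TP53 contrast (55% vs 37% at
n = 53/204) sits near the detection boundary of a 14-gene FDR screen, so
individual cohorts often miss it. The ImGene AUC on a desk-scale synthetic
cohort is not comparable to real-cohort figures.

Scoring a patient with the published multivariable risk model:

```r
mdl <- pn_risk_model()
covs <- setNames(numeric(14), names(mdl$coefficients))
covs[c("Path_LVI", "PIK3CG")] <- 1
score_logistic(mdl, covs)
#> 0.7193      # lymphovascular invasion + PIK3CG mutation
score_logistic(mdl, setNames(numeric(14), names(mdl$coefficients)))
#> 0.04436     # baseline, all covariates zero
```

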