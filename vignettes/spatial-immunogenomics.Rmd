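---
title: "Methods: spatial immunogenomic analysis of nodal metastasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial immunogenomic analysis of nodal metastasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imgene)
```

## The problem

In resected lung adenocarcinoma (LUAD), pathologic lymph-node status (pN+
vs pN−) is a dominant prognostic factor, yet it is only known after
surgery. This package implements an integrated analysis of two preoperative
data modalities from the primary tumor — targeted-panel sequencing and
multiplex immunohistochemistry (mIHC) single-cell imaging — that together
characterize and predict nodal metastasis. The pipeline covers: panel
genomics summary statistics, single-cell phenotyping, spatial
neighbourhood and interaction analysis, consensus-NMF subtyping of the
tumor immune microenvironment (TIME), and the integrated "ImGene"
predictor. Because no patient-level data are publicly deposited for this
design, the package ships a synthetic cohort generator that plants the
published effect sizes, so every stage is testable end-to-end.

## Genomic statistics

* **Mutation count** is the number of alterations per patient
  (nonsynonymous SNVs, indels, CNVs, gene fusions).
* **TMB** divides the nonsynonymous SNV + indel count by the panel's
  covered footprint (1.21 Mb by default); CNVs and fusions enter the
  mutation count but not TMB, since TMB is defined in mutations per
  megabase.
* **MATH** (mutant-allele tumor heterogeneity) summarizes the dispersion
  of the variant-allele-frequency distribution as
  `100 · 1.4826 · MAD(v) / median(v)`, with the raw (unscaled) median
  absolute deviation inside. The 1.4826 consistency constant follows the
  standard MATH formulation; it is an argument (`mad_constant`) should a
  different convention be needed. MATH is undefined (NA) below 3 VAFs.
* Per-gene group comparisons use Fisher's exact test with
  Benjamini–Hochberg correction at q < 0.1; co-occurrence/mutual
  exclusivity uses per-pair Fisher tests signed by the log odds ratio.
* **Pathway aggregation** maps genes to oncogenic signaling pathways via a
  static, editable table (`default_pathway_map()`); variants of unknown
  significance are discarded before counting a patient as pathway-altered.
  Actionability levels (L1 > L3A > L3B > L4) are likewise a static table;
  samples are classified by their highest-level alteration.
* **Propensity matching** is greedy 1:1 nearest-neighbour on the logit
  propensity without replacement, caliper 0.2 SD; the match order is
  randomized because no order is canonical.

A note on the categorical tests: the package exposes both Fisher's exact
test and the Pearson chi-squared test. The characteristic-table p-values
this pipeline reproduces (0.775 for sex, 0.985 for smoking, 0.262 for
STAS) match the *uncorrected* chi-squared test, so that is the default for
table reproduction, while Fisher is used for sparse genomic tables.

The published multivariable nodal-risk model is available verbatim as
`pn_risk_model()` (intercept −3.07 through PIK3CG 2.66). Two of its
printed quantities are knowingly inconsistent: the tumor-size coefficient
is printed as −0.035 while its odds ratio is printed as 1.036 (implying
+0.035). The printed coefficient is used as printed; scoring functions do
not silently flip signs.

## Phenotyping

Marker intensities (PANCK, CD4, CD8, FOXP3, CD68, PD-L1) are transformed
with `asinh(x / cofactor)`, cofactor 1, then z-scored per marker.
Metaclusters are assigned by deterministic gating at z > 0.5 with a fixed
precedence — PANCK (epithelial, PD-L1 subsplit), then CD68 (macrophage,
PD-L1 subsplit), then CD4⁺FOXP3⁺ (Treg), CD4⁺, CD8⁺, any remaining
marker-positive cell (other immune), else other — yielding the 9-class
label set. Gating was chosen over unsupervised clustering because the
panel is small and every class has a textbook marker definition; the
threshold and rules are arguments. "Immune cells" are all non-epithelial,
non-Other labels; that denominator choice matters for composition
fractions and is explicit in `composition_compare()`.

Batch structure is removed in PCA space (top 20 components, capped at the
marker count): iterative soft clustering followed by per-batch,
per-cluster centroid alignment, five rounds. With one batch the correction
is the identity. The correction aligns batch centroids globally and per
cluster; it is validated in the tests by planting an additive shift on a
balanced two-batch mixture and checking that a cross-validated classifier
can no longer tell batches apart, while silhouette by true cell class is
preserved.

## Spatial analysis

Adjacency is the Delaunay triangulation of cell centroids per ROI
(`deldir`), with a nearest-neighbour fallback below 3 non-collinear cells
and a 1e−6 µm jitter for duplicate coordinates. Interaction partners can
be restricted to edges of at most 4 µm. Cellular neighbourhoods (CNs)
aggregate each cell's k = 20 nearest cells (center included, both
configurable) into a composition window; windows from all ROIs are
clustered jointly by K-means with k = 10 and 10 restarts. CN integer
labels are arbitrary, so annotation keys on the dominant metacluster with
functional groups (epithelial, macrophage-and-T, immune-suppressed, T);
ties break toward the cohort-wide rarer class.

The interaction/avoidance test shuffles metacluster labels within each ROI
(geometry fixed), recomputes pairwise adjacency counts, and reports
z = (obs − null mean)/null SD with the +1-corrected empirical two-sided
p-value, 1000 permutations by default. Group-level direction is the
majority over significant ROIs. The per-pair statistic is checked against
an exhaustive-permutation oracle on toy ROIs, and its type-I error is
calibrated on label-shuffled data in the acceptance suite.

Voronoi maps clip every tile to the ROI bounding box, so tile areas sum
exactly to the box area — the tests assert conservation to 1e−6 relative.

## TIME subtyping

The ROI × metacluster fraction matrix is factorized by rank-2 NMF
(multiplicative updates, Frobenius objective, tolerance 1e−6, at most 500
iterations; a KL-divergence objective is available as an option), 50 runs
from seeded random initializations. Each run clusters ROIs by the largest
scale-normalized basis coefficient; the consensus matrix records
co-clustering fractions; final labels cut the 1 − consensus distance by
average-linkage hierarchical clustering, and cluster quality is the mean
silhouette width on consensus distances. Structureless inputs (identical
rows) are flagged degenerate. Patient labels integrate ROI labels by
majority vote, ties broken toward the subtype with higher mean consensus
confidence.

## The ImGene predictor

Per block (image features: metacluster fractions of total and immune
cells; genomic features: driver indicators plus mutation count, TMB,
MATH), features are ranked by the magnitude of their standardized
univariable logistic coefficient on the training split and the top 10
kept. Each block trains an SVM tuned by leave-one-out cross-validated
accuracy over C ∈ {0.01, 0.1, 1, 10, 100}, kernel ∈ {linear, radial},
gamma ∈ {0.001, 0.01, 0.1, 1} — the parameters named by the design; the
grid itself is a package choice. Decision scores are min-max calibrated to
[0, 1] on training scores so the two blocks are commensurate; the
integration is a logistic regression on the two calibrated scores, with
the published form Z = 3.51 + β_Im·Im + β_Gene·Gene, Pr = logistic(Z); the
intercept is overridable to the printed 3.51 for formula-level checks
(`integrate_scores()`). Classification cutoffs maximize validation-split
accuracy (ties take the lower cutoff). Evaluation reports rank-based AUC
(checked against an exhaustive concordance oracle), F1 and accuracy, for
ImGene and both monomodal baselines.

## The synthetic cohort generator

The generator reproduces the study conditions: 257 patients (204 pN−, 53
pN+), a 92-patient imaged subset split 46/46 (mirroring 1:1 matching),
5–8 ROIs per patient (~597 ROIs cohort-wide), a 1.21 Mb panel. Planted
parameters are the published effect sizes: TP53 55% vs 37%, PIK3CG 7.5%
vs 0.5% (other drivers at their cohort frequencies with no group effect);
Poisson nonsynonymous counts with means 5.74/3.82 so count medians land
at 6/4 and TMB medians near 4.74/3.16 mutations/Mb; Beta-distributed VAFs
with shapes (1.7, 5.1) vs (2.05, 6.15), calibrated once so MATH medians
land near 53.5/45.7; macrophage 7.1% vs 4.8% and Treg 0.85% vs 0.29% of
total cells with immune infiltrate near 36.5%/31.1%.

Composition is generated through a latent two-archetype TIME structure —
an epithelial archetype and a macrophage-enriched immune archetype — with
archetype probability 0.25 (pN−) vs 0.70 (pN+). The two archetype
compositions are solved from the group-level targets so the group means
are preserved in expectation; the Treg fraction is tied directly to the
nodal group (its contrast is a per-group quantity, and rare-class
bimodality would otherwise dominate its sampling noise). Per-patient
compositions are Dirichlet draws (concentration 800) around the archetype;
floors at 1e−3 keep every Dirichlet component non-degenerate.

Spatially, epithelial cells form Thomas-process tumor nests (3 parents,
25 µm spread); in pN+ ROIs macrophages are drawn toward nests and
Tregs/PD-L1⁺ macrophages co-locate at an immune-suppressed niche (60% of
cells, 15 µm spread); everything else is uniform. Marker intensities are
log-normal around a 9 × 6 profile matrix (positive ≈ 40 counts,
background ≈ 2, sdlog 0.2 — at which the default gates recover ≥ 95% of
true labels), multiplied by per-batch log-normal shifts (4 batches,
sdlog 0.25). Default ROI scale is Poisson(80) cells in a 200 µm square —
roughly 500 cells per patient, far below real mIHC yields but enough to
power the composition contrasts; all sizes are configuration, and the
test and acceptance suites run at this scale. A `null_effects`
configuration removes every group difference for type-I calibration.

What the generator does **not** emulate: segmentation and phenotyping
errors beyond log-normal intensity noise (no spillover, no doublets),
tissue architecture beyond nests and niches, spatially varying cell
density, ROI-to-ROI correlation within a slide beyond the shared patient
composition, and real per-ROI cell counts. Passing recovery tests
therefore show that the pipeline detects the planted structure at desk
scale, not that it would behave identically on real images.

## Known limitations and honest outcomes

The acceptance suite re-detects each planted effect across 20 seeded
full-scale cohorts. The macrophage and Treg contrasts are recovered at
their stated levels in ≥ 90% of seeds. The gene-frequency contrasts are
not: Bernoulli resampling of TP53 at 55% vs 37% (n = 53/204) gives a
Fisher p near 0.02, which survives a 14-gene Benjamini–Hochberg
correction at q < 0.1 in only about half of the seeds, and PIK3CG at
7.5% vs 0.5% reaches p < 0.05 in about 85% of seeds. Those two
assertions fail by design rather than being weakened: a single observed
cohort at those rates does not imply 90% replicability. The ImGene AUC on
synthetic cohorts (~0.7 at default scale) is not comparable to any real
cohort's figure and is not treated as a target.
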