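Package: imgene
Title: Spatial Immunogenomic Analysis of Lymph-Node Metastasis in Lung Adenocarcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for spatial immunogenomic analysis of
    lymph-node (pN) status in lung adenocarcinoma primary tumors. Provides
    panel-NGS summary statistics (tumor mutational burden, MATH intratumor
    heterogeneity, gene-frequency and co-occurrence tests, oncogenic-pathway
    and actionability summaries, propensity matching), multiplex
    immunohistochemistry single-cell phenotyping (asinh transformation,
    PCA-space batch correction, marker-gate metaclustering), spatial analysis
    (Delaunay graphs, neighbourhood windows, cellular-neighbourhood K-means,
    permutation interaction tests, Voronoi maps), consensus non-negative matrix
    factorization subtyping of the tumor immune microenvironment, and the
    integrated ImGene SVM + logistic predictor of nodal stage. Includes a
    synthetic cohort generator that plants the published effect sizes so every
    stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    deldir,
    FNN,
    cluster,
    e1071,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
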