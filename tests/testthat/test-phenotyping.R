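toy_cells <- function(z) {
  # build a cell table whose transformed z-scores are controlled directly
  colnames(z) <- marker_names()
  z
}

test_that("transform_markers applies asinh then per-marker standardization", {
  co <- small_cohort()
  emb <- transform_markers(co$cells, cofactor = 1)
  expect_equal(asinh(1), 0.8814, tolerance = 1e-4)
  expect_equal(unname(emb$asinh[1, 1]), asinh(co$cells$panck[1]))
  expect_true(all(abs(colMeans(emb$z)) < 1e-8))
  expect_true(all(abs(apply(emb$z, 2, sd) - 1) < 1e-8))
  # zero intensity transforms to zero before scaling
  cells0 <- co$cells; cells0$panck[1] <- 0
  expect_equal(unname(transform_markers(cells0)$asinh[1, "panck"]), 0)
  # zero-variance marker becomes all-zero z-scores
  cells1 <- co$cells; cells1$pdl1 <- 5
  expect_true(all(transform_markers(cells1)$z[, "pdl1"] == 0))
  expect_error(transform_markers(co$cells[, -7]), "marker columns")
})

test_that("metacluster gating follows the declared precedence", {
  hi <- 2; lo <- -1
  z <- rbind(
    c(hi, lo, lo, lo, lo, hi),   # PANCK+ PD-L1+  -> PDL1pos_Epithelial
    c(hi, hi, lo, lo, lo, lo),   # PANCK wins     -> Epithelial
    c(lo, hi, lo, hi, lo, lo),   # CD4+FOXP3+     -> Treg
    c(lo, hi, lo, lo, lo, lo),   # CD4+           -> CD4_T
    c(lo, lo, hi, lo, lo, lo),   # CD8+           -> CD8_T
    c(lo, hi, lo, hi, hi, lo),   # CD68 beats Treg-> Macrophage
    c(lo, lo, lo, lo, hi, hi),   # CD68+PD-L1+    -> PDL1pos_Macrophage
    c(lo, lo, lo, hi, lo, lo),   # FOXP3 only     -> Other_Immune
    c(lo, lo, lo, lo, lo, lo))   # nothing        -> Other
  lab <- assign_metaclusters(toy_cells(z))
  expect_equal(lab, c("PDL1pos_Epithelial", "Epithelial", "Treg", "CD4_T",
                      "CD8_T", "Macrophage", "PDL1pos_Macrophage",
                      "Other_Immune", "Other"))
  # permutation invariance over cell order
  perm <- c(5, 3, 9, 1, 7, 2, 8, 6, 4)
  expect_equal(assign_metaclusters(toy_cells(z[perm, ])), lab[perm])
})

test_that("gating recovers the generator's planted metaclusters", {
  co <- small_cohort()
  lab <- assign_metaclusters(transform_markers(co$cells))
  expect_gte(mean(lab == co$truth$cell_metacluster$true_metacluster), 0.95)
})

test_that("batch correction removes a planted additive shift", {
  # balanced two-batch mixture with a pure additive shift on every marker
  co <- small_cohort()
  set.seed(91)
  idx <- sample(nrow(co$cells), 2400)
  cells <- co$cells[idx, ]
  truth <- co$truth$cell_metacluster$true_metacluster[idx]
  z <- transform_markers(cells)$z
  batch <- rep(c("A", "B"), length.out = nrow(z))
  z[batch == "B", ] <- z[batch == "B", ] + 0.8
  ec <- embed_and_correct(z, batch)
  expect_equal(dim(ec$corrected), dim(ec$pcs))

  # cross-validated logistic batch predictability drops toward chance
  batch_acc <- function(scores) {
    b <- as.numeric(batch == "A")
    half <- seq_len(floor(length(b) / 2))
    fit <- suppressWarnings(glm(b[half] ~ scores[half, ],
                                family = binomial()))
    pred <- plogis(cbind(1, scores[-half, ]) %*% coef(fit)) > 0.5
    mean(pred == b[-half])
  }
  expect_gt(batch_acc(ec$pcs), 0.75)       # the shift is detectable
  expect_lt(batch_acc(ec$corrected), 0.6)  # and removed

  # separability of true metaclusters is not destroyed
  sub <- sample(nrow(z), 1200)
  sil <- function(m) {
    s <- cluster::silhouette(as.integer(factor(truth[sub])),
                             dist(m[sub, , drop = FALSE]))
    mean(s[, "sil_width"])
  }
  expect_gte(sil(ec$corrected), sil(ec$pcs) - 0.1)
})

test_that("cohort batch-centroid offsets shrink after correction", {
  co <- small_cohort()
  idx <- seq_len(4000)
  cells <- co$cells[idx, ]
  ec <- embed_and_correct(transform_markers(cells), cells$batch_id)
  offset <- function(m) {
    ag <- aggregate(m, list(cells$batch_id), mean)
    d <- as.matrix(ag[, -1])
    mean(sqrt(rowSums(sweep(d, 2, colMeans(m))^2)))
  }
  expect_lt(offset(ec$corrected), 0.2 * offset(ec$pcs))
})

test_that("single-batch correction is the identity", {
  co <- small_cohort()
  cells <- co$cells[1:500, ]
  emb <- transform_markers(cells)
  ec <- embed_and_correct(emb, rep("B1", nrow(cells)))
  expect_identical(ec$pcs, ec$corrected)
})

test_that("composition_compare arithmetic and denominators", {
  labels <- c(rep("Epithelial", 4), rep("Macrophage", 3), rep("CD8_T", 2),
              "Treg")
  pats <- rep("P1", 10)
  groups <- c(P1 = "pos", P2 = "neg")
  labels <- c(labels, "Epithelial", "Macrophage")
  pats <- c(pats, "P2", "P2")
  cc <- composition_compare(labels, pats, groups, "total")
  expect_equal(unname(cc$fractions["P1", "Macrophage"]), 0.3)
  expect_equal(unname(rowSums(cc$fractions)), c(1, 1))
  ci <- composition_compare(labels, pats, groups, "immune")
  expect_equal(unname(ci$fractions["P1", "Macrophage"]), 0.5)
  # a patient with no immune cells is excluded under the immune denominator
  labels2 <- c(labels, "Other", "Other")
  pats2 <- c(pats, "P3", "P3")
  ci2 <- composition_compare(labels2, pats2, c(groups, P3 = "neg"), "immune")
  expect_false("P3" %in% rownames(ci2$fractions))
  expect_error(composition_compare(labels, pats, groups["P1"]), "group")
})

test_that("planted macrophage and Treg enrichment shows at reduced scale", {
  # at this reduced subset the direction and magnitude of the planted
  # effects are stable; their significance is exercised at full cohort
  # scale in the acceptance suite
  co <- small_cohort()
  lab <- assign_metaclusters(transform_markers(co$cells))
  groups <- setNames(co$clinical$pn, co$clinical$patient_id)
  cc <- composition_compare(lab, co$cells$patient_id, groups, "total")
  tt <- cc$tests
  expect_gt(tt$mean_pos[tt$metacluster == "Macrophage"],
            tt$mean_neg[tt$metacluster == "Macrophage"])
  expect_gt(tt$mean_pos[tt$metacluster == "Treg"],
            tt$mean_neg[tt$metacluster == "Treg"])
  # recovered fractions sit near the planted group targets
  expect_equal(tt$mean_pos[tt$metacluster == "Macrophage"], 0.071,
               tolerance = 0.5)
  expect_equal(tt$mean_neg[tt$metacluster == "Macrophage"], 0.048,
               tolerance = 0.5)
})
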