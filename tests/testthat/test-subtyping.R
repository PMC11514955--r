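test_that("nmf_fit reconstructs low-rank non-negative structure", {
  set.seed(71)
  W0 <- matrix(runif(40, 0, 2), 20, 2)
  H0 <- matrix(runif(18, 0, 2), 2, 9)
  V <- W0 %*% H0
  f <- nmf_fit(V, rank = 2, objective = "frobenius", max_iter = 2000)
  expect_lt(sum((V - f$W %*% f$H)^2) / sum(V^2), 1e-3)
  fkl <- nmf_fit(V, rank = 2, objective = "kl", max_iter = 2000)
  expect_lt(sum((V - fkl$W %*% fkl$H)^2) / sum(V^2), 1e-2)
  expect_error(nmf_fit(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("cnmf recovers the block fixture exactly for every seed", {
  V <- block_composition()
  truth <- rep(1:2, each = 12)
  for (s in 1:3) {
    res <- cnmf(V, rank = 2, iters = 20, seed = s)
    # perfect two-way recovery up to label swap
    agree <- max(mean(res$labels == truth), mean(res$labels == 3 - truth))
    expect_equal(agree, 1)
    expect_gt(res$silhouette, 0.9)
    # consensus is (near) block identity
    within <- c(res$consensus[1:12, 1:12], res$consensus[13:24, 13:24])
    across <- res$consensus[1:12, 13:24]
    expect_gt(min(within), 0.95)
    expect_lt(max(across), 0.05)
  }
})

test_that("cnmf consensus contract and degeneracy flag", {
  V <- block_composition()
  res <- cnmf(V, rank = 2, iters = 10, seed = 1)
  expect_true(isSymmetric(res$consensus))
  expect_equal(unname(diag(res$consensus)), rep(1, 24))
  expect_true(all(res$consensus >= 0 & res$consensus <= 1))

  # ROI reordering permutes labels consistently
  perm <- sample(24)
  res_p <- cnmf(V[perm, ], rank = 2, iters = 10, seed = 1)
  expect_equal(length(unique(paste(res$labels[perm], res_p$labels))), 2)

  # identical rows: no structure, flagged degenerate
  V0 <- matrix(rep(c(0.5, 0.2, 0.1, 0.05, 0.05, 0.04, 0.03, 0.02, 0.01),
                   each = 10), nrow = 10)
  res0 <- cnmf(V0, rank = 2, iters = 10, seed = 1)
  expect_true(res0$degenerate)
  expect_lte(res0$silhouette, 0)

  expect_error(cnmf(V[1:2, ], rank = 2), "rank \\+ 1")
  expect_error(cnmf(-V, rank = 2), "non-negative")
})

test_that("ROI labels integrate to patients by majority with confidence ties", {
  cons <- diag(5)
  cons[1, 2] <- cons[2, 1] <- 0.9   # subtype-1 ROIs tightly co-cluster
  # R4 (label 1) co-clusters strongly with the subtype-1 ROIs; R5 (label 2)
  # only weakly with the subtype-2 ROI R3
  cons[4, 1] <- cons[1, 4] <- 0.8
  cons[4, 2] <- cons[2, 4] <- 0.8
  cons[5, 3] <- cons[3, 5] <- 0.1
  res <- structure(list(
    consensus = cons, labels = c(1L, 1L, 2L, 1L, 2L), rank = 2,
    silhouette = 0.5, degenerate = FALSE, iters = 10,
    roi_ids = paste0("R", 1:5)), class = "subtype_result")
  map <- setNames(c("A", "A", "A", "B", "B"), paste0("R", 1:5))
  got <- integrate_roi_labels(res, map)
  expect_equal(got[["A"]], 1L)   # majority 2:1
  # patient B ties 1:1; subtype 1 has higher mean consensus confidence
  expect_equal(got[["B"]], 1L)
  # single-ROI patient keeps its ROI label
  map2 <- setNames(c("A", "A", "A", "B", "C"), paste0("R", 1:5))
  expect_equal(integrate_roi_labels(res, map2)[["C"]], 2L)
  expect_error(integrate_roi_labels(res, map[1:3]), "map")
})

test_that("subtype associations detect the planted archetype-pN coupling", {
  co <- small_cohort()
  arch <- co$truth$patient_archetype
  cells <- co$cells
  cells$metacluster <- assign_metaclusters(transform_markers(cells))
  lev <- metacluster_levels()
  pc <- table(cells$patient_id, factor(cells$metacluster, lev))
  pc <- sweep(as.matrix(pc), 1, rowSums(pc), `/`)
  res <- subtype_associations(arch, co$clinical, patient_composition = pc,
                              muts = co$mutations)
  expect_lt(res$pn_test$p_value, 0.05)
  ct <- res$composition_tests
  # immune-enriched archetype: more macrophages, fewer epithelial cells
  expect_gt(ct$mean_subtype2[ct$metacluster == "Macrophage"],
            ct$mean_subtype1[ct$metacluster == "Macrophage"])
  expect_lt(ct$mean_subtype2[ct$metacluster == "Epithelial"],
            ct$mean_subtype1[ct$metacluster == "Epithelial"])
  expect_lt(ct$p[ct$metacluster == "Epithelial"], 0.05)
})

test_that("per-gene subtype comparison flags a planted enrichment", {
  set.seed(73)
  pats <- sprintf("P%02d", 1:60)
  subtype <- setNames(rep(1:2, each = 30), pats)
  clin <- data.frame(patient_id = pats,
                     pn = sample(c("pos", "neg"), 60, TRUE),
                     stringsAsFactors = FALSE)
  mutated <- c(sample(pats[1:30], 2), sample(pats[31:60], 14))
  muts <- data.frame(patient_id = mutated, gene = "PIK3CG",
                     class = "nonsynonymous_snv", vaf = 0.2,
                     oncogenic = "oncogenic", level = "L3B",
                     stringsAsFactors = FALSE)
  res <- subtype_associations(subtype, clin, muts = muts)
  gt <- res$gene_tests
  expect_lt(gt$p[gt$gene == "PIK3CG"], 0.05)
  expect_gt(gt$freq_subtype2[gt$gene == "PIK3CG"],
            gt$freq_subtype1[gt$gene == "PIK3CG"])

  # a subtype with fewer than 2 patients skips associations with a warning
  st <- setNames(c(1L, rep(2L, 59)), pats)
  expect_warning(r0 <- subtype_associations(st, clin), "skipped")
  expect_null(r0$pn_test)
})
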