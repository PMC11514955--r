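test_that("build_graph produces the Delaunay edge set", {
  g3 <- build_graph(c(0, 1, 0.5), c(0, 0, 1))
  expect_equal(nrow(g3$edges), 3)
  expect_equal(as.integer(table(c(g3$edges))), rep(2L, 3))  # each degree 2

  # unit square: 4 sides + 1 diagonal
  g4 <- build_graph(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(nrow(g4$edges), 5)

  # contract: i < j, no self edges, unique
  set.seed(61)
  g <- build_graph(runif(40, 0, 100), runif(40, 0, 100))
  expect_true(all(g$edges[, 1] < g$edges[, 2]))
  expect_false(anyDuplicated(g$edges) > 0)
  expect_equal(g$lengths,
               sqrt((g$x[g$edges[, 1]] - g$x[g$edges[, 2]])^2 +
                    (g$y[g$edges[, 1]] - g$y[g$edges[, 2]])^2))

  # duplicate coordinates are jittered, not fatal
  set.seed(62)
  gd <- build_graph(c(5, 5, 1, 9), c(5, 5, 1, 9))
  expect_gte(nrow(gd$edges), 3)
})

test_that("interaction_partners prunes by contact radius", {
  g <- build_graph(c(0, 3, 10), c(0, 0, 0))
  p4 <- interaction_partners(g, radius = 4)
  expect_equal(nrow(p4$edges), 1)
  expect_equal(p4$lengths, 3)
  expect_equal(interaction_partners(g, radius = Inf)$edges, g$edges)
  expect_error(interaction_partners(g, radius = 0), "positive")
})

test_that("neighbourhood windows are normalized compositions", {
  # homogeneous ROI: every window is one-hot
  set.seed(63)
  w <- neighborhood_windows(runif(30), runif(30), rep("CD8_T", 30), k = 10)
  expect_true(all(w[, "CD8_T"] == 1))
  expect_true(all(abs(rowSums(w) - 1) < 1e-12))

  # center cell with 10 epithelial + 10 macrophage equidistant neighbours
  th <- seq(0, 2 * pi, length.out = 21)[-21]
  x <- c(0, cos(th)); y <- c(0, sin(th))
  labs <- c("Treg", rep(c("Epithelial", "Macrophage"), 10))
  w2 <- neighborhood_windows(x, y, labs, k = 20, include_self = FALSE)
  expect_equal(unname(w2[1, "Epithelial"]), 0.5)
  expect_equal(unname(w2[1, "Macrophage"]), 0.5)

  # ROI smaller than k: window covers the whole ROI
  w3 <- neighborhood_windows(runif(5), runif(5),
                             c("Treg", rep("CD4_T", 4)), k = 20)
  expect_equal(unname(w3[, "Treg"]), rep(0.2, 5))

  # rigid motions leave windows unchanged
  set.seed(64)
  x <- runif(50, 0, 100); y <- runif(50, 0, 100)
  labs <- sample(metacluster_levels(), 50, replace = TRUE)
  w4 <- neighborhood_windows(x, y, labs, k = 15)
  a <- 0.7
  xr <- 12 + x * cos(a) - y * sin(a); yr <- -3 + x * sin(a) + y * cos(a)
  expect_equal(neighborhood_windows(xr, yr, labs, k = 15), w4)
})

test_that("cluster_cns recovers constructed spatial partitions", {
  # two segregated regions with distinct pure compositions
  set.seed(65)
  n <- 60
  x <- c(runif(n, 0, 40), runif(n, 160, 200)); y <- runif(2 * n, 0, 50)
  labs <- rep(c("Epithelial", "Macrophage"), each = n)
  w <- neighborhood_windows(x, y, labs, k = 10)
  cn <- cluster_cns(w, k_cn = 2, seed = 1)
  expect_equal(length(unique(cn$cn[1:n])), 1)
  expect_equal(length(unique(cn$cn[(n + 1):(2 * n)])), 1)
  expect_false(cn$cn[1] == cn$cn[n + 1])

  # permuting cells gives the same partition up to relabeling
  perm <- sample(2 * n)
  cn2 <- cluster_cns(w[perm, ], k_cn = 2, seed = 1)
  expect_equal(length(unique(paste(cn$cn[perm], cn2$cn))), 2)

  expect_equal(unique(cluster_cns(w, k_cn = 1, seed = 1)$cn), 1L)
  expect_warning(cluster_cns(w[c(1, 1, 1, n + 1), ], k_cn = 3, seed = 1),
                 "distinct windows")
})

test_that("annotate_cns maps dominant compositions to functional groups", {
  lev <- metacluster_levels()
  mk <- function(v) { names(v) <- lev; v }
  w <- rbind(
    mk(c(0.8, 0.05, 0.02, 0.02, 0.01, 0.05, 0.01, 0.02, 0.02)),
    mk(c(0.1, 0.05, 0.1, 0.05, 0.5, 0.2, 0, 0, 0)),
    mk(c(0.1, 0.05, 0.15, 0.15, 0.02, 0.45, 0.03, 0.02, 0.03)),
    mk(c(0.1, 0.05, 0.45, 0.3, 0.02, 0.02, 0.01, 0.02, 0.03)))
  asn <- structure(list(cn = c(1L, 2L, 3L, 4L), windows = w,
                        centers = w, k_cn = 4L), class = "cn_assignment")
  ann <- annotate_cns(asn)
  expect_equal(ann$functional_group,
               c("Epithelial-CN", "Immune-suppressed-CN", "MF_and_T-CN",
                 "T-CN"))
  expect_equal(ann$dominant[2], "Treg")
})

test_that("interaction_test matches the exhaustive permutation oracle", {
  # toy ROI, 7 cells: two tight A-B pairs force attraction
  cells <- data.frame(
    roi_id = "R1",
    x_um = c(0, 1, 10, 11, 5, 20, 21),
    y_um = c(0, 0, 10, 10, 18, 0, 1),
    metacluster = c("Epithelial", "Macrophage", "Epithelial", "Macrophage",
                    "CD8_T", "Epithelial", "Macrophage"),
    stringsAsFactors = FALSE)
  res <- interaction_test(cells, n_perm = 4000, seed = 2)
  g <- build_graph(cells$x_um, cells$y_um)
  oc <- oracle_interaction(cells$metacluster, g$edges, "Epithelial",
                           "Macrophage")
  row <- res$per_roi[res$per_roi$type_a == "Epithelial" &
                       res$per_roi$type_b == "Macrophage", ]
  expect_equal(row$observed, oc$obs)
  expect_equal(row$null_mean, oc$null_mean, tolerance = 0.05)
  expect_equal(row$p, oc$p_two, tolerance = 0.03)
  expect_gt(row$z, 0)

  # single-metacluster ROI yields an empty result
  mono <- data.frame(roi_id = "R1", x_um = runif(10), y_um = runif(10),
                     metacluster = "Epithelial", stringsAsFactors = FALSE)
  expect_null(interaction_test(mono, n_perm = 50, seed = 1)$per_roi)
})

test_that("planted macrophage-epithelial contact shows up as interaction", {
  cfg <- sim_config(cells_per_roi = 120, contact_frac = 0.9,
                    contact_sd_um = 8)
  set.seed(66)
  rois <- do.call(rbind, lapply(1:6, function(r) {
    roi <- simulate_roi(cfg, group = "pos", roi_id = paste0("R", r))
    roi$metacluster <- roi$true_metacluster
    roi
  }))
  res <- interaction_test(rois, n_perm = 400, seed = 3)
  cmb <- res$combined
  row <- cmb[cmb$pair == "Epithelial:Macrophage", ]
  expect_equal(row$direction, "interaction")
  expect_gt(row$mean_z, 0)
})

test_that("voronoi tessellation conserves area and contains generators", {
  vm <- voronoi_map(c(25, 75, 75, 25), c(25, 25, 75, 75),
                    bbox = c(0, 100, 0, 100))
  expect_equal(sort(vm$areas), rep(2500, 4))
  set.seed(67)
  x <- runif(40, 0, 200); y <- runif(40, 0, 200)
  vm2 <- voronoi_map(x, y, bbox = c(0, 200, 0, 200))
  expect_equal(sum(vm2$areas), 200 * 200, tolerance = 1e-6)
  for (i in seq_along(x))
    expect_true(point_in_polygon(x[i], y[i], vm2$polygons[[i]]$x,
                                 vm2$polygons[[i]]$y))
  expect_error(voronoi_map(1:3, 1:3), "at least 4")
})

test_that("CN abundances couple to their dominant metacluster across patients", {
  co <- small_cohort()
  cells <- co$cells
  cells$metacluster <- assign_metaclusters(transform_markers(cells))
  rois <- split(seq_len(nrow(cells)), cells$roi_id)
  w <- do.call(rbind, lapply(rois, function(i)
    neighborhood_windows(cells$x_um[i], cells$y_um[i],
                         cells$metacluster[i], k = 20)))
  ord <- unlist(rois, use.names = FALSE)
  w <- w[order(ord), , drop = FALSE]
  cn <- cluster_cns(w, k_cn = 6, seed = 2)
  groups <- setNames(co$clinical$pn, co$clinical$patient_id)
  res <- cn_group_analysis(cn, cells$patient_id, groups, cells$metacluster,
                           muts = co$mutations)
  expect_equal(nrow(res$group_tests), 6)
  expect_true(all(abs(rowSums(res$frequencies) - 1) < 1e-9))
  # at least one CN strongly tracks its dominant metacluster's proportion
  rho <- res$metacluster_correlation
  expect_gt(max(rho$rho), 0.5)
  expect_true(is.data.frame(res$gene_tests) || is.null(res$gene_tests))
  # a perfectly monotone abundance-proportion pair gives rho = 1
  expect_equal(unname(spearman_cor(1:15, (1:15)^2)$estimate), 1)
})
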