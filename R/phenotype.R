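#' Single-cell marker transformation
#'
#' Applies `asinh(intensity / cofactor)` to each marker, then z-scores each
#' marker across all cells. Zero-variance markers get z-score 0.
#'
#' @param cells cell table with the six marker columns (see [marker_names()]).
#' @param cofactor asinh cofactor (default 1).
#' @return list of class `cell_embedding`: `z` (cells x markers z-scored
#'   matrix), `asinh` (pre-scaling), `cofactor`.
#' @export
transform_markers <- function(cells, cofactor = 1) {
  mk <- marker_names()
  if (!all(mk %in% colnames(cells)))
    stop("cell table lacks marker columns: ",
         paste(setdiff(mk, colnames(cells)), collapse = ", "), call. = FALSE)
  raw <- as.matrix(cells[, mk])
  if (any(raw < 0)) stop("marker intensities must be non-negative", call. = FALSE)
  a <- asinh(raw / cofactor)
  z <- scale(a)
  sd0 <- attr(z, "scaled:scale") == 0 | !is.finite(attr(z, "scaled:scale"))
  if (any(sd0)) z[, sd0] <- 0
  structure(list(z = unclass(z)[, , drop = FALSE], asinh = a,
                 cofactor = cofactor), class = "cell_embedding")
}

#' PCA embedding with iterative batch correction
#'
#' Projects transformed markers onto the top principal components (20, or
#' the marker count if fewer) and removes batch structure in PC space by
#' iteratively soft-clustering cells and aligning per-batch cluster
#' centroids to the global cluster centroid - the scheme popularized for
#' single-cell batch integration. A single batch makes the correction the
#' identity.
#'
#' @param embedding a `cell_embedding` from [transform_markers()], or a
#'   numeric matrix of transformed values.
#' @param batch per-cell batch labels.
#' @param n_pc number of principal components (capped at the marker count).
#' @param n_clusters soft-clustering cluster count.
#' @param iterations correction rounds.
#' @return list of class `corrected_embedding`: `pcs` (raw PC scores),
#'   `corrected` (batch-corrected scores, same shape), `rotation`, `batch`.
#' @export
embed_and_correct <- function(embedding, batch, n_pc = 20, n_clusters = 9,
                              iterations = 5) {
  z <- if (inherits(embedding, "cell_embedding")) embedding$z else
    as.matrix(embedding)
  batch <- as.character(batch)
  if (nrow(z) != length(batch))
    stop("batch labels must match cell count", call. = FALSE)
  n_pc <- min(n_pc, ncol(z), nrow(z) - 1)
  pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  corrected <- scores
  if (length(unique(batch)) >= 2) {
    corrected <- correct_batch(scores, batch, n_clusters = n_clusters,
                               iterations = iterations)
  }
  structure(list(pcs = scores, corrected = corrected,
                 rotation = pc$rotation[, seq_len(n_pc), drop = FALSE],
                 batch = batch),
            class = "corrected_embedding")
}

# Iterative soft k-means + per-batch-per-cluster centroid alignment in PC
# space. Responsibilities are a softmax of negative squared distances to the
# cluster centroids; each round subtracts, per cell, the responsibility-
# weighted offset of its batch's cluster centroid from the global one.
correct_batch <- function(scores, batch, n_clusters = 9, iterations = 5,
                          temperature = NULL) {
  x <- scores
  batches <- unique(batch)
  n_clusters <- min(n_clusters, nrow(x) - 1)
  for (it in seq_len(iterations)) {
    km <- suppressWarnings(stats::kmeans(x, centers = n_clusters,
                                         nstart = 3, iter.max = 30))
    d2 <- outer(rowSums(x^2), rowSums(km$centers^2), `+`) -
      2 * x %*% t(km$centers)
    if (is.null(temperature)) temperature <- stats::median(d2)
    r <- exp(-(d2 - apply(d2, 1, min)) / max(temperature, 1e-8))
    r <- r / rowSums(r)
    shift <- matrix(0, nrow(x), ncol(x))
    for (k in seq_len(n_clusters)) {
      wk <- r[, k]
      if (sum(wk) < 1e-8) next
      global <- colSums(x * wk) / sum(wk)
      for (b in batches) {
        ib <- batch == b
        wb <- wk[ib]
        if (sum(wb) < 1e-8) next
        cent_b <- colSums(x[ib, , drop = FALSE] * wb) / sum(wb)
        shift[ib, ] <- shift[ib, ] +
          outer(wb, cent_b - global)
      }
    }
    x <- x - shift
  }
  dimnames(x) <- dimnames(scores)
  x
}

#' Default marker-gate rules for the 9 metaclusters
#'
#' Deterministic gating on positivity-thresholded transformed intensities
#' with precedence: PANCK+ cells are Epithelial (PD-L1+ subsplit), then
#' CD68+ are Macrophage (PD-L1+ subsplit), then CD4+FOXP3+ are Treg, CD4+
#' are CD4_T, CD8+ are CD8_T; any remaining marker-positive cell is
#' Other_Immune; the rest are Other.
#'
#' @param threshold positivity threshold on z-scored transformed intensity.
#' @return list with `threshold` and the ordered `labels`.
#' @export
metacluster_gates <- function(threshold = 0.5) {
  list(threshold = threshold, labels = metacluster_levels())
}

#' Assign cells to metaclusters by marker gating
#'
#' @param embedding a `cell_embedding` ([transform_markers()] output) or a
#'   z-scored cells x markers matrix with the standard marker columns.
#' @param gates gate rules from [metacluster_gates()].
#' @return character vector of metacluster labels, one per cell.
#' @export
assign_metaclusters <- function(embedding, gates = metacluster_gates()) {
  z <- if (inherits(embedding, "cell_embedding")) embedding$z else
    as.matrix(embedding)
  if (!all(marker_names() %in% colnames(z)))
    stop("need the six standard marker columns", call. = FALSE)
  pos <- z > gates$threshold
  lab <- rep("Other", nrow(z))
  any_marker <- rowSums(pos) > 0
  lab[any_marker] <- "Other_Immune"
  lab[pos[, "cd8"]] <- "CD8_T"
  lab[pos[, "cd4"]] <- "CD4_T"
  lab[pos[, "cd4"] & pos[, "foxp3"]] <- "Treg"
  lab[pos[, "cd68"]] <- "Macrophage"
  lab[pos[, "cd68"] & pos[, "pdl1"]] <- "PDL1pos_Macrophage"
  lab[pos[, "panck"]] <- "Epithelial"
  lab[pos[, "panck"] & pos[, "pdl1"]] <- "PDL1pos_Epithelial"
  lab
}

immune_metaclusters <- function() {
  c("CD4_T", "CD8_T", "Treg", "Macrophage", "PDL1pos_Macrophage",
    "Other_Immune")
}

#' Per-patient metacluster composition and group comparison
#'
#' Computes per-patient metacluster fractions under the chosen denominator
#' (all cells, or immune cells only - immune being every non-epithelial,
#' non-Other label) and compares groups per metacluster with the
#' Mann-Whitney U test.
#'
#' @param labels per-cell metacluster labels.
#' @param patient_id per-cell patient ids.
#' @param groups named vector mapping patient id -> group ("pos"/"neg").
#' @param denominator `"total"` or `"immune"`.
#' @return list: `fractions` (patients x metaclusters), `tests`
#'   (per-metacluster data.frame with group means and Mann-Whitney p).
#' @export
composition_compare <- function(labels, patient_id, groups,
                                denominator = c("total", "immune")) {
  denominator <- match.arg(denominator)
  if (!all(unique(patient_id) %in% names(groups)))
    stop("every cell's patient must have a group", call. = FALSE)
  lev <- metacluster_levels()
  keep <- rep(TRUE, length(labels))
  if (denominator == "immune") keep <- labels %in% immune_metaclusters()
  tab <- table(patient_id[keep], factor(labels[keep], lev))
  denom <- rowSums(tab)
  frac <- sweep(as.matrix(tab), 1, denom, `/`)
  frac <- frac[denom > 0, , drop = FALSE]  # zero-denominator patients excluded
  grp <- groups[rownames(frac)]
  tests <- do.call(rbind, lapply(lev, function(mc) {
    x <- frac[grp == "pos", mc]; y <- frac[grp == "neg", mc]
    p <- if (length(x) && length(y)) mann_whitney(x, y)$p_value else NA_real_
    data.frame(metacluster = mc, mean_pos = mean(x), mean_neg = mean(y),
               p = p)
  }))
  list(fractions = frac, groups = grp, tests = tests,
       denominator = denominator)
}
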