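#' Permutation test for pairwise cell-cell interaction and avoidance
#'
#' For every metacluster pair in every ROI, compares the observed number of
#' Delaunay-adjacent (optionally radius-pruned) cell pairs against a null
#' built by shuffling metacluster labels within the ROI, coordinates fixed.
#' The per-ROI statistic is z = (observed - null mean) / null SD with an
#' empirical two-sided p using the +1 correction,
#' p = (1 + #\{|null - mean| >= |obs - mean|\}) / (1 + n_perm). Group-level
#' calls combine ROIs by the majority direction among significant ROIs.
#'
#' @param cells cell table with `roi_id`, `x_um`, `y_um`, and a
#'   `metacluster` column.
#' @param radius optional contact radius (microns) passed to
#'   [interaction_partners()]; NULL keeps all Delaunay edges.
#' @param n_perm permutations per ROI (default 1000).
#' @param seed RNG seed.
#' @param alpha per-ROI significance level for the group-level majority rule.
#' @param groups optional named vector roi_id -> group; when given, results
#'   are additionally aggregated per group.
#' @return list of class `interaction_result`: `per_roi` (data.frame with
#'   roi_id, pair, observed, z, p), `combined` (per pair x group: counts of
#'   significant attracting/avoiding ROIs, mean z, direction).
#' @export
interaction_test <- function(cells, radius = NULL, n_perm = 1000, seed = 1,
                             alpha = 0.05, groups = NULL) {
  stopifnot(all(c("roi_id", "x_um", "y_um", "metacluster") %in%
                  colnames(cells)))
  set.seed(seed)
  lev <- metacluster_levels()
  rois <- unique(cells$roi_id)
  per_roi <- vector("list", length(rois))
  for (ri in seq_along(rois)) {
    sub <- cells[cells$roi_id == rois[ri], , drop = FALSE]
    labs <- match(sub$metacluster, lev)
    if (length(unique(labs)) < 2) next  # no testable pairs
    g <- build_graph(sub$x_um, sub$y_um)
    if (!is.null(radius)) g <- interaction_partners(g, radius)
    E <- g$edges
    if (nrow(E) == 0) next
    L <- length(lev)
    code <- function(l) {
      a <- pmin(l[E[, 1]], l[E[, 2]]); b <- pmax(l[E[, 1]], l[E[, 2]])
      (a - 1L) * L + b
    }
    obs <- tabulate(code(labs), nbins = L * L)
    null_counts <- matrix(0L, L * L, n_perm)
    for (p in seq_len(n_perm))
      null_counts[, p] <- tabulate(code(sample(labs)), nbins = L * L)
    present <- which(obs > 0 | rowSums(null_counts) > 0)
    mu <- rowMeans(null_counts[present, , drop = FALSE])
    sdv <- apply(null_counts[present, , drop = FALSE], 1, stats::sd)
    z <- ifelse(sdv > 0, (obs[present] - mu) / sdv, 0)
    dev <- abs(obs[present] - mu)
    pvals <- vapply(seq_along(present), function(k)
      (1 + sum(abs(null_counts[present[k], ] - mu[k]) >= dev[k])) /
        (1 + n_perm), numeric(1))
    a_idx <- (present - 1L) %/% L + 1L
    b_idx <- (present - 1L) %% L + 1L
    per_roi[[ri]] <- data.frame(
      roi_id = rois[ri],
      type_a = lev[a_idx], type_b = lev[b_idx],
      observed = obs[present], null_mean = mu, z = z, p = pvals)
  }
  per_roi <- do.call(rbind, per_roi)
  combined <- NULL
  if (!is.null(per_roi)) {
    per_roi$group <- if (is.null(groups)) "all" else
      unname(groups[per_roi$roi_id])
    per_roi$pair <- paste(per_roi$type_a, per_roi$type_b, sep = ":")
    combined <- do.call(rbind, lapply(
      split(per_roi, list(per_roi$pair, per_roi$group), drop = TRUE),
      function(d) {
        sig <- d$p < alpha
        n_pos <- sum(sig & d$z > 0); n_neg <- sum(sig & d$z < 0)
        data.frame(pair = d$pair[1], group = d$group[1],
                   n_roi = nrow(d), n_attract = n_pos, n_avoid = n_neg,
                   mean_z = mean(d$z),
                   direction = if (n_pos + n_neg == 0) "none" else
                     if (n_pos >= n_neg) "interaction" else "avoidance")
      }))
    rownames(combined) <- NULL
  }
  structure(list(per_roi = per_roi, combined = combined, alpha = alpha,
                 n_perm = n_perm),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  if (is.null(x$combined)) {
    cat("Interaction test: no testable pairs\n")
  } else {
    cat(sprintf("Interaction test: %d pair/group combinations over %d ROIs\n",
                nrow(x$combined), length(unique(x$per_roi$roi_id))))
    sig <- x$combined[x$combined$direction != "none", , drop = FALSE]
    if (nrow(sig)) print(utils::head(sig[order(-abs(sig$mean_z)), ], 10))
  }
  invisible(x)
}
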