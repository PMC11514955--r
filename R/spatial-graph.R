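#' Delaunay spatial graph of one ROI
#'
#' Builds the Delaunay triangulation of cell centroids (Euclidean distance);
#' edges define spatial adjacency. Fewer than 3 cells, or collinear cells,
#' fall back to nearest-neighbour edges. Duplicate coordinates are jittered
#' by 1e-6 microns to keep the triangulation defined.
#'
#' @param x,y cell centroid coordinates in microns.
#' @param max_edge_um optional pruning cutoff: edges longer than this are
#'   dropped.
#' @return object of class `spatial_graph`: `edges` (2-column matrix of cell
#'   indices, i < j), `lengths` (edge lengths, microns), `n`, `x`, `y`.
#' @export
build_graph <- function(x, y, max_edge_um = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (anyDuplicated(cbind(x, y))) {
    dup <- duplicated(cbind(x, y))
    x[dup] <- x[dup] + stats::runif(sum(dup), -1e-6, 1e-6)
    y[dup] <- y[dup] + stats::runif(sum(dup), -1e-6, 1e-6)
  }
  edges <- NULL
  if (n >= 3) {
    dxy <- tryCatch(deldir::deldir(x, y, suppressMsge = TRUE),
                    error = function(e) NULL)
    if (!is.null(dxy))
      edges <- as.matrix(dxy$delsgs[, c("ind1", "ind2")])
  }
  if (is.null(edges)) {  # degenerate: nearest-neighbour fallback
    if (n < 2) edges <- matrix(integer(0), ncol = 2) else {
      k <- min(2, n - 1)
      nn <- FNN::get.knn(cbind(x, y), k = k)$nn.index
      edges <- unique(t(apply(cbind(rep(seq_len(n), k), as.vector(nn)), 1,
                              sort)))
    }
  }
  edges <- matrix(as.integer(edges), ncol = 2)
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges[edges[, 1] != edges[, 2], , drop = FALSE])
  len <- sqrt((x[edges[, 1]] - x[edges[, 2]])^2 +
              (y[edges[, 1]] - y[edges[, 2]])^2)
  if (!is.null(max_edge_um)) {
    keep <- len <= max_edge_um
    edges <- edges[keep, , drop = FALSE]
    len <- len[keep]
  }
  structure(list(edges = edges, lengths = len, n = n, x = x, y = y),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("Spatial graph: %d cells, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}

#' Retain interaction partners within a contact radius
#'
#' Prunes a Delaunay graph to edges with centroid distance at most `radius`
#' microns - the interaction-partner definition (default 4 um).
#'
#' @param graph a `spatial_graph`.
#' @param radius contact radius in microns.
#' @return a pruned `spatial_graph`.
#' @export
interaction_partners <- function(graph, radius = 4) {
  stopifnot(inherits(graph, "spatial_graph"))
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  keep <- graph$lengths <= radius
  graph$edges <- graph$edges[keep, , drop = FALSE]
  graph$lengths <- graph$lengths[keep]
  graph
}

#' Neighbourhood composition windows
#'
#' For every cell, the metacluster composition of its k nearest cells in the
#' same ROI (the cell itself included by default), normalized to sum to 1.
#' ROIs with at most k cells use all their cells as the window. Distance
#' ties are broken by cell order.
#'
#' @param x,y coordinates within one ROI.
#' @param labels per-cell metacluster labels.
#' @param k window size (default 20).
#' @param include_self count the center cell in its own window.
#' @return matrix cells x metaclusters of window compositions (rows sum to 1).
#' @export
neighborhood_windows <- function(x, y, labels, k = 20, include_self = TRUE) {
  n <- length(x)
  lev <- metacluster_levels()
  labf <- factor(labels, lev)
  out <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
  kk <- min(k - include_self, n - 1)
  idx <- if (kk >= 1)
    FNN::get.knn(cbind(x, y), k = kk)$nn.index else
    matrix(integer(0), nrow = n)
  for (i in seq_len(n)) {
    members <- idx[i, ]
    if (include_self) members <- c(i, members)
    tab <- tabulate(labf[members], nbins = length(lev))
    out[i, ] <- tab / sum(tab)
  }
  out
}

#' Voronoi topology map of one ROI
#'
#' Voronoi tessellation of cell centroids clipped to the ROI bounding box;
#' one polygon per cell, typically colored by cellular-neighbourhood label.
#' Unbounded outer tiles are clipped, never dropped, so tile areas sum to
#' the box area.
#'
#' @param x,y cell coordinates in microns.
#' @param values per-cell value used for coloring (e.g. CN label).
#' @param bbox clip rectangle `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   coordinate range.
#' @return object of class `voronoi_map`: `polygons` (list of data.frames
#'   with x, y vertices), `areas`, `values`, `bbox`.
#' @export
voronoi_map <- function(x, y, values = rep(1L, length(x)), bbox = NULL) {
  if (length(x) < 4) stop("need at least 4 cells", call. = FALSE)
  if (is.null(bbox)) bbox <- c(range(x), range(y))
  dxy <- deldir::deldir(x, y, rw = bbox, suppressMsge = TRUE)
  tiles <- deldir::tile.list(dxy)
  polys <- unname(lapply(tiles, function(t) data.frame(x = t$x, y = t$y)))
  areas <- vapply(polys, function(p) {
    xx <- p$x; yy <- p$y
    abs(sum(xx * c(yy[-1], yy[1]) - c(xx[-1], xx[1]) * yy)) / 2
  }, numeric(1))
  structure(list(polygons = polys, areas = areas,
                 points = unname(vapply(tiles, function(t)
                   c(t$pt[1], t$pt[2]), numeric(2))),
                 values = values, bbox = bbox),
            class = "voronoi_map")
}

#' @export
plot.voronoi_map <- function(x, col = NULL, border = "grey30", ...) {
  vals <- as.integer(factor(x$values))
  if (is.null(col)) col <- grDevices::hcl.colors(max(vals), "Set 3")
  plot(NA, xlim = x$bbox[1:2], ylim = rev(x$bbox[3:4]), asp = 1,
       xlab = "x (µm)", ylab = "y (µm)", ...)
  for (i in seq_along(x$polygons))
    graphics::polygon(x$polygons[[i]]$x, x$polygons[[i]]$y,
                      col = col[vals[i]], border = border)
  invisible(x)
}
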