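#' Non-negative matrix factorization by multiplicative updates
#'
#' Multiplicative-update NMF (V ~ W H, all non-negative) with either the
#' Frobenius objective (the default) or the generalized Kullback-Leibler
#' divergence objective used by the classical consensus-NMF clustering
#' literature. Runs to a relative-change tolerance of 1e-6 or 500
#' iterations.
#'
#' @param V non-negative matrix (rows = samples).
#' @param rank factorization rank.
#' @param objective `"kl"` or `"frobenius"`.
#' @param max_iter,tol stopping rule.
#' @return list `W` (rows x rank), `H` (rank x cols), `loss`, `objective`.
#' @export
nmf_fit <- function(V, rank = 2, objective = c("frobenius", "kl"),
                    max_iter = 500, tol = 1e-6) {
  objective <- match.arg(objective)
  V <- unclass(as.matrix(V))
  storage.mode(V) <- "double"
  if (any(V < 0)) stop("NMF input must be non-negative", call. = FALSE)
  n <- nrow(V); m <- ncol(V)
  W <- matrix(stats::runif(n * rank, 0.1, 1), n, rank)
  H <- matrix(stats::runif(rank * m, 0.1, 1), rank, m)
  eps <- 1e-10
  loss_old <- Inf
  for (it in seq_len(max_iter)) {
    if (objective == "kl") {
      WH <- W %*% H + eps
      H <- H * (t(W) %*% (V / WH)) / (colSums(W) + eps)
      WH <- W %*% H + eps
      W <- W * ((V / WH) %*% t(H)) /
        matrix(rowSums(H) + eps, n, rank, byrow = TRUE)
      WH <- W %*% H + eps
      loss <- sum(V * log((V + eps) / WH) - V + WH)
    } else {
      H <- H * (t(W) %*% V) / (t(W) %*% W %*% H + eps)
      W <- W * (V %*% t(H)) / (W %*% (H %*% t(H)) + eps)
      loss <- sum((V - W %*% H)^2)
    }
    if (!is.finite(loss)) break
    if (is.finite(loss_old) &&
        abs(loss_old - loss) <= tol * max(abs(loss_old), eps)) break
    loss_old <- loss
  }
  list(W = W, H = H, loss = loss, objective = objective)
}

#' Consensus NMF subtyping of ROI composition profiles
#'
#' Runs NMF `iters` times from distinct seeded initializations on the
#' ROI x metacluster composition matrix; each run clusters ROIs by their
#' largest (scale-normalized) basis coefficient. The consensus matrix holds
#' the fraction of runs co-clustering each ROI pair; final labels come from
#' an average-linkage hierarchical cut of 1 - consensus into `rank` groups,
#' with cluster quality summarized by the mean silhouette width on consensus
#' distances. A structureless input (all co-clusterings identical) is
#' flagged degenerate.
#'
#' @param composition ROI x metacluster non-negative matrix (typically rows
#'   sum to 1).
#' @param rank number of subtypes (default 2).
#' @param iters NMF runs entering the consensus (default 50).
#' @param seed RNG seed.
#' @param objective NMF objective passed to [nmf_fit()].
#' @return object of class `subtype_result`: `consensus`, `labels`
#'   (per-ROI subtype 1..rank), `silhouette` (mean width), `degenerate`,
#'   `rank`, `iters`.
#' @export
cnmf <- function(composition, rank = 2, iters = 50, seed = 1,
                 objective = "frobenius") {
  V <- unclass(as.matrix(composition))
  if (any(V < 0)) stop("composition must be non-negative", call. = FALSE)
  n <- nrow(V)
  if (n < rank + 1) stop("need at least rank + 1 ROIs", call. = FALSE)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max %/% 2, iters)
  # structureless input: identical rows carry nothing to cluster
  row_spread <- max(stats::dist(V))
  consensus <- matrix(0, n, n)
  for (s in run_seeds) {
    set.seed(s)
    fit <- nmf_fit(V, rank = rank, objective = objective)
    scale_r <- rowSums(fit$H)
    cl <- max.col(sweep(fit$W, 2, scale_r, `*`), ties.method = "first")
    consensus <- consensus + outer(cl, cl, `==`)
  }
  consensus <- consensus / iters
  diag(consensus) <- 1
  d <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = rank)
  sil <- cluster::silhouette(labels, d)
  mean_sil <- if (is.matrix(sil)) mean(sil[, "sil_width"]) else 0
  degenerate <- length(unique(labels)) < rank ||
    stats::sd(as.vector(d)) == 0 || mean_sil <= 0 || row_spread < 1e-10
  if (row_spread < 1e-10) mean_sil <- 0
  structure(list(consensus = consensus, labels = labels,
                 silhouette = mean_sil, degenerate = degenerate,
                 rank = rank, iters = iters,
                 roi_ids = rownames(V)),
            class = "subtype_result")
}

#' @export
print.subtype_result <- function(x, ...) {
  cat(sprintf(
    "Consensus NMF: %d ROIs, rank %d, %d runs; mean silhouette %.3f%s\n",
    nrow(x$consensus), x$rank, x$iters, x$silhouette,
    if (x$degenerate) " (degenerate)" else ""))
  print(table(subtype = x$labels))
  invisible(x)
}

#' Integrate ROI subtype labels to patient level
#'
#' Majority vote over a patient's ROIs; ties break toward the subtype with
#' the higher mean within-subtype consensus confidence among that patient's
#' ROIs.
#'
#' @param result a `subtype_result`.
#' @param roi_patient named vector roi_id -> patient_id covering every ROI.
#' @return named integer vector patient -> subtype.
#' @export
integrate_roi_labels <- function(result, roi_patient) {
  stopifnot(inherits(result, "subtype_result"))
  rois <- result$roi_ids
  if (is.null(rois)) rois <- as.character(seq_along(result$labels))
  if (!all(rois %in% names(roi_patient)))
    stop("every ROI must map to a patient", call. = FALSE)
  pat <- roi_patient[rois]
  vapply(split(seq_along(rois), pat), function(idx) {
    votes <- table(result$labels[idx])
    top <- as.integer(names(votes)[votes == max(votes)])
    if (length(top) == 1) return(top)
    # tie: mean consensus of each candidate subtype's ROIs (within patient)
    conf <- vapply(top, function(s) {
      members <- idx[result$labels[idx] == s]
      allmem <- which(result$labels == s)
      mean(result$consensus[members, allmem, drop = FALSE])
    }, numeric(1))
    top[which.max(conf)]
  }, integer(1))
}

#' Subtype associations with nodal status, composition, and mutations
#'
#' Fisher's exact test of subtype x pN; per-metacluster Mann-Whitney of
#' composition across subtypes; per-gene Fisher of mutation frequency
#' across subtypes. Subtypes with fewer than 2 patients are skipped.
#'
#' @param patient_subtype named vector patient -> subtype.
#' @param clinical data.frame with `patient_id`, `pn`.
#' @param patient_composition optional patients x metaclusters fraction
#'   matrix.
#' @param muts optional mutation table.
#' @param genes genes for the mutation comparison.
#' @return list: `pn_test` (assoc_test), `pn_table`, `composition_tests`,
#'   `gene_tests`.
#' @export
subtype_associations <- function(patient_subtype, clinical,
                                 patient_composition = NULL, muts = NULL,
                                 genes = NULL) {
  pats <- names(patient_subtype)
  sizes <- table(patient_subtype)
  if (length(sizes) < 2 || any(sizes < 2)) {
    warning("subtype with < 2 patients: associations skipped", call. = FALSE)
    return(list(pn_test = NULL, pn_table = NULL, composition_tests = NULL,
                gene_tests = NULL))
  }
  pn <- clinical$pn[match(pats, clinical$patient_id)]
  pn_table <- table(subtype = patient_subtype, pn = pn)
  pn_test <- fisher_exact(pn_table)

  composition_tests <- NULL
  if (!is.null(patient_composition)) {
    pc <- patient_composition[pats, , drop = FALSE]
    composition_tests <- do.call(rbind, lapply(colnames(pc), function(mc) {
      x <- pc[patient_subtype == 1, mc]; y <- pc[patient_subtype == 2, mc]
      data.frame(metacluster = mc, mean_subtype1 = mean(x),
                 mean_subtype2 = mean(y), p = mann_whitney(x, y)$p_value)
    }))
  }

  gene_tests <- NULL
  if (!is.null(muts)) {
    if (is.null(genes))
      genes <- setdiff(unique(muts$gene), grep("^PSG", unique(muts$gene),
                                               value = TRUE))
    gene_tests <- do.call(rbind, lapply(genes, function(g) {
      mutated <- pats %in% muts$patient_id[muts$gene == g]
      if (sum(mutated) == 0) return(NULL)
      tab <- table(factor(mutated, c(FALSE, TRUE)),
                   factor(patient_subtype, sort(unique(patient_subtype))))
      data.frame(gene = g,
                 freq_subtype1 = mean(mutated[patient_subtype == 1]),
                 freq_subtype2 = mean(mutated[patient_subtype == 2]),
                 p = fisher_exact(tab)$p_value)
    }))
  }
  list(pn_test = pn_test, pn_table = pn_table,
       composition_tests = composition_tests, gene_tests = gene_tests)
}
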