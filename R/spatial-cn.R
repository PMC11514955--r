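#' Cellular-neighbourhood detection by K-means on window compositions
#'
#' Clusters neighbourhood composition windows from all ROIs jointly into
#' `k_cn` cellular neighbourhoods (CNs); every cell is labeled by its
#' window's cluster. K-means uses 10 restarts with best-inertia selection
#' and is deterministic given `seed`. CN integer labels are arbitrary;
#' reporting should key on annotation.
#'
#' @param windows cells x metaclusters window-composition matrix
#'   ([neighborhood_windows()] rows, stacked across ROIs).
#' @param k_cn number of neighbourhoods (default 10).
#' @param seed RNG seed.
#' @return object of class `cn_assignment`: `cn` (integer label per cell),
#'   `centers` (CN x metacluster mean compositions), `windows`, `k_cn`.
#' @export
cluster_cns <- function(windows, k_cn = 10, seed = 1) {
  windows <- as.matrix(windows)
  n_distinct <- nrow(unique(windows))
  if (n_distinct < k_cn) {
    warning("fewer distinct windows than k_cn; reducing k to ", n_distinct,
            call. = FALSE)
    k_cn <- n_distinct
  }
  set.seed(seed)
  if (k_cn == 1) {
    return(structure(list(cn = rep(1L, nrow(windows)),
                          centers = matrix(colMeans(windows), 1,
                                           dimnames = list(NULL, colnames(windows))),
                          windows = windows, k_cn = 1L),
                     class = "cn_assignment"))
  }
  km <- suppressWarnings(stats::kmeans(windows, centers = k_cn, nstart = 10,
                                       iter.max = 100))
  structure(list(cn = as.integer(km$cluster), centers = km$centers,
                 windows = windows, k_cn = k_cn),
            class = "cn_assignment")
}

#' @export
print.cn_assignment <- function(x, ...) {
  cat(sprintf("CN assignment: %d cells in %d neighbourhoods\n",
              length(x$cn), x$k_cn))
  invisible(x)
}

#' Annotate cellular neighbourhoods by dominant metacluster
#'
#' Each CN is annotated with its highest-mean-composition metacluster and a
#' functional group: epithelial-dominant CNs are `Epithelial-CN`;
#' Treg- or PD-L1+-macrophage-dominant CNs are `Immune-suppressed-CN`;
#' macrophage-dominant CNs (which carry T-cell admixture by construction of
#' the windows) are `MF_and_T-CN`; CD4/CD8-dominant CNs are `T-CN`. CNs
#' dominated by uninformative labels (Other / Other_Immune) are assigned to
#' the functional group with the largest aggregate composition. Ties on the
#' dominant composition break toward the metacluster that is rarer
#' cohort-wide.
#'
#' @param assignment a `cn_assignment`.
#' @param labels per-cell metacluster labels (for cohort-wide rarity).
#' @return data.frame: cn, dominant, functional_group, plus the mean
#'   composition matrix as attribute `"composition"`.
#' @export
annotate_cns <- function(assignment, labels = NULL) {
  stopifnot(inherits(assignment, "cn_assignment"))
  comp <- rowsum(assignment$windows, assignment$cn)
  comp <- comp / rowSums(comp)
  lev <- colnames(comp)
  rarity <- if (!is.null(labels))
    table(factor(labels, lev)) else
    setNames(rep(1, length(lev)), lev)
  dominant <- apply(comp, 1, function(v) {
    best <- which(v == max(v))
    if (length(best) > 1) best <- best[which.min(rarity[lev[best]])]
    lev[best]
  })
  fgroup <- vapply(seq_len(nrow(comp)), function(i) {
    d <- dominant[i]
    if (d %in% c("Epithelial", "PDL1pos_Epithelial")) return("Epithelial-CN")
    if (d %in% c("Treg", "PDL1pos_Macrophage")) return("Immune-suppressed-CN")
    if (d == "Macrophage") return("MF_and_T-CN")
    if (d %in% c("CD4_T", "CD8_T")) return("T-CN")
    agg <- c(`Epithelial-CN` = sum(comp[i, c("Epithelial", "PDL1pos_Epithelial")]),
             `Immune-suppressed-CN` = sum(comp[i, c("Treg", "PDL1pos_Macrophage")]),
             `MF_and_T-CN` = comp[i, "Macrophage"],
             `T-CN` = sum(comp[i, c("CD4_T", "CD8_T")]))
    names(which.max(agg))
  }, character(1))
  res <- data.frame(cn = as.integer(rownames(comp)), dominant = dominant,
                    functional_group = fgroup, row.names = NULL)
  attr(res, "composition") <- comp
  res
}

#' CN abundance analyses: group differences, metacluster coupling, genes
#'
#' Per-patient CN frequencies (fraction of a patient's cells in each CN)
#' are compared across nodal groups with the Mann-Whitney U test; each CN's
#' abundance is correlated (Spearman) with the per-patient proportion of
#' its dominant metacluster; and, when a mutation table is supplied, CN
#' abundance is compared between mutated and wild-type patients per gene.
#'
#' @param assignment a `cn_assignment`.
#' @param patient_id per-cell patient ids (aligned with the windows).
#' @param groups named vector patient id -> "pos"/"neg".
#' @param labels per-cell metacluster labels.
#' @param muts optional mutation table for gene associations.
#' @param genes genes to test (default: genes in `muts` hitting >= 3
#'   patients of the imaged subset).
#' @return list: `frequencies` (patients x CN), `group_tests`,
#'   `metacluster_correlation`, `gene_tests` (or NULL), `annotation`.
#' @export
cn_group_analysis <- function(assignment, patient_id, groups, labels,
                              muts = NULL, genes = NULL) {
  stopifnot(inherits(assignment, "cn_assignment"))
  ann <- annotate_cns(assignment, labels)
  cns <- sort(unique(assignment$cn))
  tab <- table(patient_id, factor(assignment$cn, cns))
  freq <- sweep(as.matrix(tab), 1, rowSums(tab), `/`)
  grp <- groups[rownames(freq)]

  group_tests <- do.call(rbind, lapply(seq_along(cns), function(i) {
    x <- freq[grp == "pos", i]; y <- freq[grp == "neg", i]
    data.frame(cn = cns[i],
               functional_group = ann$functional_group[ann$cn == cns[i]],
               mean_pos = mean(x), mean_neg = mean(y),
               p = mann_whitney(x, y)$p_value)
  }))

  mfrac <- table(patient_id, factor(labels, metacluster_levels()))
  mfrac <- sweep(as.matrix(mfrac), 1, rowSums(mfrac), `/`)
  mfrac <- mfrac[rownames(freq), , drop = FALSE]
  mc_cor <- do.call(rbind, lapply(seq_along(cns), function(i) {
    dom <- ann$dominant[ann$cn == cns[i]]
    ct <- spearman_cor(freq[, i], mfrac[, dom])
    data.frame(cn = cns[i], dominant = dom, rho = ct$estimate,
               p = ct$p_value)
  }))

  gene_tests <- NULL
  if (!is.null(muts)) {
    pats <- rownames(freq)
    if (is.null(genes)) {
      hits <- table(unique(muts[muts$patient_id %in% pats &
                                  !grepl("^PSG", muts$gene),
                                c("patient_id", "gene")])$gene)
      genes <- names(hits[hits >= 3])
    }
    gene_tests <- do.call(rbind, lapply(genes, function(g) {
      mutated <- pats %in% muts$patient_id[muts$gene == g]
      if (sum(mutated) < 2 || sum(!mutated) < 2) return(NULL)
      do.call(rbind, lapply(seq_along(cns), function(i) {
        data.frame(gene = g, cn = cns[i],
                   mean_mut = mean(freq[mutated, i]),
                   mean_wt = mean(freq[!mutated, i]),
                   p = mann_whitney(freq[mutated, i],
                                    freq[!mutated, i])$p_value)
      }))
    }))
  }
  list(frequencies = freq, group_tests = group_tests,
       metacluster_correlation = mc_cor, gene_tests = gene_tests,
       annotation = ann)
}
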