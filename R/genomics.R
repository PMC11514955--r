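#' Panel-NGS summary statistics and nodal-association analyses
#'
#' Operates on a mutation table: one row per alteration with columns
#' `patient_id`, `gene`, `class` (nonsynonymous_snv / indel / cnv / fusion),
#' `vaf` (in (0, 1], NA for cnv/fusion), `oncogenic`
#' (oncogenic / likely / predicted / vus) and `level` (L1 / L3A / L3B / L4 /
#' none).
#'
#' @name genomics
NULL

tmb_classes <- c("nonsynonymous_snv", "indel")

#' Tumor mutational burden
#'
#' Nonsynonymous SNV + indel count divided by the megabases covered by the
#' panel. CNVs and fusions contribute to the total alteration count but not
#' to TMB.
#'
#' @param muts mutation table.
#' @param panel_mb covered megabases (default 1.21).
#' @param patient_id single patient, or NULL for all patients present.
#' @return named numeric vector of TMB (mutations/Mb).
#' @export
compute_tmb <- function(muts, panel_mb = 1.21, patient_id = NULL) {
  if (is.null(patient_id)) patient_id <- unique(muts$patient_id)
  if (!all(patient_id %in% muts$patient_id))
    stop("unknown patient: ",
         paste(setdiff(patient_id, muts$patient_id), collapse = ", "),
         call. = FALSE)
  vapply(patient_id, function(p)
    sum(muts$patient_id == p & muts$class %in% tmb_classes) / panel_mb,
    numeric(1))
}

#' MATH intratumor-heterogeneity score
#'
#' Mutant-allele tumor heterogeneity: the scaled dispersion of the variant
#' allele frequency distribution,
#' `100 * 1.4826 * median(|v - median(v)|) / median(v)`. Higher MATH means
#' higher intratumor heterogeneity. Undefined (NA) for fewer than 3 VAFs or
#' a zero median.
#'
#' @param vafs numeric vector of variant allele frequencies.
#' @param mad_constant the MAD consistency constant (default 1.4826).
#' @return MATH score, or NA when undefined.
#' @export
compute_math <- function(vafs, mad_constant = 1.4826) {
  vafs <- vafs[!is.na(vafs)]
  if (length(vafs) < 3) return(NA_real_)
  med <- stats::median(vafs)
  if (med <= 0) return(NA_real_)
  100 * mad_constant * stats::median(abs(vafs - med)) / med
}

#' Per-patient genomic summary
#'
#' @param muts mutation table.
#' @param clinical data.frame with `patient_id` (patients with zero
#'   alterations get count 0, TMB 0, MATH NA).
#' @param panel_mb covered megabases.
#' @return data.frame: patient_id, mutation_count, tmb, math.
#' @export
genomic_summary <- function(muts, clinical, panel_mb = 1.21) {
  ids <- clinical$patient_id
  data.frame(
    patient_id = ids,
    mutation_count = vapply(ids, function(p)
      sum(muts$patient_id == p), numeric(1)),
    tmb = vapply(ids, function(p)
      sum(muts$patient_id == p & muts$class %in% tmb_classes) / panel_mb,
      numeric(1)),
    math = vapply(ids, function(p)
      compute_math(muts$vaf[muts$patient_id == p]), numeric(1)),
    row.names = NULL)
}

#' Per-gene mutation-frequency comparison across nodal groups
#'
#' Fisher's exact test on the mutated/wild-type 2x2 per gene, with
#' Benjamini-Hochberg correction at q < 0.1.
#'
#' @param muts mutation table.
#' @param clinical data.frame with `patient_id` and `pn` ("pos"/"neg").
#' @param genes genes to test (default: the panel's non-passenger genes,
#'   i.e. every gene mutated in at least one patient, excluding `PSG*`
#'   passenger labels).
#' @param threshold FDR threshold.
#' @return data.frame: gene, n_pos, n_neg, freq_pos, freq_neg, odds_ratio,
#'   p, q, significant.
#' @export
compare_gene_frequencies <- function(muts, clinical, genes = NULL,
                                     threshold = 0.1) {
  if (is.null(genes)) {
    genes <- setdiff(unique(muts$gene), grep("^PSG", unique(muts$gene),
                                             value = TRUE))
  }
  pos <- clinical$patient_id[clinical$pn == "pos"]
  neg <- clinical$patient_id[clinical$pn == "neg"]
  if (length(pos) == 0 || length(neg) == 0)
    stop("both nodal groups must be non-empty", call. = FALSE)
  rows <- lapply(genes, function(g) {
    mut_pat <- unique(muts$patient_id[muts$gene == g])
    a <- sum(pos %in% mut_pat); b <- sum(neg %in% mut_pat)
    if (a + b == 0) return(NULL)  # gene absent everywhere: skipped
    tab <- matrix(c(a, length(pos) - a, b, length(neg) - b), 2)
    ft <- fisher_exact(tab)
    data.frame(gene = g, n_pos = a, n_neg = b,
               freq_pos = a / length(pos), freq_neg = b / length(neg),
               odds_ratio = ft$estimate, p = ft$p_value)
  })
  res <- do.call(rbind, rows)
  fdr <- bh_fdr(res$p, threshold = threshold)
  res$q <- fdr$q
  res$significant <- fdr$significant
  res[order(res$p), , drop = FALSE]
}

#' Pairwise co-occurrence / mutual-exclusivity analysis
#'
#' Fisher's exact test per gene pair on the patient-level mutated/wild-type
#' 2x2; positive log-odds labels co-occurrence, negative labels mutual
#' exclusivity. Monomorphic genes are skipped.
#'
#' @param muts mutation table.
#' @param patients character vector of patient ids defining the cohort.
#' @param genes genes to pair up.
#' @return data.frame: gene1, gene2, log_odds, direction, p, q.
#' @export
cooccurrence_analysis <- function(muts, patients, genes) {
  if (length(genes) < 2) stop("need at least 2 genes", call. = FALSE)
  status <- sapply(genes, function(g)
    patients %in% muts$patient_id[muts$gene == g])
  keep <- colSums(status) > 0 & colSums(status) < nrow(status)
  status <- status[, keep, drop = FALSE]
  genes <- genes[keep]
  if (length(genes) < 2) return(NULL)
  pairs <- utils::combn(length(genes), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tab <- table(factor(status[, i], c(FALSE, TRUE)),
                 factor(status[, j], c(FALSE, TRUE)))
    ft <- fisher_exact(tab)
    lo <- log(ft$estimate)
    data.frame(gene1 = genes[i], gene2 = genes[j], log_odds = lo,
               direction = ifelse(lo > 0, "co_occurrence", "exclusivity"),
               p = ft$p_value)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, "BH")
  res
}

#' Default oncogenic-pathway map
#'
#' Static gene-to-pathway assignment in the style of curated oncogenic
#' signaling pathway catalogs.
#'
#' @return named character vector: gene -> pathway.
#' @export
default_pathway_map <- function() {
  c(EGFR = "RTK/RAS", KRAS = "RTK/RAS", BRAF = "RTK/RAS", HGF = "RTK/RAS",
    NF1 = "RTK/RAS", ALK = "RTK/RAS", ERBB2 = "RTK/RAS", MET = "RTK/RAS",
    PIK3CA = "PI3K", PIK3CG = "PI3K", STK11 = "PI3K", PTEN = "PI3K",
    TP53 = "p53", ATM = "p53", MDM2 = "p53", RB1 = "Cell cycle",
    CDKN2A = "Cell cycle", KEAP1 = "NRF2", NFE2L2 = "NRF2",
    CTNNB1 = "Wnt", ARID1A = "Chromatin", SETD2 = "Chromatin",
    KMT2B = "Chromatin", BRD4 = "Chromatin", SMARCA4 = "Chromatin",
    RBM10 = "RNA splicing", SF3B1 = "RNA splicing")
}

#' Oncogenic-pathway alteration frequencies by nodal group
#'
#' A patient counts as pathway-altered if at least one retained alteration
#' hits a pathway gene; with `oncogenic_only` (the default), variants of
#' unknown significance are discarded first. Fisher's exact test per
#' pathway, BH-corrected.
#'
#' @param muts mutation table.
#' @param clinical data.frame with `patient_id`, `pn`.
#' @param pathway_map named vector gene -> pathway.
#' @param oncogenic_only drop VUS alterations before counting.
#' @return list: `frequencies` (pathway x group matrix), `tests`
#'   (data.frame pathway, p, q), `unmapped` (genes without a pathway).
#' @export
pathway_alteration_frequency <- function(muts, clinical,
                                         pathway_map = default_pathway_map(),
                                         oncogenic_only = TRUE) {
  keep <- muts
  if (oncogenic_only) keep <- keep[keep$oncogenic != "vus", , drop = FALSE]
  keep$pathway <- pathway_map[keep$gene]
  unmapped <- sort(unique(keep$gene[is.na(keep$pathway)]))
  keep <- keep[!is.na(keep$pathway), , drop = FALSE]
  pathways <- sort(unique(pathway_map))
  pos <- clinical$patient_id[clinical$pn == "pos"]
  neg <- clinical$patient_id[clinical$pn == "neg"]
  freq <- matrix(0, length(pathways), 2,
                 dimnames = list(pathways, c("pn_neg", "pn_pos")))
  pvals <- rep(NA_real_, length(pathways))
  for (i in seq_along(pathways)) {
    altered <- unique(keep$patient_id[keep$pathway == pathways[i]])
    a <- sum(pos %in% altered); b <- sum(neg %in% altered)
    freq[i, ] <- c(b / length(neg), a / length(pos))
    tab <- matrix(c(a, length(pos) - a, b, length(neg) - b), 2)
    pvals[i] <- fisher_exact(tab)$p_value
  }
  tests <- data.frame(pathway = pathways, p = pvals,
                      q = stats::p.adjust(pvals, "BH"))
  list(frequencies = freq, tests = tests, unmapped = unmapped)
}

actionability_order <- c("L1", "L3A", "L3B", "L4")

#' Therapeutic actionability summary
#'
#' Tallies actionable alterations by evidence level and classifies each
#' sample by its highest-level alteration (L1 > L3A > L3B > L4).
#'
#' @param muts mutation table (rows with level `"none"` are not actionable).
#' @param patients full patient id vector (denominator for sample-level
#'   percentages; defaults to patients present in `muts`).
#' @return list: `alteration_counts` (+`alteration_pct`), `sample_levels`
#'   (per-sample highest level), `sample_counts`, `n_actionable_samples`,
#'   `pct_actionable_samples`, `pct_level1_of_actionable`.
#' @export
actionability_summary <- function(muts, patients = unique(muts$patient_id)) {
  lv <- muts$level
  bad <- setdiff(unique(lv), c(actionability_order, "none"))
  if (length(bad))
    stop("unknown actionability level: ", paste(bad, collapse = ", "),
         call. = FALSE)
  act <- muts[lv %in% actionability_order, , drop = FALSE]
  alteration_counts <- table(factor(act$level, actionability_order))
  total <- sum(alteration_counts)
  sample_levels <- vapply(patients, function(p) {
    lvp <- act$level[act$patient_id == p]
    if (length(lvp) == 0) return("none")
    actionability_order[min(match(lvp, actionability_order))]
  }, character(1))
  sample_counts <- table(factor(sample_levels, c(actionability_order, "none")))
  n_act <- sum(sample_levels != "none")
  list(
    alteration_counts = alteration_counts,
    alteration_pct = if (total > 0) 100 * alteration_counts / total else
      alteration_counts * NA_real_,
    n_actionable_alterations = total,
    sample_levels = sample_levels,
    sample_counts = sample_counts,
    n_actionable_samples = n_act,
    pct_actionable_samples = 100 * n_act / length(patients),
    pct_level1_of_actionable = if (n_act > 0)
      100 * sum(sample_levels == "L1") / n_act else NA_real_)
}

#' 1:1 propensity-score matching with a caliper
#'
#' Logistic propensity on the listed covariates; greedy nearest-neighbour
#' matching without replacement within a caliper of 0.2 standard deviations
#' of the logit propensity. Case order is randomized (set a seed for
#' reproducibility); unmatched cases are reported.
#'
#' @param data data.frame containing `case` (0/1) and the covariates.
#' @param covariates character vector of covariate column names.
#' @param caliper_sd caliper width in SD units of the logit propensity.
#' @return list: `pairs` (data.frame case/control row indices),
#'   `unmatched` (case row indices), `propensity` (logit scale), `smd`
#'   (pre/post standardized mean differences per covariate).
#' @export
propensity_match <- function(data, covariates, caliper_sd = 0.2) {
  if (any(!covariates %in% colnames(data)))
    stop("missing covariate columns", call. = FALSE)
  if (anyNA(data[, covariates]))
    stop("covariates must be complete", call. = FALSE)
  informative <- covariates[vapply(covariates, function(v)
    stats::sd(as.numeric(data[[v]])) > 0, logical(1))]
  if (length(informative)) {
    m <- fit_logistic(data$case, data[, informative, drop = FALSE])
    lp <- stats::qlogis(score_logistic(m, data[, informative, drop = FALSE]))
  } else lp <- rep(0, nrow(data))  # indistinguishable subjects
  caliper <- caliper_sd * stats::sd(lp)
  cases <- which(data$case == 1)
  controls <- which(data$case == 0)
  available <- rep(TRUE, length(controls))
  pairs <- list(); unmatched <- integer(0)
  for (i in sample(cases)) {
    d <- abs(lp[controls] - lp[i])
    d[!available] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= caliper) {
      pairs[[length(pairs) + 1]] <- c(case = i, control = controls[j])
      available[j] <- FALSE
    } else unmatched <- c(unmatched, i)
  }
  if (length(pairs) == 0)
    warning("no controls within caliper for any case", call. = FALSE)
  pairs <- if (length(pairs)) as.data.frame(do.call(rbind, pairs)) else
    data.frame(case = integer(0), control = integer(0))
  smd <- function(idx_a, idx_b) vapply(covariates, function(v) {
    xa <- as.numeric(data[[v]][idx_a]); xb <- as.numeric(data[[v]][idx_b])
    s <- sqrt((stats::var(xa) + stats::var(xb)) / 2)
    if (s == 0) 0 else abs(mean(xa) - mean(xb)) / s
  }, numeric(1))
  list(pairs = pairs, unmatched = unmatched, propensity = lp,
       smd = cbind(pre = smd(cases, controls),
                   post = if (nrow(pairs)) smd(pairs$case, pairs$control)
                          else rep(NA_real_, length(covariates))))
}
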