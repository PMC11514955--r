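#' Read and validate a cell table
#'
#' CSV with header columns `cell_id, patient_id, roi_id, batch_id, x_um,
#' y_um, panck, cd4, cd8, foxp3, cd68, pdl1` (coordinates in microns).
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_cell_table <- function(path) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cell_table(cells)
}

#' @rdname read_cell_table
#' @param cells cell table to validate or write.
#' @export
validate_cell_table <- function(cells) {
  need <- c("cell_id", "patient_id", "roi_id", "batch_id", "x_um", "y_um",
            marker_names())
  miss <- setdiff(need, colnames(cells))
  if (length(miss))
    stop("cell table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(cells$x_um)) || any(!is.finite(cells$y_um)))
    stop("coordinates must be finite", call. = FALSE)
  if (any(as.matrix(cells[, marker_names()]) < 0))
    stop("marker intensities must be non-negative", call. = FALSE)
  if (anyDuplicated(cells[, c("roi_id", "cell_id")]))
    stop("duplicate (roi_id, cell_id)", call. = FALSE)
  cells
}

#' @rdname read_cell_table
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(validate_cell_table(cells), path, row.names = FALSE)
  invisible(path)
}

mutation_classes <- c("nonsynonymous_snv", "indel", "cnv", "fusion")

#' Read and validate a mutation table
#'
#' Tab-separated with header `patient_id, gene, class, vaf, oncogenic,
#' level` (a MAF-subset dialect). VAF must lie in (0, 1] and may be empty
#' for cnv/fusion rows.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_mutation_table <- function(path) {
  muts <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  validate_mutation_table(muts)
}

#' @rdname read_mutation_table
#' @param muts mutation table to validate or write.
#' @export
validate_mutation_table <- function(muts) {
  need <- c("patient_id", "gene", "class", "vaf", "oncogenic", "level")
  miss <- setdiff(need, colnames(muts))
  if (length(miss))
    stop("mutation table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(muts) == 0) return(muts)
  bad_class <- setdiff(unique(muts$class), mutation_classes)
  if (length(bad_class))
    stop("unknown alteration class: ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  bad_vaf <- which(!is.na(muts$vaf) & (muts$vaf <= 0 | muts$vaf > 1))
  if (length(bad_vaf))
    stop("VAF outside (0, 1] at row(s): ",
         paste(utils::head(bad_vaf, 5), collapse = ", "), call. = FALSE)
  if (any(!nzchar(muts$gene)))
    stop("empty gene symbol", call. = FALSE)
  muts
}

#' @rdname read_mutation_table
#' @export
write_mutation_table <- function(muts, path) {
  utils::write.table(validate_mutation_table(muts), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble per-patient feature blocks for the ImGene predictor
#'
#' ImFeatures: per-patient metacluster fractions of total and of immune
#' cells. GeneFeatures: driver-gene mutation indicators plus mutation
#' count, TMB and MATH.
#'
#' @param cells cell table with a `metacluster` column.
#' @param muts mutation table.
#' @param clinical clinical table.
#' @param panel_mb covered megabases.
#' @return list `im` and `gene` feature matrices (rownames = patient ids).
#' @export
build_feature_blocks <- function(cells, muts, clinical, panel_mb = 1.21) {
  lev <- metacluster_levels()
  tab <- table(cells$patient_id, factor(cells$metacluster, lev))
  total <- sweep(as.matrix(tab), 1, rowSums(tab), `/`)
  colnames(total) <- paste0("frac_total_", lev)
  imm <- cells$metacluster %in% immune_metaclusters()
  tab_i <- table(factor(cells$patient_id[imm], rownames(tab)),
                 factor(cells$metacluster[imm], immune_metaclusters()))
  denom <- rowSums(tab_i)
  imm_frac <- sweep(as.matrix(tab_i), 1, pmax(denom, 1), `/`)
  colnames(imm_frac) <- paste0("frac_immune_", immune_metaclusters())
  im <- cbind(total, imm_frac)

  ids <- rownames(im)
  genes <- setdiff(unique(muts$gene), grep("^PSG", unique(muts$gene),
                                           value = TRUE))
  ind <- sapply(genes, function(g)
    as.numeric(ids %in% muts$patient_id[muts$gene == g]))
  rownames(ind) <- ids
  gs <- genomic_summary(muts, data.frame(patient_id = ids), panel_mb)
  gene <- cbind(ind, mutation_count = gs$mutation_count, tmb = gs$tmb,
                math = ifelse(is.na(gs$math), 0, gs$math))
  list(im = im, gene = gene)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Stages run in order: simulate, genomics, phenotype, spatial, subtype,
#' imgene; each stage is deterministic given the seed and can be toggled
#' off. Returns a run report holding every stage's outputs and headline
#' statistics.
#'
#' @param config a [sim_config()].
#' @param seed global RNG seed.
#' @param stages character vector of stages to run.
#' @param n_perm permutations for the interaction test.
#' @param k_cn number of cellular neighbourhoods.
#' @param cn_window neighbourhood window size.
#' @return list of class `imgene_run` with one element per completed stage.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1,
                         stages = c("simulate", "genomics", "phenotype",
                                    "spatial", "subtype", "imgene"),
                         n_perm = 200, k_cn = 10, cn_window = 20) {
  report <- list(seed = seed, stages = stages)
  cohort <- simulate_cohort(config, seed = seed)
  report$cohort <- cohort
  clin <- cohort$clinical
  groups <- setNames(clin$pn, clin$patient_id)

  if ("genomics" %in% stages) {
    gs <- genomic_summary(cohort$mutations, clin, config$panel_mb)
    gs$pn <- clin$pn[match(gs$patient_id, clin$patient_id)]
    report$genomics <- list(
      summary = gs,
      gene_tests = compare_gene_frequencies(cohort$mutations, clin),
      pathways = pathway_alteration_frequency(cohort$mutations, clin),
      actionability = actionability_summary(cohort$mutations,
                                            clin$patient_id),
      tmb_test = mann_whitney(gs$tmb[gs$pn == "pos"], gs$tmb[gs$pn == "neg"]),
      math_test = mann_whitney(gs$math[gs$pn == "pos" & !is.na(gs$math)],
                               gs$math[gs$pn == "neg" & !is.na(gs$math)]))
  }

  cells <- cohort$cells
  if ("phenotype" %in% stages) {
    emb <- transform_markers(cells)
    corrected <- embed_and_correct(emb, cells$batch_id)
    cells$metacluster <- assign_metaclusters(emb)
    report$phenotype <- list(
      embedding = corrected,
      composition_total = composition_compare(cells$metacluster,
                                              cells$patient_id, groups,
                                              "total"),
      composition_immune = composition_compare(cells$metacluster,
                                               cells$patient_id, groups,
                                               "immune"))
    report$cells <- cells
  }

  if ("spatial" %in% stages && "phenotype" %in% stages) {
    rois <- split(seq_len(nrow(cells)), cells$roi_id)
    windows <- do.call(rbind, lapply(rois, function(idx)
      neighborhood_windows(cells$x_um[idx], cells$y_um[idx],
                           cells$metacluster[idx], k = cn_window)))
    ord <- unlist(rois, use.names = FALSE)
    windows <- windows[order(ord), , drop = FALSE]
    cn <- cluster_cns(windows, k_cn = k_cn, seed = seed)
    report$spatial <- list(
      cn = cn,
      cn_analysis = cn_group_analysis(cn, cells$patient_id, groups,
                                      cells$metacluster,
                                      muts = cohort$mutations),
      interactions = interaction_test(cells, n_perm = n_perm, seed = seed,
                                      groups = setNames(
                                        groups[cells$patient_id[!duplicated(cells$roi_id)]],
                                        unique(cells$roi_id))))
    cells$cn <- cn$cn
    report$cells <- cells
  }

  if ("subtype" %in% stages && "phenotype" %in% stages) {
    lev <- metacluster_levels()
    roi_comp <- table(cells$roi_id, factor(cells$metacluster, lev))
    roi_comp <- sweep(as.matrix(roi_comp), 1, rowSums(roi_comp), `/`)
    sub <- cnmf(roi_comp, rank = 2, iters = 50, seed = seed)
    roi_patient <- setNames(cells$patient_id[!duplicated(cells$roi_id)],
                            unique(cells$roi_id))[rownames(roi_comp)]
    pat_sub <- integrate_roi_labels(sub, roi_patient)
    pat_comp <- table(cells$patient_id, factor(cells$metacluster, lev))
    pat_comp <- sweep(as.matrix(pat_comp), 1, rowSums(pat_comp), `/`)
    report$subtype <- list(
      result = sub, patient_subtype = pat_sub,
      associations = subtype_associations(pat_sub, clin, pat_comp,
                                          cohort$mutations))
  }

  if ("imgene" %in% stages && "phenotype" %in% stages) {
    blocks <- build_feature_blocks(cells, cohort$mutations, clin,
                                   config$panel_mb)
    labels <- setNames(as.numeric(groups[rownames(blocks$im)] == "pos"),
                       rownames(blocks$im))
    report$imgene <- tryCatch(
      imgene_fit(blocks$im, blocks$gene, labels, seed = seed),
      error = function(e) {
        warning("imgene stage failed: ", conditionMessage(e), call. = FALSE)
        NULL
      })
  }

  class(report) <- "imgene_run"
  report
}

#' @export
print.imgene_run <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ")\n", sep = "")
  print(x$cohort)
  if (!is.null(x$genomics)) {
    sig <- x$genomics$gene_tests[x$genomics$gene_tests$significant, "gene"]
    cat("genomics: genes at q<0.1:", paste(sig, collapse = ", "), "\n")
  }
  if (!is.null(x$phenotype)) {
    tt <- x$phenotype$composition_total$tests
    cat(sprintf("phenotype: macrophage %.1f%% vs %.1f%% (p=%.3g); Treg %.2f%% vs %.2f%% (p=%.3g)\n",
                100 * tt$mean_pos[tt$metacluster == "Macrophage"],
                100 * tt$mean_neg[tt$metacluster == "Macrophage"],
                tt$p[tt$metacluster == "Macrophage"],
                100 * tt$mean_pos[tt$metacluster == "Treg"],
                100 * tt$mean_neg[tt$metacluster == "Treg"],
                tt$p[tt$metacluster == "Treg"]))
  }
  if (!is.null(x$subtype))
    cat(sprintf("subtype: silhouette %.3f, pN association p=%.3g\n",
                x$subtype$result$silhouette,
                x$subtype$associations$pn_test$p_value))
  if (!is.null(x$imgene)) { cat("imgene: "); print(x$imgene$report$imgene) }
  invisible(x)
}
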