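#' Simulate a synthetic spatial immunogenomic cohort
#'
#' Generates clinical covariates, a targeted-panel mutation table, and
#' per-cell mIHC tables with the statistical structure the downstream
#' analyses assume, plus a ground-truth record of every planted effect.
#' Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed; all randomness flows from it.
#' @return object of class `synthetic_cohort`: list with `clinical`,
#'   `mutations`, `cells`, and `truth` (per-cell true metaclusters, batch
#'   shifts, planted parameters).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  clinical <- simulate_clinical(config)
  mutations <- simulate_mutations(config, clinical)

  # imaged subset: even split across groups, mirroring 1:1 matching
  n_half <- config$n_mihc %/% 2
  mihc_ids <- c(sample(clinical$patient_id[clinical$pn == "pos"], n_half),
                sample(clinical$patient_id[clinical$pn == "neg"],
                       config$n_mihc - n_half))
  clinical$mihc <- clinical$patient_id %in% mihc_ids
  batch_of <- setNames(rep(paste0("B", seq_len(config$n_batches)),
                           length.out = length(mihc_ids)), mihc_ids)

  batch_shifts <- matrix(
    exp(stats::rnorm(config$n_batches * 6, 0, config$batch_shift_sdlog)),
    nrow = config$n_batches,
    dimnames = list(paste0("B", seq_len(config$n_batches)), marker_names()))

  cells <- vector("list", length(mihc_ids))
  truth_cells <- vector("list", length(mihc_ids))
  conc <- config$composition_concentration
  # latent TIME archetype per imaged patient (immune-enriched vs epithelial)
  grp_of <- setNames(clinical$pn, clinical$patient_id)
  p_immune <- unname(config$subtype_probs[ifelse(grp_of[mihc_ids] == "pos",
                                                 "pos", "neg")])
  archetype <- setNames(1L + stats::rbinom(length(mihc_ids), 1, p_immune),
                        mihc_ids)
  for (i in seq_along(mihc_ids)) {
    pid <- mihc_ids[i]
    grp <- clinical$pn[clinical$patient_id == pid]
    target <- config$archetype_fracs[archetype[[pid]], ]
    # the Treg fraction is tied directly to the nodal group (its printed
    # contrast is per-group); the archetype carries the epithelial and
    # macrophage contrasts that define the TIME subtypes
    target["Treg"] <- config$metacluster_fracs[
      if (grp == "pos") "pn_pos" else "pn_neg", "Treg"]
    target <- target / sum(target)
    # patient-level composition: Dirichlet jitter around the archetype target
    g <- stats::rgamma(length(target), shape = target * conc)
    comp <- g / sum(g)
    n_roi <- sample(config$rois_per_patient, 1)
    rois <- vector("list", n_roi)
    for (r in seq_len(n_roi)) {
      roi_id <- sprintf("%s_R%02d", pid, r)
      rois[[r]] <- simulate_roi(config, group = grp, roi_id = roi_id,
                                patient_id = pid, batch_id = batch_of[[pid]],
                                composition = comp,
                                batch_shift = batch_shifts[batch_of[[pid]], ])
    }
    rois <- do.call(rbind, rois)
    truth_cells[[i]] <- rois[, c("roi_id", "cell_id", "true_metacluster")]
    rois$true_metacluster <- NULL
    cells[[i]] <- rois
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  truth_cells <- do.call(rbind, truth_cells)
  rownames(truth_cells) <- NULL

  structure(list(
    clinical = clinical, mutations = mutations, cells = cells,
    truth = list(cell_metacluster = truth_cells,
                 patient_archetype = archetype,
                 batch_shifts = batch_shifts,
                 gene_table = config$gene_table,
                 metacluster_fracs = config$metacluster_fracs,
                 seed = seed)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d patients (%d pN+), %d imaged (%d ROIs, %d cells), %d alterations\n",
    nrow(x$clinical), sum(x$clinical$pn == "pos"), sum(x$clinical$mihc),
    length(unique(x$cells$roi_id)), nrow(x$cells), nrow(x$mutations)))
  invisible(x)
}

# Clinical covariates drawn per group with the cohort's characteristic-table
# proportions; tumor size log-normal with group-specific medians (2.3 vs 2.9 cm).
simulate_clinical <- function(config) {
  n <- config$n_patients
  npos <- config$n_pn_positive
  pn <- c(rep("neg", n - npos), rep("pos", npos))
  p <- function(p_neg, p_pos) ifelse(pn == "neg", p_neg, p_pos)
  if (config$null_effects) p <- function(p_neg, p_pos) {
    rep((p_neg + p_pos) / 2, length(pn))
  }
  rb <- function(prob) stats::rbinom(n, 1, prob)
  hist_probs <- cbind(
    ACI_PAP = p(0.745, 0.434), MIP_SOL = p(0.147, 0.547),
    LEP = p(0.034, 0.000), Others = p(0.074, 0.019))
  hist_probs <- hist_probs / rowSums(hist_probs)
  histology <- vapply(seq_len(n), function(i)
    sample(colnames(hist_probs), 1, prob = hist_probs[i, ]), character(1))
  size_meanlog <- ifelse(pn == "neg", log(2.3), log(2.9))
  size_sdlog <- ifelse(pn == "neg", 0.49, 0.33)
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    pn = pn,
    sex_male = rb(p(0.456, 0.434)),
    smoking = rb(p(0.284, 0.283)),
    nodule_solid = rb(p(0.529, 0.906)),
    histology = histology,
    tumor_size_cm = round(stats::rlnorm(n, size_meanlog, size_sdlog), 1),
    path_stas = rb(p(0.113, 0.170)),
    path_vpi = rb(p(0.172, 0.566)),
    path_lvi = rb(p(0.255, 0.717)),
    mihc = FALSE,
    stringsAsFactors = FALSE)
}

# Per-patient alterations: driver genes Bernoulli with group frequency; total
# nonsynonymous count Poisson with group mean (passengers fill the gap, so
# the TMB numerator follows the Poisson target); VAF Beta with wider
# dispersion in pN-positive tumors; occasional CNVs/fusions (no VAF, outside
# the TMB numerator).
simulate_mutations <- function(config, clinical) {
  gt <- config$gene_table
  onc_labels <- c("oncogenic", "likely", "predicted")
  out <- vector("list", nrow(clinical))
  for (i in seq_len(nrow(clinical))) {
    grp <- clinical$pn[i]
    freq <- if (grp == "pos") gt$freq_pos else gt$freq_neg
    lambda <- if (grp == "pos") config$mut_lambda_pos else config$mut_lambda_neg
    shp <- if (grp == "pos") config$vaf_shape_pos else config$vaf_shape_neg
    hit <- stats::runif(nrow(gt)) < freq
    genes <- gt$gene[hit]
    n_total <- max(length(genes), stats::rpois(1, lambda))
    n_psg <- n_total - length(genes)
    psg <- if (n_psg > 0) sprintf("PSG%03d", sample(1:500, n_psg)) else character(0)
    gene <- c(genes, psg)
    if (length(gene) == 0) next
    cls <- sample(c("nonsynonymous_snv", "indel"), length(gene),
                  replace = TRUE, prob = c(0.85, 0.15))
    vaf <- pmin(stats::rbeta(length(gene), shp[1], shp[2]) + 1e-4, 1)
    onc <- ifelse(
      gene %in% genes & stats::runif(length(gene)) < rep(
        gt$oncogenic_prob[hit], length.out = length(gene)) & gene %in% genes,
      sample(onc_labels, length(gene), replace = TRUE, prob = c(0.6, 0.3, 0.1)),
      "vus")
    level <- rep("none", length(gene))
    idx <- match(gene, gt$gene)
    drv <- !is.na(idx) & onc != "vus"
    level[drv] <- gt$level[idx[drv]]
    rec <- data.frame(patient_id = clinical$patient_id[i], gene = gene,
                      class = cls, vaf = vaf, oncogenic = onc, level = level,
                      stringsAsFactors = FALSE)
    # sprinkle CNVs / fusions on top (mutation count, not TMB)
    if (stats::runif(1) < 0.10 && length(genes) > 0)
      rec <- rbind(rec, data.frame(
        patient_id = clinical$patient_id[i], gene = sample(genes, 1),
        class = "cnv", vaf = NA_real_, oncogenic = "likely", level = "none"))
    if (stats::runif(1) < 0.03)
      rec <- rbind(rec, data.frame(
        patient_id = clinical$patient_id[i], gene = "ALK",
        class = "fusion", vaf = NA_real_, oncogenic = "oncogenic", level = "L1"))
    out[[i]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate one mIHC region of interest
#'
#' Epithelial cells are placed as a Thomas-type clustered process (tumor
#' nests); immune and other cells as uniform points; in pN-positive ROIs a
#' fraction of macrophages is drawn toward nest centers (contact enrichment).
#' Marker intensities are log-normal around the true-metacluster profile,
#' multiplied by per-batch shifts. Coordinates are continuous microns in a
#' square ROI, origin top-left.
#'
#' @param config a [sim_config()].
#' @param group `"pos"` or `"neg"` nodal group.
#' @param roi_id,patient_id,batch_id identifiers stamped on each cell.
#' @param composition optional length-9 composition vector (defaults to the
#'   group target).
#' @param batch_shift named length-6 multiplicative marker shift (default 1).
#' @return data.frame with the cell-table schema plus `true_metacluster`.
#' @export
simulate_roi <- function(config, group = c("neg", "pos"), roi_id = "ROI1",
                         patient_id = "P000", batch_id = "B1",
                         composition = NULL, batch_shift = NULL) {
  group <- match.arg(group)
  if (is.null(composition))
    composition <- config$metacluster_fracs[
      if (group == "pos") "pn_pos" else "pn_neg", ]
  if (is.null(batch_shift))
    batch_shift <- setNames(rep(1, 6), marker_names())
  L <- config$roi_size_um
  n <- max(25L, stats::rpois(1, config$cells_per_roi))
  lev <- metacluster_levels()
  type <- lev[sample.int(9, n, replace = TRUE, prob = composition)]

  x <- stats::runif(n, 0, L)
  y <- stats::runif(n, 0, L)
  parents <- cbind(stats::runif(config$nest_parents, 0.2 * L, 0.8 * L),
                   stats::runif(config$nest_parents, 0.2 * L, 0.8 * L))
  epi <- type %in% c("Epithelial", "PDL1pos_Epithelial")
  if (any(epi)) {
    pa <- sample.int(nrow(parents), sum(epi), replace = TRUE)
    x[epi] <- parents[pa, 1] + stats::rnorm(sum(epi), 0, config$nest_sd_um)
    y[epi] <- parents[pa, 2] + stats::rnorm(sum(epi), 0, config$nest_sd_um)
  }
  mac <- type == "Macrophage"
  if (group == "pos" && any(mac) && config$contact_frac > 0) {
    pull <- mac & stats::runif(n) < config$contact_frac
    if (any(pull)) {
      pa <- sample.int(nrow(parents), sum(pull), replace = TRUE)
      x[pull] <- parents[pa, 1] + stats::rnorm(sum(pull), 0, config$contact_sd_um)
      y[pull] <- parents[pa, 2] + stats::rnorm(sum(pull), 0, config$contact_sd_um)
    }
  }
  # immune-suppressed niche: Tregs and PD-L1+ macrophages co-locate at one
  # niche center in pN-positive ROIs
  sup <- type %in% c("Treg", "PDL1pos_Macrophage")
  if (group == "pos" && any(sup) && config$contact_frac > 0) {
    niche <- c(stats::runif(1, 0.2 * L, 0.8 * L),
               stats::runif(1, 0.2 * L, 0.8 * L))
    pull <- sup & stats::runif(n) < config$contact_frac
    if (any(pull)) {
      x[pull] <- niche[1] + stats::rnorm(sum(pull), 0, config$contact_sd_um)
      y[pull] <- niche[2] + stats::rnorm(sum(pull), 0, config$contact_sd_um)
    }
  }
  x <- pmin(pmax(x, 0), L)
  y <- pmin(pmax(y, 0), L)

  mu <- config$marker_profile[type, , drop = FALSE]
  raw <- matrix(stats::rlnorm(n * 6, meanlog = log(mu),
                              sdlog = config$marker_sdlog), nrow = n)
  raw <- sweep(raw, 2, batch_shift[marker_names()], `*`)
  colnames(raw) <- marker_names()

  out <- data.frame(cell_id = sprintf("c%04d", seq_len(n)),
                    patient_id = patient_id, roi_id = roi_id,
                    batch_id = batch_id, x_um = x, y_um = y,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(raw))
  out$true_metacluster <- type
  out
}
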