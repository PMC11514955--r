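#' Metacluster label set
#'
#' The 9 phenotypic classes assigned from the 6-marker panel
#' (PANCK, CD4, CD8, FOXP3, CD68, PD-L1).
#'
#' @return character vector of length 9.
#' @export
metacluster_levels <- function() {
  c("Epithelial", "PDL1pos_Epithelial", "CD4_T", "CD8_T", "Treg",
    "Macrophage", "PDL1pos_Macrophage", "Other_Immune", "Other")
}

#' Marker column names of a cell table
#' @return character vector of length 6.
#' @export
marker_names <- function() c("panck", "cd4", "cd8", "foxp3", "cd68", "pdl1")

#' Default per-gene alteration frequencies by nodal group
#'
#' TP53 (55% vs 37%) and PIK3CG (7.5% vs 0.5%) carry the planted group
#' differences; the remaining drivers sit at their overall cohort
#' frequencies with no group effect. Evidence levels follow a static
#' OncoKB-style table.
#'
#' @return data.frame: gene, freq_neg, freq_pos, oncogenic_prob, level.
#' @export
default_gene_table <- function() {
  data.frame(
    gene = c("EGFR", "TP53", "KRAS", "RBM10", "RB1", "STK11", "SETD2",
             "SF3B1", "PTEN", "HGF", "BRAF", "ARID1A", "KEAP1", "PIK3CG",
             "ATM", "PIK3CA", "CTNNB1", "BRD4", "KMT2B"),
    freq_neg = c(0.66, 0.37, 0.12, 0.08, 0.05, 0.03, 0.04,
                 0.03, 0.03, 0.04, 0.02, 0.05, 0.02, 0.005,
                 0.05, 0.04, 0.05, 0.02, 0.02),
    freq_pos = c(0.66, 0.55, 0.12, 0.08, 0.05, 0.03, 0.04,
                 0.03, 0.03, 0.04, 0.08, 0.05, 0.02, 0.075,
                 0.08, 0.08, 0.05, 0.05, 0.05),
    oncogenic_prob = c(0.95, 0.9, 0.95, 0.7, 0.8, 0.8, 0.6,
                       0.6, 0.7, 0.5, 0.9, 0.6, 0.8, 0.6,
                       0.6, 0.9, 0.8, 0.5, 0.5),
    level = c("L1", "none", "L1", "none", "none", "L4", "none",
              "none", "L4", "L3B", "L1", "none", "none", "L3B",
              "L3B", "L3A", "none", "none", "none"),
    stringsAsFactors = FALSE
  )
}

#' Default per-group metacluster composition targets
#'
#' Macrophage (7.1% vs 4.8% of total cells) and Treg (0.85% vs 0.29%)
#' carry the planted differences; immune infiltrate totals ~36.5% vs
#' ~31.1%.
#'
#' @return 2 x 9 matrix with rows `pn_neg`, `pn_pos`.
#' @export
default_metacluster_fracs <- function() {
  m <- rbind(
    pn_neg = c(0.5000, 0.050, 0.060, 0.060, 0.0029, 0.048, 0.012, 0.130, 0.1371),
    pn_pos = c(0.4400, 0.060, 0.055, 0.065, 0.0085, 0.071, 0.018, 0.148, 0.1345))
  colnames(m) <- metacluster_levels()
  m
}

# Solve the two-archetype mixture so that per-group composition targets are
# preserved in expectation: group = w * immune-enriched + (1-w) * epithelial
# archetype, with archetype weights w given by subtype_probs. Negative
# solutions (possible for very rare classes) are clipped and renormalized.
archetype_fracs <- function(metacluster_fracs, subtype_probs) {
  w_neg <- subtype_probs["neg"]; w_pos <- subtype_probs["pos"]
  det <- (1 - w_neg) * w_pos - w_neg * (1 - w_pos)
  tn <- metacluster_fracs["pn_neg", ]; tp <- metacluster_fracs["pn_pos", ]
  c1 <- (w_pos * tn - w_neg * tp) / det         # epithelial archetype
  c2 <- ((1 - w_neg) * tp - (1 - w_pos) * tn) / det  # immune-enriched
  # floor keeps every Dirichlet component non-degenerate (alpha not << 1)
  c1 <- pmax(c1, 1e-3); c2 <- pmax(c2, 1e-3)
  rbind(subtype1 = c1 / sum(c1), subtype2 = c2 / sum(c2))
}

# Mean marker intensity by true metacluster (rows) and marker (cols).
# Positive markers ~40 counts, background ~2; per-cell log-normal noise.
default_marker_profile <- function() {
  hi <- 40; lo <- 2
  m <- matrix(lo, nrow = 9, ncol = 6,
              dimnames = list(metacluster_levels(), marker_names()))
  m["Epithelial", "panck"] <- hi
  m["PDL1pos_Epithelial", c("panck", "pdl1")] <- hi
  m["CD4_T", "cd4"] <- hi
  m["CD8_T", "cd8"] <- hi
  m["Treg", c("cd4", "foxp3")] <- hi
  m["Macrophage", "cd68"] <- hi
  m["PDL1pos_Macrophage", c("cd68", "pdl1")] <- hi
  m["Other_Immune", "foxp3"] <- hi
  m
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions the analysis assumes: 257 patients
#' (204 pN-negative, 53 pN-positive), a 92-patient mIHC subset (46 per group,
#' mirroring 1:1 matching) imaged over 5-8 regions of interest (ROIs) per
#' patient (~597 ROIs), a 1.21 Mb targeted panel, group-specific driver
#' frequencies (TP53 55% vs 37%, PIK3CG 7.5% vs 0.5%), nonsynonymous mutation
#' counts with medians 6 vs 4 (so TMB medians land near 4.74 vs 3.16
#' mutations/Mb), wider VAF dispersion in pN-positive tumors (MATH medians
#' near 53 vs 46), and spatial enrichment of macrophages and Tregs in
#' pN-positive tissue.
#'
#' @param n_patients total cohort size.
#' @param n_pn_positive number of pN-positive patients.
#' @param n_mihc size of the imaged subset (split evenly across groups).
#' @param rois_per_patient integer vector ROI counts are drawn from.
#' @param cells_per_roi Poisson mean cell count per ROI.
#' @param roi_size_um ROI side length, microns (square ROI).
#' @param panel_mb megabases covered by the sequencing panel.
#' @param gene_table data.frame(gene, freq_neg, freq_pos, oncogenic_prob, level).
#' @param mut_lambda_neg,mut_lambda_pos Poisson means for per-patient
#'   nonsynonymous mutation counts by group.
#' @param vaf_shape_neg,vaf_shape_pos Beta shape pairs for VAF draws.
#' @param metacluster_fracs 2 x 9 matrix of composition targets
#'   (rows `pn_neg`, `pn_pos`).
#' @param composition_concentration Dirichlet concentration controlling
#'   between-patient composition variability.
#' @param subtype_probs named probabilities (`neg`, `pos`) that a patient of
#'   each nodal group carries the immune-enriched (macrophage/Treg) TIME
#'   archetype rather than the epithelial archetype; the two archetype
#'   compositions are derived so the group-level targets hold in
#'   expectation.
#' @param n_batches number of mIHC staining batches.
#' @param batch_shift_sdlog sdlog of the per-batch multiplicative marker
#'   shifts (0 = no batch effect).
#' @param marker_profile 9 x 6 matrix of mean marker intensities.
#' @param marker_sdlog per-cell log-normal intensity noise.
#' @param nest_parents tumor-nest (Thomas process) parent count per ROI.
#' @param nest_sd_um Gaussian spread of epithelial cells around nest centers.
#' @param contact_frac fraction of macrophages drawn toward epithelial nests
#'   in pN-positive ROIs.
#' @param contact_sd_um spread of nest-associated macrophages.
#' @param null_effects if TRUE, all group differences are removed (both
#'   groups receive the pooled parameters); used for type-I calibration.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 257, n_pn_positive = 53, n_mihc = 92,
                       rois_per_patient = 5:8, cells_per_roi = 80,
                       roi_size_um = 200, panel_mb = 1.21,
                       gene_table = default_gene_table(),
                       mut_lambda_neg = 3.82, mut_lambda_pos = 5.74,
                       vaf_shape_neg = c(2.05, 6.15), vaf_shape_pos = c(1.7, 5.1),
                       metacluster_fracs = default_metacluster_fracs(),
                       composition_concentration = 800,
                       subtype_probs = c(neg = 0.25, pos = 0.7),
                       n_batches = 4, batch_shift_sdlog = 0.25,
                       marker_profile = default_marker_profile(),
                       marker_sdlog = 0.2,
                       nest_parents = 3, nest_sd_um = 25,
                       contact_frac = 0.6, contact_sd_um = 15,
                       null_effects = FALSE) {
  if (n_pn_positive > n_patients)
    stop("n_pn_positive must not exceed n_patients", call. = FALSE)
  if (any(gene_table$freq_neg < 0 | gene_table$freq_neg > 1) ||
      any(gene_table$freq_pos < 0 | gene_table$freq_pos > 1))
    stop("gene frequencies must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(metacluster_fracs) - 1) > 1e-6))
    stop("metacluster compositions must sum to 1 per group", call. = FALSE)
  if (roi_size_um <= 0) stop("ROI dimensions must be positive", call. = FALSE)
  if (null_effects) {
    f <- (gene_table$freq_neg + gene_table$freq_pos) / 2
    gene_table$freq_neg <- gene_table$freq_pos <- f
    lam <- (mut_lambda_neg + mut_lambda_pos) / 2
    mut_lambda_neg <- mut_lambda_pos <- lam
    vaf_shape_pos <- vaf_shape_neg
    fr <- colMeans(metacluster_fracs)
    metacluster_fracs <- rbind(pn_neg = fr / sum(fr), pn_pos = fr / sum(fr))
    contact_frac <- 0
    pbar <- mean(subtype_probs)
    subtype_probs <- c(neg = pbar, pos = pbar)
  }
  structure(list(
    n_patients = n_patients, n_pn_positive = n_pn_positive, n_mihc = n_mihc,
    rois_per_patient = rois_per_patient, cells_per_roi = cells_per_roi,
    roi_size_um = roi_size_um, panel_mb = panel_mb, gene_table = gene_table,
    mut_lambda_neg = mut_lambda_neg, mut_lambda_pos = mut_lambda_pos,
    vaf_shape_neg = vaf_shape_neg, vaf_shape_pos = vaf_shape_pos,
    metacluster_fracs = metacluster_fracs,
    archetype_fracs = archetype_fracs(metacluster_fracs, subtype_probs),
    subtype_probs = subtype_probs,
    composition_concentration = composition_concentration,
    n_batches = n_batches, batch_shift_sdlog = batch_shift_sdlog,
    marker_profile = marker_profile, marker_sdlog = marker_sdlog,
    nest_parents = nest_parents, nest_sd_um = nest_sd_um,
    contact_frac = contact_frac, contact_sd_um = contact_sd_um,
    null_effects = null_effects), class = "sim_config")
}
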