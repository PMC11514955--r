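# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# A reduced cohort: full group structure at a fraction of the default size,
# enough for module-level recovery checks without full-cohort runtimes.
small_cohort <- function(seed = 7) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config(n_patients = 150, n_pn_positive = 40, n_mihc = 60,
                      rois_per_patient = 3:4, cells_per_roi = 70)
    .fixture_env[[key]] <- simulate_cohort(cfg, seed = seed)
  }
  .fixture_env[[key]]
}

# Printed-count actionability table: 260 actionable alterations over 257
# samples (184 L1 / 7 L3A / 23 L3B / 46 L4), arranged so 216 samples are
# actionable and 180 of them carry level-1 evidence.
printed_actionability_table <- function() {
  ids <- sprintf("S%03d", 1:257)
  rows <- list()
  add <- function(pat, level) data.frame(patient_id = pat, gene = "EGFR",
                                         class = "nonsynonymous_snv",
                                         vaf = 0.3, oncogenic = "oncogenic",
                                         level = level,
                                         stringsAsFactors = FALSE)
  # 180 L1-highest samples carrying 184 L1 alterations
  rows[[1]] <- add(ids[1:180], "L1")
  rows[[2]] <- add(ids[1:4], "L1")
  # 7 L3A-highest, 23 L3B-highest, 6 L4-highest samples
  rows[[3]] <- add(ids[181:187], "L3A")
  rows[[4]] <- add(ids[188:210], "L3B")
  rows[[5]] <- add(ids[211:216], "L4")
  # remaining 40 L4 alterations on already-actionable samples
  rows[[6]] <- add(ids[1:40], "L4")
  do.call(rbind, rows)
}

# Block-structured ROI composition fixture: two groups with disjoint
# dominant metaclusters.
block_composition <- function(n_per_block = 12, noise = 0.02, seed = 5) {
  set.seed(seed)
  lev <- metacluster_levels()
  base1 <- c(0.85, 0.05, 0.02, 0.02, 0.01, 0.01, 0.01, 0.02, 0.01)
  base2 <- c(0.05, 0.02, 0.10, 0.10, 0.15, 0.40, 0.10, 0.05, 0.03)
  V <- rbind(
    t(replicate(n_per_block, abs(base1 + stats::rnorm(9, 0, noise)))),
    t(replicate(n_per_block, abs(base2 + stats::rnorm(9, 0, noise)))))
  V <- V / rowSums(V)
  colnames(V) <- lev
  rownames(V) <- sprintf("ROI%02d", seq_len(nrow(V)))
  V
}
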