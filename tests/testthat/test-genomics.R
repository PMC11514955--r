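mut_row <- function(pat, gene, class = "nonsynonymous_snv", vaf = 0.3,
                    onc = "oncogenic", level = "none") {
  data.frame(patient_id = pat, gene = gene, class = class, vaf = vaf,
             oncogenic = onc, level = level, stringsAsFactors = FALSE)
}

test_that("compute_tmb is count over panel megabases", {
  muts <- mut_row(rep("P1", 6), paste0("G", 1:6))
  expect_equal(unname(compute_tmb(muts, 1.21, "P1")), 6 / 1.21,
               tolerance = 1e-9)
  expect_equal(6 / 1.21, 4.96, tolerance = 1e-2)
  # linearity: doubling the mutations doubles TMB
  muts2 <- rbind(muts, mut_row(rep("P1", 6), paste0("H", 1:6)))
  expect_equal(unname(compute_tmb(muts2, 1.21, "P1")),
               2 * unname(compute_tmb(muts, 1.21, "P1")))
  # cnv/fusion are excluded from the numerator
  muts3 <- rbind(muts, mut_row("P1", "ALK", class = "fusion", vaf = NA))
  expect_equal(unname(compute_tmb(muts3, 1.21, "P1")), 6 / 1.21)
  expect_error(compute_tmb(muts, 1.21, "P9"), "unknown patient")
  # additivity over disjoint subsets
  expect_equal(unname(compute_tmb(muts2, 1.21, "P1")),
               unname(compute_tmb(muts, 1.21, "P1")) +
                 unname(compute_tmb(muts2[7:12, ], 1.21, "P1")))
})

test_that("compute_math matches the scaled MAD/median definition", {
  expect_equal(compute_math(c(0.1, 0.2, 0.3, 0.4, 0.5)), 49.42,
               tolerance = 1e-2)
})

test_that("MATH properties: scale invariance, dispersion monotonicity, guards", {
  v <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(compute_math(v), 100 * 1.4826 * median(abs(v - median(v))) /
                 median(v), tolerance = 1e-9)
  expect_equal(compute_math(v), compute_math(v * 0.5), tolerance = 1e-9)
  expect_equal(compute_math(c(0.3, 0.3, 0.3)), 0)
  expect_true(is.na(compute_math(c(0.2, 0.4))))
  expect_true(is.na(compute_math(c(0, 0, 0))))
  # moving one value away from the median (median fixed) raises MATH
  v2 <- c(0.2, 0.25, 0.3, 0.35, 0.4)
  v3 <- c(0.2, 0.15, 0.3, 0.35, 0.4)
  expect_gt(compute_math(v3), compute_math(v2))
})

test_that("gene-frequency comparison flags printed PIK3CG counts", {
  clin <- data.frame(
    patient_id = sprintf("P%03d", 1:257),
    pn = c(rep("pos", 53), rep("neg", 204)), stringsAsFactors = FALSE)
  # printed reconstruction: 4/53 vs 1/204 mutated
  muts <- rbind(mut_row(clin$patient_id[1:4], "PIK3CG"),
                mut_row(clin$patient_id[54], "PIK3CG"),
                mut_row(clin$patient_id[c(1:29, 54:128)], "TP53"))
  res <- compare_gene_frequencies(muts, clin)
  expect_lt(res$p[res$gene == "PIK3CG"], 0.05)
  # TP53 at 29/53 vs 75/204: the printed 55% vs 37% reconstruction
  expect_equal(res$p[res$gene == "TP53"], 0.0193, tolerance = 1e-3)
  expect_true(all(res$q >= res$p - 1e-12))
  expect_error(compare_gene_frequencies(muts, clin[clin$pn == "pos", ]),
               "non-empty")
})

test_that("co-occurrence analysis signs and guards are correct", {
  pats <- sprintf("P%02d", 1:20)
  # perfectly exclusive pair
  muts <- rbind(mut_row(pats[1:10], "A"), mut_row(pats[11:20], "B"))
  res <- cooccurrence_analysis(muts, pats, c("A", "B"))
  expect_equal(unname(exp(res$log_odds)), 0, tolerance = 1e-6)
  expect_equal(res$direction, "exclusivity")
  # strong co-occurrence
  muts2 <- rbind(mut_row(pats[1:9], "A"), mut_row(pats[c(1:9, 15)], "B"))
  res2 <- cooccurrence_analysis(muts2, pats, c("A", "B"))
  expect_gt(res2$log_odds, 0)
  expect_lt(res2$p, 0.05)
  # monomorphic gene skipped
  muts3 <- rbind(muts2, mut_row(pats, "C"))
  expect_equal(nrow(cooccurrence_analysis(muts3, pats, c("A", "B", "C"))), 1)
  expect_error(cooccurrence_analysis(muts, pats, "A"), "2 genes")
})

test_that("pathway alteration frequency applies the VUS filter", {
  clin <- data.frame(patient_id = c("P1", "P2", "P3", "P4"),
                     pn = c("pos", "pos", "neg", "neg"),
                     stringsAsFactors = FALSE)
  muts <- rbind(mut_row(c("P1", "P2", "P3", "P4"), "TP53"),
                mut_row("P3", "NOVELGENE"),
                mut_row("P4", "KRAS", onc = "vus"))
  res <- pathway_alteration_frequency(muts, clin)
  expect_equal(unname(res$frequencies["p53", ]), c(1, 1))
  # VUS-only alteration does not make P4 RTK/RAS-altered
  expect_equal(unname(res$frequencies["RTK/RAS", "pn_neg"]), 0)
  expect_equal(res$unmapped, "NOVELGENE")
  res2 <- pathway_alteration_frequency(muts, clin, oncogenic_only = FALSE)
  expect_equal(unname(res2$frequencies["RTK/RAS", "pn_neg"]), 0.5)
})

test_that("actionability summary reproduces printed cohort arithmetic", {
  muts <- printed_actionability_table()
  res <- actionability_summary(muts, sprintf("S%03d", 1:257))
  expect_equal(as.integer(res$alteration_counts), c(184L, 7L, 23L, 46L))
  expect_equal(res$n_actionable_alterations, 260)
  expect_equal(unname(round(res$alteration_pct["L1"])), 71)
  expect_equal(unname(round(res$pct_actionable_samples)), 84)
  expect_equal(unname(round(res$pct_level1_of_actionable)), 83)
  # sample-level classification is a partition
  expect_equal(sum(res$sample_counts), 257)
  # highest-level rule
  m2 <- rbind(mut_row("X1", "A", level = "L3B"),
              mut_row("X1", "B", level = "L1"))
  expect_equal(unname(actionability_summary(m2, "X1")$sample_levels), "L1")
  expect_error(actionability_summary(mut_row("X1", "A", level = "L9")),
               "unknown actionability")
})

test_that("propensity matching respects the caliper and reduces imbalance", {
  set.seed(51)
  # identical covariates: everything matches
  d1 <- data.frame(case = rep(c(1, 0), each = 10), age = 60, size = 2)
  m1 <- propensity_match(d1, c("age", "size"))
  expect_equal(nrow(m1$pairs), 10)
  expect_length(m1$unmatched, 0)

  # one case far outside the caliper stays unmatched
  d2 <- data.frame(case = c(rep(1, 5), rep(0, 20)),
                   x = c(rnorm(4), 8, rnorm(20)))
  m2 <- propensity_match(d2, "x")
  expect_true(5 %in% m2$unmatched)

  # planted imbalance shrinks after matching
  d3 <- data.frame(case = rep(c(1, 0), c(30, 120)),
                   age = c(rnorm(30, 65, 5), rnorm(120, 58, 5)),
                   size = c(rnorm(30, 3, 0.5), rnorm(120, 2.2, 0.5)))
  m3 <- suppressWarnings(propensity_match(d3, c("age", "size")))
  expect_true(all(m3$smd[, "post"] < m3$smd[, "pre"]))
})
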