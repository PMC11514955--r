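#' Association tests on contingency tables and rank statistics
#'
#' Thin, validated wrappers around the classical tests used throughout the
#' pipeline. All return an `assoc_test` object with a uniform structure so
#' downstream tables can mix test types.
#'
#' @name assoc-tests
#' @keywords internal
NULL

new_assoc_test <- function(statistic, p_value, method, estimate = NA_real_,
                           alternative = "two.sided") {
  structure(
    list(statistic = unname(statistic), p_value = unname(p_value),
         method = method, estimate = unname(estimate),
         alternative = alternative),
    class = "assoc_test"
  )
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g", x$method,
              x$statistic, x$p_value))
  if (!is.na(x$estimate)) cat(sprintf(", estimate = %.4g", x$estimate))
  cat("\n")
  invisible(x)
}

check_counts <- function(tab) {
  tab <- as.matrix(tab)
  if (!is.numeric(tab) || any(!is.finite(tab)))
    stop("contingency table must contain finite numeric counts", call. = FALSE)
  if (any(tab < 0)) stop("contingency counts must be non-negative", call. = FALSE)
  if (any(tab != round(tab))) stop("contingency counts must be integers", call. = FALSE)
  if (sum(tab) == 0) stop("contingency table is empty", call. = FALSE)
  tab
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the sum-of-tables-at-most-as-probable convention
#' (the hypergeometric enumeration used by [stats::fisher.test()]); the
#' conditional MLE odds ratio is reported, with 0/Inf allowed for zero cells.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param alternative one of `"two.sided"`, `"less"`, `"greater"`.
#' @return an `assoc_test` with the odds ratio as `estimate`.
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2))
#' @export
fisher_exact <- function(tab, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  tab <- check_counts(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("fisher_exact requires a 2x2 table", call. = FALSE)
  ft <- stats::fisher.test(tab, alternative = alternative)
  new_assoc_test(NA_real_, ft$p.value, "fisher_exact",
                 estimate = ft$estimate, alternative = alternative)
}

#' Pearson chi-squared test on an r x c table
#'
#' @param tab r x c matrix of non-negative integer counts.
#' @param correct apply Yates continuity correction (2x2 only). Off by
#'   default: the uncorrected statistic is what reproduces the cohort
#'   characteristic-table p-values.
#' @return an `assoc_test` with the X-squared statistic.
#' @export
pearson_chi2 <- function(tab, correct = FALSE) {
  tab <- check_counts(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal total: expected counts undefined", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  new_assoc_test(ct$statistic, ct$p.value, "pearson_chi2")
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact for small samples without ties, normal approximation with tie
#' correction otherwise (the [stats::wilcox.test()] policy).
#'
#' @param x,y numeric samples.
#' @return an `assoc_test` with the U statistic as `estimate`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("mann_whitney requires non-empty samples", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  new_assoc_test(wt$statistic, wt$p.value, "mann_whitney_u",
                 estimate = wt$statistic)
}

#' Kruskal-Wallis H test
#'
#' @param values numeric vector.
#' @param groups factor of the same length with >= 2 levels.
#' @return an `assoc_test`.
#' @export
kruskal_wallis <- function(values, groups) {
  kt <- stats::kruskal.test(values, as.factor(groups))
  new_assoc_test(kt$statistic, kt$p.value, "kruskal_wallis")
}

#' Spearman rank correlation test
#'
#' @param x,y numeric vectors of equal length.
#' @return an `assoc_test` with rho as `estimate`.
#' @export
spearman_cor <- function(x, y) {
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  new_assoc_test(ct$statistic, ct$p.value, "spearman", estimate = ct$estimate)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up q-values in the original order of `p`. The default significance
#' threshold follows the pipeline-wide convention q < 0.1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param threshold FDR significance threshold (default 0.1).
#' @return list of class `fdr_result`: `p`, `q`, `threshold`, `significant`.
#' @export
bh_fdr <- function(p, threshold = 0.1) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  structure(list(p = p, q = q, threshold = threshold,
                 significant = q < threshold),
            class = "fdr_result")
}
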