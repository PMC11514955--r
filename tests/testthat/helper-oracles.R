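# Independent brute-force oracles used to validate the analytical paths.

# Two-sided Fisher p by full hypergeometric enumeration over all 2x2 tables
# with the observed margins (sum of tables at most as probable).
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a)
    stats::dhyper(a, r1, r2, c1), numeric(1))
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sided Mann-Whitney p by exhaustive enumeration of all group
# assignments (no ties assumed); mirrors the exact Wilcoxon distribution.
oracle_mw_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  idx <- utils::combn(n + m, n)
  u_of <- function(ix) {
    r <- rank(pooled)
    sum(r[ix]) - n * (n + 1) / 2
  }
  u_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  u_all <- apply(idx, 2, function(ix)
    sum(rank(pooled)[ix]) - n * (n + 1) / 2)
  mu <- n * m / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# AUC as the exhaustive pairwise concordance count.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  gr <- outer(pos, neg, `>`); eq <- outer(pos, neg, `==`)
  (sum(gr) + 0.5 * sum(eq)) / (length(pos) * length(neg))
}

# Exhaustive permutation null for the pairwise adjacency count of one
# metacluster pair in a toy ROI: every distinct relabeling, equally likely.
oracle_interaction <- function(labels, edges, type_a, type_b) {
  n <- length(labels)
  perms <- NULL
  permute_all <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      rest <- permute_all(v[-i])
      out <- c(out, lapply(rest, function(r) c(v[i], r)))
    }
    out
  }
  all_lab <- permute_all(labels)
  count_pair <- function(l) {
    a <- l[edges[, 1]]; b <- l[edges[, 2]]
    sum((a == type_a & b == type_b) | (a == type_b & b == type_a))
  }
  obs <- count_pair(labels)
  null <- vapply(all_lab, count_pair, numeric(1))
  list(obs = obs, null_mean = mean(null), null_sd = stats::sd(null),
       p_two = mean(abs(null - mean(null)) >= abs(obs - mean(null)) - 1e-9))
}

# point-in-polygon, even-odd rule
point_in_polygon <- function(px, py, xx, yy) {
  n <- length(xx); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (((yy[i] > py) != (yy[j] > py)) &&
        (px < (xx[j] - xx[i]) * (py - yy[i]) / (yy[j] - yy[i]) + xx[i]))
      inside <- !inside
    j <- i
  }
  inside
}
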