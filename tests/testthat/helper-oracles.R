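# Independent brute-force oracles, deliberately scalar and naive.

# quantile normalization on a complete matrix: sort each column, average
# across columns rank by rank, put the averages back in each column's order
oracle_quantile <- function(m) {
  ord <- apply(m, 2, order)
  target <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) out[ord[, j], j] <- target
  out
}

# Benjamini-Hochberg by the definition: q_i = min over j with p_j >= p_i of
# m * p_(j) / rank(j), capped at 1 (O(m^2))
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * p[o[j]] / j, 0)
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# AUC by pair counting with half-credit for ties
oracle_auc <- function(scores, is_tumor) {
  t <- scores[is_tumor]; c <- scores[!is_tumor]
  tot <- 0
  for (a in t) for (b in c)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(t) * length(c))
}

# Pearson chi-square by the definition
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e) ^ 2 / e)
}

# groupwise NaN-ignoring means by scalar loops
oracle_group_means <- function(m, groups) {
  out <- matrix(NA_real_, nrow(m), length(unique(groups)),
                dimnames = list(rownames(m), unique(groups)))
  for (i in seq_len(nrow(m))) for (g in unique(groups)) {
    v <- m[i, groups == g]
    v <- v[!is.na(v)]
    if (length(v)) out[i, g] <- sum(v) / length(v)
  }
  out
}

# up/down tallies by a scalar loop
oracle_dereg <- function(e) {
  up <- down <- zero <- miss <- 0
  for (v in e) {
    if (!is.finite(v)) miss <- miss + 1
    else if (v > 0) up <- up + 1
    else if (v < 0) down <- down + 1
    else zero <- zero + 1
  }
  c(up = up, down = down, zero = zero, miss = miss)
}

# average-linkage agglomeration by brute force; returns sorted merge heights
oracle_average_linkage_heights <- function(x) {
  groups <- as.list(seq_len(nrow(x)))
  d <- as.matrix(stats::dist(x))
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i >= j) next
      h <- mean(d[groups[[i]], groups[[j]]])
      if (h < bh) { bh <- h; best <- c(i, j) }
    }
    heights <- c(heights, bh)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  heights
}

# best WCSS over all 2-partitions of the rows (tiny n only)
oracle_best_wcss_k2 <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (code in 1:(2 ^ (n - 1) - 1)) {
    grp <- as.integer(intToBits(code))[1:n]
    if (all(grp == 0) || all(grp == 1)) next
    w <- 0
    for (g in 0:1) {
      xg <- x[grp == g, , drop = FALSE]
      w <- w + sum(sweep(xg, 2, colMeans(xg)) ^ 2)
    }
    best <- min(best, w)
  }
  best
}

# small random matrix, optionally with missing cells
rand_mat <- function(nr, nc, na_frac = 0) {
  m <- matrix(stats::rnorm(nr * nc, 8, 2), nr, nc,
              dimnames = list(paste0("F", seq_len(nr)),
                              paste0("S", seq_len(nc))))
  if (na_frac > 0)
    m[sample(length(m), round(na_frac * length(m)))] <- NA_real_
  m
}

# two-series toy study with one shared symbol
toy_series_pair <- function() {
  s1 <- series_table("A", "P1", c("hsa-miR-1", "hsa-miR-2", "hsa-miR-3"),
                     c("a1", "a2"), matrix(1:6, 3, 2))
  s2 <- series_table("B", "P2", c("hsa-miR-4", "hsa-miR-5", "hsa-miR-6"),
                     c("b1", "b2"), matrix(7:12, 3, 2))
  list(s1, s2)
}
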