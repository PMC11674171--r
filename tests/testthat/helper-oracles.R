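# Independent oracles used to cross-check the package implementations.
# Each is written as a direct, naive evaluation of the defining formula,
# sharing no code with the functions it checks.

oracle_skew <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  total <- 0
  for (xi in x) total <- total + ((xi - m) / s)^3
  n / ((n - 1) * (n - 2)) * total
}

oracle_kurt <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  total <- 0
  for (xi in x) total <- total + ((xi - m) / s)^4
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * total -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

# Naive tie-corrected Kruskal-Wallis by the rank formula.
oracle_kw <- function(values, groups) {
  groups <- as.character(groups)
  r <- rank(values)
  big_n <- length(values)
  h <- 0
  for (g in unique(groups)) {
    rg <- r[groups == g]
    h <- h + length(rg) * (mean(rg) - (big_n + 1) / 2)^2
  }
  h <- 12 / (big_n * (big_n + 1)) * h
  tie_sizes <- table(values)
  corr <- 1 - sum(tie_sizes^3 - tie_sizes) / (big_n^3 - big_n)
  h / corr
}

# Brute-force AUC by pairwise concordance, ties counting one half.
# Orientation: lower-positive (a positive scoring lower than a negative is
# concordant).
oracle_auc_lower <- function(pos, neg) {
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p < q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Least squares through the normal equations, solved directly.
oracle_ols <- function(x_mat, y) {
  solve(crossprod(x_mat), crossprod(x_mat, y))[, 1L]
}

# Signed standardized rank-sum statistic for one pair (used by the
# Steel-Dwass permutation checks).
oracle_pair_z <- function(x1, x2) {
  n1 <- length(x1)
  nn <- n1 + length(x2)
  r <- rank(c(x1, x2))
  r1 <- sum(r[seq_len(n1)])
  v <- n1 * length(x2) / (nn * (nn - 1)) * (sum(r^2) - nn * (nn + 1)^2 / 4)
  if (v <= 0) 0 else (r1 - n1 * (nn + 1) / 2) / sqrt(v)
}

# Family-wise permutation tail of the Steel-Dwass statistic: permutes all
# observations across the k groups and records the maximum of
# sqrt(2) * |z| over every pair.
oracle_sd_perm_tail <- function(values, sizes, q_obs, n_draws) {
  k <- length(sizes)
  idx <- split(seq_len(sum(sizes)), rep(seq_len(k), sizes))
  pairs <- utils::combn(k, 2L)
  draws <- replicate(n_draws, {
    p <- sample(values)
    max(vapply(seq_len(ncol(pairs)), function(j) {
      sqrt(2) * abs(oracle_pair_z(p[idx[[pairs[1L, j]]]],
                                  p[idx[[pairs[2L, j]]]]))
    }, numeric(1)))
  })
  vapply(q_obs, function(q) mean(draws >= q - 1e-12), numeric(1))
}
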