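#' Tie-corrected Kruskal-Wallis test
#'
#' Rank-based k-sample test of a location difference, the primary omnibus
#' test for the non-normally distributed per-cluster metrics. Mid-ranks are
#' used over the pooled sample; the statistic is divided by the tie
#' correction `1 - sum(t^3 - t) / (N^3 - N)` and referred to the chi-square
#' distribution with `k - 1` degrees of freedom. A completely tied sample is
#' returned as `H = 0`, `p = 1`.
#'
#' @param data A data frame with one row per cluster.
#' @param value <[`data-masking`][rlang::args_data_masking]> Numeric column
#'   to test.
#' @param group <[`data-masking`][rlang::args_data_masking]> Grouping column.
#' @return A one-row tibble: `statistic` (H), `df`, `p.value`, `n`.
#' @examples
#' d <- tibble::tibble(v = c(1, 2, 3, 4), g = c("a", "a", "b", "b"))
#' kruskal_wallis(d, v, g)  # H = 2.4
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- pull(data, {{ value }})
  g <- factor(pull(data, {{ group }}))
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]
  g <- droplevels(g[keep])
  if (nlevels(g) < 2L) {
    stop_hcg("Kruskal-Wallis needs at least 2 groups", "hcg_error_groups")
  }
  if (length(v) < 3L) {
    stop_hcg("Kruskal-Wallis needs a pooled n of at least 3", "hcg_error_groups")
  }
  if (length(unique(v)) == 1L) {
    return(tibble(statistic = 0, df = nlevels(g) - 1L, p.value = 1,
                  n = length(v)))
  }
  kt <- kruskal.test(v, g)
  tibble(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p.value = kt$p.value,
    n = length(v)
  )
}

# Signed Steel-Dwass statistic for one pair of samples, using mid-ranks of
# the combined pair and the tie-corrected variance
#   V = n1 n2 / (N (N - 1)) * (sum r^2 - N (N + 1)^2 / 4).
# A completely tied pair has V = 0 and is reported as z = 0.
steel_dwass_z <- function(x1, x2) {
  n1 <- length(x1)
  n2 <- length(x2)
  nn <- n1 + n2
  r <- rank(c(x1, x2))
  r1 <- sum(r[seq_len(n1)])
  e1 <- n1 * (nn + 1) / 2
  v <- n1 * n2 / (nn * (nn - 1)) * (sum(r^2) - nn * (nn + 1)^2 / 4)
  if (v <= 0) {
    return(0)
  }
  (r1 - e1) / sqrt(v)
}

#' Steel-Dwass all-pairs nonparametric multiple comparison
#'
#' Rank-based post hoc test for every unordered pair of groups, controlling
#' the family-wise error rate through the studentized-range distribution.
#' For each pair the combined two samples are mid-ranked, the standardized
#' rank-sum statistic `z` is computed with tie-corrected variance, and the
#' two-sided p-value is the upper tail of the studentized range for `k`
#' groups at infinite degrees of freedom evaluated at `sqrt(2) * |z|`
#' (large-sample approximation; no exact small-sample tables). Swapping a
#' pair flips the sign of `z` and leaves `p` unchanged; a completely tied
#' pair reports `z = 0`, `p = 1`.
#'
#' @inheritParams kruskal_wallis
#' @return A tibble with one row per unordered pair: `group1`, `group2`,
#'   `n1`, `n2`, `z`, `p.value`. `z > 0` means `group1` tends to larger
#'   values.
#' @export
steel_dwass <- function(data, value, group) {
  v <- pull(data, {{ value }})
  g <- factor(pull(data, {{ group }}))
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]
  g <- droplevels(g[keep])
  k <- nlevels(g)
  if (k < 2L) {
    stop_hcg("Steel-Dwass needs at least 2 groups", "hcg_error_groups")
  }
  sizes <- table(g)
  if (any(sizes < 2L)) {
    stop_hcg("Steel-Dwass needs n >= 2 in every group", "hcg_error_groups")
  }
  lev <- levels(g)
  pairs <- utils::combn(lev, 2L)
  out <- map(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1L, p]
    b <- pairs[2L, p]
    z <- steel_dwass_z(v[g == a], v[g == b])
    tibble(
      group1 = a, group2 = b,
      n1 = as.integer(sizes[[a]]), n2 = as.integer(sizes[[b]]),
      z = z,
      p.value = if (z == 0) 1 else
        ptukey(sqrt(2) * abs(z), nmeans = k, df = Inf, lower.tail = FALSE)
    )
  })
  bind_rows(out)
}

#' Pearson correlation matrix of per-cluster metrics
#'
#' Pairwise Pearson correlations over complete records. A constant variable
#' has no defined correlation; its off-diagonal entries are `NA` and a
#' warning names it.
#'
#' @param data A data frame of per-cluster records.
#' @param vars Character vector of (numeric) column names; default the four
#'   study metrics.
#' @return A symmetric correlation matrix with unit diagonal and an `n`
#'   attribute giving the number of complete records used.
#' @export
pearson_matrix <- function(data,
                           vars = c("thickness_um", "skewness",
                                    "kurtosis", "gray_mode")) {
  m <- as.matrix(data[, vars, drop = FALSE])
  storage.mode(m) <- "double"
  cc <- complete.cases(m)
  m <- m[cc, , drop = FALSE]
  if (nrow(m) < 3L) {
    stop_hcg("correlation needs at least 3 complete records", "hcg_error_n")
  }
  sds <- apply(m, 2L, sd)
  constant <- sds == 0
  if (any(constant)) {
    warn(paste0("constant variable(s), correlations undefined: ",
                paste(vars[constant], collapse = ", ")))
  }
  r <- suppressWarnings(cor(m))
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r) <- 1
  attr(r, "n") <- nrow(m)
  r
}
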