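library(tibble)

two_groups <- function(a, b) {
  tibble(v = c(a, b), g = rep(c("a", "b"), c(length(a), length(b))))
}

test_that("Kruskal-Wallis reproduces the rank formula", {
  r <- kruskal_wallis(two_groups(c(1, 2), c(3, 4)), v, g)
  expect_equal(r$statistic, 2.4)
  expect_equal(r$df, 1L)
  expect_equal(r$p.value, pchisq(2.4, 1, lower.tail = FALSE))

  same <- kruskal_wallis(two_groups(c(1, 2, 3), c(1, 2, 3)), v, g)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p.value, 1, tolerance = 1e-12)

  tied <- kruskal_wallis(two_groups(c(2, 2), c(2, 2, 2)), v, g)
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p.value, 1)
})

test_that("Kruskal-Wallis matches the naive tie-corrected oracle on fuzzed data", {
  set.seed(41)
  for (i in 1:60) {
    k <- sample(2:4, 1L)
    sizes <- sample(3:8, k, replace = TRUE)
    vals <- sample(1:6, sum(sizes), replace = TRUE)  # heavy ties
    d <- tibble(v = vals, g = rep(letters[1:k], sizes))
    if (length(unique(vals)) == 1L) next
    r <- kruskal_wallis(d, v, g)
    expect_equal(r$statistic, oracle_kw(vals, d$g), tolerance = 1e-10)
  }
})

test_that("Steel-Dwass handles null pairs, antisymmetry, and the two-group identity", {
  idt <- steel_dwass(two_groups(c(1, 2, 3), c(1, 2, 3)), v, g)
  expect_equal(idt$z, 0)
  expect_equal(idt$p.value, 1)

  set.seed(42)
  d <- tibble(v = rnorm(12), g = rep(c("a", "b", "c"), each = 4))
  res <- steel_dwass(d, v, g)
  expect_equal(nrow(res), 3L)
  # swapping group labels flips z and keeps p
  d2 <- d
  d2$g <- factor(d2$g, levels = c("b", "a", "c"))
  res2 <- steel_dwass(d2, v, g)
  ab <- res[res$group1 == "a" & res$group2 == "b", ]
  ba <- res2[res2$group1 == "b" & res2$group2 == "a", ]
  expect_equal(ba$z, -ab$z)
  expect_equal(ba$p.value, ab$p.value)

  # with k = 2 the studentized range reduces to the two-sided normal p
  dk2 <- two_groups(rnorm(8), rnorm(8, 1))
  rk2 <- steel_dwass(dk2, v, g)
  expect_equal(rk2$p.value, 2 * pnorm(abs(rk2$z), lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("the asymptotic Steel-Dwass p approaches the permutation tail at moderate n", {
  set.seed(7)
  n <- 30L
  vals <- c(rnorm(n, 0), rnorm(n, 0.45), rnorm(n, 0.9))
  d <- tibble(v = vals, g = rep(c("a", "b", "c"), each = n))
  res <- steel_dwass(d, v, g)
  perm <- oracle_sd_perm_tail(vals, rep(n, 3L), sqrt(2) * abs(res$z),
                              n_draws = 20000L)
  expect_true(all(abs(res$p.value - perm) <= 0.03))
})

test_that("ROC handles perfect separation, partial overlap, and exchangeable groups", {
  r <- roc_analysis(c(1, 2), c(3, 4), "lower-positive")
  expect_equal(r$auc, 1)
  expect_equal(r$cutoff, 2.5)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  r2 <- roc_analysis(c(1, 3), c(2, 4), "lower-positive")
  expect_equal(r2$auc, 0.75)

  r3 <- roc_analysis(c(1, 2, 3), c(1, 2, 3), "lower-positive")
  expect_equal(r3$auc, 0.5)
})

test_that("AUC equals brute-force concordance and obeys the complement identity", {
  set.seed(43)
  for (i in 1:60) {
    pos <- sample(0:40, sample(2:12, 1L), replace = TRUE)
    neg <- sample(0:40, sample(2:12, 1L), replace = TRUE)
    r <- roc_analysis(pos, neg, "lower-positive")
    expect_equal(r$auc, oracle_auc_lower(pos, neg), tolerance = 1e-12)
    r_swap <- roc_analysis(neg, pos, "lower-positive")
    expect_equal(r$auc + r_swap$auc, 1, tolerance = 1e-12)
  }
})

test_that("AUC equals the trapezoidal integral of its own curve", {
  set.seed(44)
  for (i in 1:20) {
    pos <- rnorm(sample(5:30, 1L))
    neg <- rnorm(sample(5:30, 1L), mean = 1)
    r <- roc_analysis(pos, neg, "auto")
    curve <- dplyr::arrange(r$curve, fpr, sensitivity)
    trap <- sum(diff(curve$fpr) *
                  (head(curve$sensitivity, -1) + tail(curve$sensitivity, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
  }
})

test_that("cut-offs land on half-integer midpoints for integer gray data", {
  pos <- c(10L, 12L, 30L, 33L)
  neg <- c(34L, 40L, 55L, 60L)
  r <- roc_analysis(pos, neg, "lower-positive")
  expect_equal(r$cutoff, 33.5)
  expect_equal(r$cutoff %% 1, 0.5)
})

test_that("Pearson matrices match the covariance oracle and flag constants", {
  d <- tibble(thickness_um = 1:10, skewness = 2 * (1:10),
              kurtosis = -(1:10), gray_mode = rnorm(10))
  r <- pearson_matrix(d)
  expect_equal(r["thickness_um", "skewness"], 1)
  expect_equal(r["thickness_um", "kurtosis"], -1)
  expect_true(isSymmetric(unname(r[1:4, 1:4])))
  expect_equal(unname(diag(r)), rep(1, 4))

  set.seed(45)
  d2 <- tibble(thickness_um = rnorm(30), skewness = rnorm(30),
               kurtosis = rnorm(30), gray_mode = rnorm(30))
  r2 <- pearson_matrix(d2)
  cov_oracle <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(r2["skewness", "kurtosis"],
               cov_oracle(d2$skewness, d2$kurtosis), tolerance = 1e-12)

  d3 <- d2
  d3$kurtosis <- 5
  expect_warning(r3 <- pearson_matrix(d3), "constant")
  expect_true(is.na(r3["kurtosis", "skewness"]))
  expect_equal(r3["kurtosis", "kurtosis"], 1)
})

test_that("the interaction model recovers known coefficients exactly on noiseless data", {
  set.seed(46)
  n <- 40L
  d <- tibble(thickness_um = runif(n, 5, 25), skewness = rnorm(n, 2),
              kurtosis = rnorm(n, 3, 2))
  beta <- c(140, -4, -65, 8.5, 1.9, -0.2, -0.3)
  d$gray_mode <- beta[1] + beta[2] * d$thickness_um + beta[3] * d$skewness +
    beta[4] * d$kurtosis + beta[5] * d$thickness_um * d$skewness +
    beta[6] * d$thickness_um * d$kurtosis + beta[7] * d$skewness * d$kurtosis
  fit <- fit_interaction_model(d)
  est <- tidy(fit)$estimate
  expect_equal(unname(est), beta, tolerance = 1e-8)
  expect_equal(glance(fit)$r.squared, 1, tolerance = 1e-10)
})

test_that("the interaction model matches a normal-equations solve on noisy data", {
  set.seed(47)
  n <- 60L
  d <- tibble(thickness_um = runif(n, 5, 25), skewness = rnorm(n, 2),
              kurtosis = rnorm(n, 3, 2))
  d$gray_mode <- 100 - 3 * d$thickness_um - 20 * d$skewness + rnorm(n, sd = 8)
  fit <- fit_interaction_model(d)
  x_mat <- cbind(1, d$thickness_um, d$skewness, d$kurtosis,
                 d$thickness_um * d$skewness, d$thickness_um * d$kurtosis,
                 d$skewness * d$kurtosis)
  est_oracle <- oracle_ols(x_mat, d$gray_mode)
  td <- tidy(fit)
  # lm orders interactions after mains in the same pairwise sequence
  expect_equal(unname(td$estimate), unname(est_oracle), tolerance = 1e-8)
  expect_equal(unname(td$statistic), unname(td$estimate / td$std.error),
               tolerance = 1e-12)
})

test_that("degenerate regression inputs are rejected or flagged", {
  set.seed(48)
  n <- 30L
  d <- tibble(thickness_um = runif(n), skewness = rnorm(n), kurtosis = rnorm(n))
  d$gray_mode <- rnorm(n)
  d_alias <- d
  d_alias$kurtosis <- 2 * d_alias$skewness  # aliased product terms
  expect_error(fit_interaction_model(d_alias), class = "hcg_error_singular")

  d_const <- d
  d_const$gray_mode <- 7
  fit <- fit_interaction_model(d_const)
  expect_true(glance(fit)$degenerate_response)
  expect_true(is.na(glance(fit)$r.squared))
})
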