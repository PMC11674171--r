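#' The 8-bit gray-scale value: mode of a gray-level histogram
#'
#' The per-cluster summary statistic of cluster darkness: the gray level with
#' the maximal pixel count inside the trimmed region. Lower values mean darker
#' (more hyperchromatic, more stacked) clusters. Ties are broken toward the
#' smallest gray level so results are reproducible.
#'
#' @param h A `"gray_histogram"`.
#' @return An integer gray level in `[0, 255]`.
#' @export
gray_mode <- function(h) {
  stopifnot(inherits(h, "gray_histogram"))
  which.max(h$counts) - 1L
}

#' Spreadsheet-definition sample skewness
#'
#' The bias-corrected skewness matching the spreadsheet `SKEW` function:
#' \deqn{\frac{n}{(n-1)(n-2)} \sum_i \left(\frac{x_i - \bar x}{s}\right)^3}
#' with \eqn{s} the (n-1)-denominator sample standard deviation. For masked
#' gray distributions, positive skewness means mass piled near gray level 0
#' with a long bright tail — the signature of a dark, dense cluster.
#'
#' @param values Numeric vector, `n >= 3`, not all equal.
#' @return Skewness (dimensionless).
#' @export
skew_excel <- function(values) {
  n <- length(values)
  if (n < 3L) {
    stop_hcg("skewness needs at least 3 values", "hcg_error_degenerate")
  }
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    stop_hcg("skewness undefined for a constant sample", "hcg_error_degenerate")
  }
  z <- (values - mean(values)) / s
  n / ((n - 1) * (n - 2)) * sum(z^3)
}

#' Spreadsheet-definition excess kurtosis
#'
#' The bias-corrected excess kurtosis matching the spreadsheet `KURT`
#' function:
#' \deqn{\frac{n(n+1)}{(n-1)(n-2)(n-3)} \sum_i \left(\frac{x_i - \bar x}{s}\right)^4
#'       - \frac{3(n-1)^2}{(n-2)(n-3)}}
#' High kurtosis marks a sharply peaked gray distribution, i.e. a region
#' dominated by one dark density with rare outliers.
#'
#' @param values Numeric vector, `n >= 4`, not all equal.
#' @return Excess kurtosis (dimensionless; 0 for a normal sample).
#' @export
kurt_excel <- function(values) {
  n <- length(values)
  if (n < 4L) {
    stop_hcg("kurtosis needs at least 4 values", "hcg_error_degenerate")
  }
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    stop_hcg("kurtosis undefined for a constant sample", "hcg_error_degenerate")
  }
  z <- (values - mean(values)) / s
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

#' Per-cluster texture metrics from a gray-level histogram
#'
#' Expands the histogram to its multiset of pixel values and applies
#' [gray_mode()], [skew_excel()] and [kurt_excel()]; identical to computing on
#' the raw masked pixel list. Constant regions (zero variance) are flagged
#' `degenerate` with `NA` skewness/kurtosis rather than dropped, so study
#' bookkeeping can retain and exclude them explicitly.
#'
#' @param h A `"gray_histogram"` with `n_total >= 1`.
#' @return A one-row tibble: `gray_mode`, `skewness`, `kurtosis`, `n_pixels`,
#'   `degenerate`.
#' @export
metrics_from_histogram <- function(h) {
  stopifnot(inherits(h, "gray_histogram"))
  values <- rep.int(0:255, h$counts)
  mode_v <- gray_mode(h)
  skew <- tryCatch(skew_excel(values), hcg_error_degenerate = function(e) NA_real_)
  kurt <- tryCatch(kurt_excel(values), hcg_error_degenerate = function(e) NA_real_)
  tibble(
    gray_mode = mode_v,
    skewness = skew,
    kurtosis = kurt,
    n_pixels = h$n_total,
    degenerate = is.na(skew) || is.na(kurt)
  )
}
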