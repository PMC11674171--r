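#' Multiple regression of the gray-scale value with pairwise interactions
#'
#' Ordinary least squares of the 8-bit gray-scale value on cluster thickness,
#' skewness and kurtosis plus their three pairwise products — the model that
#' quantifies how much of the cluster darkness is explained by thickness and
#' cell-density structure. Covariates enter raw (uncentered) by default so
#' coefficients refer to the original measurement scales; set `center = TRUE`
#' to mean-center main effects before forming products.
#'
#' @param data A data frame of per-cluster records containing `response` and
#'   `predictors` columns; rows with missing values are dropped.
#' @param response Name of the response column (default `"gray_mode"`).
#' @param predictors Character vector of the three main-effect columns.
#' @param center Mean-center the predictors before forming interaction
#'   products? Default `FALSE`.
#' @return An object of class `"hcg_interaction_fit"` wrapping the `lm` fit;
#'   use [tidy()] for the per-term table and [glance()] for fit summaries.
#' @export
fit_interaction_model <- function(data,
                                  response = "gray_mode",
                                  predictors = c("thickness_um", "skewness",
                                                 "kurtosis"),
                                  center = FALSE) {
  stopifnot(length(predictors) == 3L)
  cols <- c(response, predictors)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L) {
    stop_hcg(paste0("missing columns: ", paste(missing_cols, collapse = ", ")),
             "hcg_error_columns")
  }
  d <- as_tibble(data)[, cols]
  d <- d[complete.cases(d), ]
  n_terms <- 7L  # intercept + 3 mains + 3 pairwise products
  if (nrow(d) <= n_terms) {
    stop_hcg("interaction model needs n > 7 complete records", "hcg_error_n")
  }
  if (center) {
    d[predictors] <- lapply(d[predictors], function(x) x - mean(x))
  }
  fml <- stats::as.formula(paste0(
    "`", response, "` ~ (`", predictors[1L], "` + `", predictors[2L],
    "` + `", predictors[3L], "`)^2"
  ))
  fit <- lm(fml, data = d)
  if (any(is.na(coef(fit))) || fit$rank < n_terms) {
    stop_hcg("design matrix is rank deficient (aliased terms)",
             "hcg_error_singular")
  }
  y <- d[[response]]
  sstot <- sum((y - mean(y))^2)
  structure(
    list(
      fit = fit,
      response = response,
      predictors = predictors,
      center = center,
      n = nrow(d),
      r_squared = if (sstot > 0) {
        suppressWarnings(summary(fit)$r.squared)  # exact fits are legitimate
      } else {
        NA_real_
      },
      degenerate_response = sstot == 0
    ),
    class = "hcg_interaction_fit"
  )
}

#' @export
print.hcg_interaction_fit <- function(x, ...) {
  cat("<hcg_interaction_fit>", x$response, "~",
      paste(x$predictors, collapse = " + "), "+ pairwise products\n")
  cat("  n =", x$n, " R-squared =",
      ifelse(is.na(x$r_squared), "undefined (constant response)",
             formatC(x$r_squared, digits = 4, format = "f")), "\n")
  invisible(x)
}

#' Per-term coefficient table of an interaction fit
#'
#' @param x An `"hcg_interaction_fit"`.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`,
#'   `std.error`, `statistic` (t), `p.value` (two-sided, `n - 7` df).
#' @method tidy hcg_interaction_fit
#' @export
tidy.hcg_interaction_fit <- function(x, ...) {
  cf <- suppressWarnings(summary(x$fit))$coefficients
  tibble(
    term = gsub("`", "", rownames(cf)),
    estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    p.value = cf[, "Pr(>|t|)"]
  )
}

#' One-row fit summary of an interaction fit
#'
#' @param x An `"hcg_interaction_fit"`.
#' @param ... Unused.
#' @return A one-row tibble: `r.squared`, `adj.r.squared`, `sigma`,
#'   `df.residual`, `nobs`, `degenerate_response`.
#' @method glance hcg_interaction_fit
#' @export
glance.hcg_interaction_fit <- function(x, ...) {
  # a flagged constant response makes summary.lm warn about a perfect fit;
  # the degenerate_response column already carries that information
  s <- suppressWarnings(summary(x$fit))
  tibble(
    r.squared = x$r_squared,
    adj.r.squared = if (is.na(x$r_squared)) NA_real_ else s$adj.r.squared,
    sigma = s$sigma,
    df.residual = x$fit$df.residual,
    nobs = x$n,
    degenerate_response = x$degenerate_response
  )
}
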