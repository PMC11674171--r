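#' ROC analysis with Youden cut-off selection
#'
#' Builds the ROC curve for separating a positive from a negative group on a
#' single marker (here usually the 8-bit gray-scale value, where the lesion
#' group takes *lower* values). Thresholds are placed at midpoints between
#' adjacent distinct pooled values plus `-Inf`/`Inf` sentinels, which is why
#' reported cut-offs on integer gray levels end in ".5". Under
#' `"lower-positive"` a case is called positive when its value is `<=` the
#' threshold. AUC is computed by the rank/concordance identity (ties count
#' 1/2), so it is exact, not a trapezoid approximation — though it equals the
#' trapezoidal integral of the reported curve. The cut-off maximizes the
#' Youden index `J = sensitivity + specificity - 1`; ties are resolved toward
#' higher specificity.
#'
#' @param pos Numeric marker values of the positive group.
#' @param neg Numeric marker values of the negative group.
#' @param orientation `"auto"` (default: pick the direction with AUC >= 0.5),
#'   `"lower-positive"` or `"higher-positive"`.
#' @return An object of class `"hcg_roc"`: list with `orientation`, `auc`,
#'   `cutoff`, `sensitivity`, `specificity` and `curve` (a tibble of
#'   `threshold`, `sensitivity`, `specificity`, `fpr`).
#' @examples
#' roc_analysis(c(1, 2), c(3, 4), "lower-positive")  # AUC 1, cutoff 2.5
#' @export
roc_analysis <- function(pos, neg,
                         orientation = c("auto", "lower-positive",
                                         "higher-positive")) {
  orientation <- match.arg(orientation)
  pos <- pos[is.finite(pos)]
  neg <- neg[is.finite(neg)]
  if (length(pos) < 1L || length(neg) < 1L) {
    stop_hcg("ROC needs a non-empty positive and negative group",
             "hcg_error_groups")
  }
  np <- length(pos)
  nn <- length(neg)
  # P(pos > neg) + P(pos == neg)/2 by the rank-sum identity.
  r <- rank(c(pos, neg))
  p_greater <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  auc_lower <- 1 - p_greater
  if (orientation == "auto") {
    orientation <- if (auc_lower >= 0.5) "lower-positive" else "higher-positive"
  }
  auc <- if (orientation == "lower-positive") auc_lower else p_greater
  pooled <- sort(unique(c(pos, neg)))
  mids <- if (length(pooled) > 1L) {
    (head(pooled, -1L) + tail(pooled, -1L)) / 2
  } else {
    numeric(0)
  }
  thresholds <- c(-Inf, mids, Inf)
  if (orientation == "lower-positive") {
    sens <- map_dbl(thresholds, ~ mean(pos <= .x))
    spec <- map_dbl(thresholds, ~ mean(neg > .x))
  } else {
    sens <- map_dbl(thresholds, ~ mean(pos >= .x))
    spec <- map_dbl(thresholds, ~ mean(neg < .x))
  }
  curve <- tibble(
    threshold = thresholds,
    sensitivity = sens,
    specificity = spec,
    fpr = 1 - spec
  )
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1L) {
    best <- best[spec[best] == max(spec[best])]
  }
  best <- best[1L]
  structure(
    list(
      orientation = orientation,
      auc = auc,
      cutoff = thresholds[best],
      sensitivity = sens[best],
      specificity = spec[best],
      curve = curve,
      n_pos = np,
      n_neg = nn
    ),
    class = "hcg_roc"
  )
}

#' @export
print.hcg_roc <- function(x, ...) {
  cat(sprintf(
    "<hcg_roc> %s  AUC = %.3f  cutoff = %s  sens = %.2f  spec = %.2f\n",
    x$orientation, x$auc, format(x$cutoff), x$sensitivity, x$specificity
  ))
  invisible(x)
}

#' Tidy an ROC result into its curve points
#'
#' @param x An `"hcg_roc"`.
#' @param ... Unused.
#' @return The curve tibble (`threshold`, `sensitivity`, `specificity`,
#'   `fpr`).
#' @method tidy hcg_roc
#' @export
tidy.hcg_roc <- function(x, ...) x$curve

#' One-row summary of an ROC result
#'
#' @param x An `"hcg_roc"`.
#' @param ... Unused.
#' @return A one-row tibble: `orientation`, `auc`, `cutoff`, `sensitivity`,
#'   `specificity`, `n_pos`, `n_neg`.
#' @method glance hcg_roc
#' @export
glance.hcg_roc <- function(x, ...) {
  tibble(
    orientation = x$orientation,
    auc = x$auc,
    cutoff = x$cutoff,
    sensitivity = x$sensitivity,
    specificity = x$specificity,
    n_pos = x$n_pos,
    n_neg = x$n_neg
  )
}

#' Plot an ROC curve
#'
#' @param object An `"hcg_roc"`.
#' @param ... Unused.
#' @return A ggplot: the ROC curve with the chance diagonal and the selected
#'   cut-off marked.
#' @method autoplot hcg_roc
#' @export
autoplot.hcg_roc <- function(object, ...) {
  curve <- dplyr::arrange(object$curve, .data$fpr, .data$sensitivity)
  at_cut <- curve[curve$threshold == object$cutoff, ]
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = at_cut, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC = %.2f, cut-off = %s", object$auc,
                      format(object$cutoff))
    ) +
    ggplot2::theme_minimal()
}
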