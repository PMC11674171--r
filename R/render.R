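# Visual outputs: pseudocolour rendering and the study figures.

# Fixed 16-colour gradient (dark -> blue -> cyan -> green -> yellow -> red ->
# white), the banding used to make gray-level strata of a cluster visible.
.pseudocolor_lut16 <- c(
  "#000000", "#01008E", "#0000FF", "#0072FF",
  "#00BFFF", "#00FFFF", "#00FF95", "#00FF00",
  "#83FF00", "#FFFF00", "#FFC100", "#FF8A00",
  "#FF5500", "#FF0000", "#C80000", "#FFFFFF"
)

#' Pseudocolour rendering of an 8-bit image
#'
#' Maps gray level `v` to band `floor(v / (256 / bands))` of a fixed
#' 16-anchor look-up table; with `bands = 256` the anchors are linearly
#' interpolated so every gray level gets its own colour. Deterministic: the
#' LUT is a package constant.
#'
#' @param img A `"gray_image"`.
#' @param bands Number of colour bands; must divide 256.
#' @return An `"rgb_image"` of the same height/width.
#' @export
render_pseudocolor <- function(img, bands = 16L) {
  bands <- as.integer(bands)
  if (bands < 1L || 256L %% bands != 0L) {
    stop_hcg("bands must divide 256", "hcg_error_bands")
  }
  anchors <- t(grDevices::col2rgb(.pseudocolor_lut16))
  lut <- if (bands <= 16L) {
    anchors[round(seq(1L, 16L, length.out = bands)), , drop = FALSE]
  } else {
    ramp <- grDevices::colorRamp(.pseudocolor_lut16)
    round_half_up(ramp((seq_len(bands) - 1) / (bands - 1)))
  }
  band <- unclass(img) %/% (256L %/% bands) + 1L
  out <- array(0L, dim = c(nrow(img), ncol(img), 3L))
  for (ch in 1:3) {
    out[, , ch] <- matrix(lut[band, ch], nrow(img), ncol(img))
  }
  new_rgb_image(out)
}

#' Box plots of the per-cluster metrics by group
#'
#' @param records Per-cluster record tibble (as in an `"hcg_study"`).
#' @return A ggplot with one panel per metric.
#' @export
plot_group_boxplots <- function(records) {
  metrics <- intersect(study_metrics, names(records))
  long <- tidyr::pivot_longer(records[, c("group", metrics)],
                              cols = dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  long <- long[is.finite(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Density of pooled gray levels by group
#'
#' Overlays, per group, the pooled masked gray-level distribution of all
#' clusters (normalised to a density over the 0-255 scale).
#'
#' @param group_histograms Named list of 256-bin count vectors, one per
#'   group (as in an `"hcg_study"`).
#' @return A ggplot.
#' @export
plot_gray_density <- function(group_histograms) {
  d <- bind_rows(imap(group_histograms, function(counts, g) {
    tibble(group = g, gray = 0:255,
           density = counts / sum(counts))
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gray, y = .data$density,
                                  colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "8-bit gray level", y = "Density") +
    ggplot2::theme_minimal()
}

#' Write the study figures
#'
#' Emits a deterministic file set: `boxplots.pdf` (one panel per metric),
#' `gray_density.pdf` (pooled gray distributions per group) and `roc.pdf`
#' (all pairwise ROC curves with the chance diagonal). Figures whose inputs
#' are absent are skipped with a log message.
#'
#' @param report An `"hcg_study"`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written files, invisibly.
#' @export
render_reports <- function(report, dir = report$output_dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  save_fig <- function(plot, name, width = 7, height = 5) {
    path <- file.path(dir, name)
    ggplot2::ggsave(path, plot, width = width, height = height,
                    device = grDevices::pdf)
    written <<- c(written, path)
  }
  if (nrow(report$records) > 0L) {
    save_fig(plot_group_boxplots(report$records), "boxplots.pdf")
  }
  if (length(report$group_histograms) > 0L) {
    save_fig(plot_gray_density(report$group_histograms), "gray_density.pdf")
  }
  if (length(report$roc) > 0L) {
    curves <- bind_rows(imap(report$roc, function(r, nm) {
      mutate(arrange(r$curve, .data$fpr, .data$sensitivity), comparison = nm)
    }))
    p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr,
                                              y = .data$sensitivity,
                                              colour = .data$comparison)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::geom_path() +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
      ggplot2::theme_minimal()
    save_fig(p, "roc.pdf", width = 7, height = 6)
  }
  invisible(written)
}
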