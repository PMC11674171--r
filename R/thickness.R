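#' Construct a Z-stack
#'
#' An ordered series of gray focal-plane images of the same field, bottom
#' first, at a fixed focal step (the study design: 40 layers at 1 µm).
#'
#' @param layers List of `"gray_image"` matrices (or plain numeric matrices),
#'   bottom to top, all the same dimensions; at least 2.
#' @param spacing_um Focal step in µm per layer (> 0).
#' @return An object of class `"zstack"`.
#' @export
zstack <- function(layers, spacing_um = 1) {
  if (length(layers) < 2L) {
    stop_hcg("a Z-stack needs at least 2 layers", "hcg_error_zstack")
  }
  dims <- unique(lapply(layers, dim))
  if (length(dims) != 1L) {
    stop_hcg("all Z-stack layers must share dimensions", "hcg_error_shape")
  }
  if (!is.numeric(spacing_um) || spacing_um <= 0) {
    stop_hcg("spacing_um must be > 0", "hcg_error_zstack")
  }
  structure(list(layers = layers, spacing_um = spacing_um), class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$layers[[1L]])
  cat("<zstack>", length(x$layers), "layers of", d[1L], "x", d[2L],
      "at", x$spacing_um, "um\n")
  invisible(x)
}

#' Read a multi-page TIFF as a Z-stack
#'
#' Pages are taken bottom first. Colour pages are converted with
#' [to_gray8()].
#'
#' @param path Multi-page TIFF path.
#' @param spacing_um Focal step in µm per page.
#' @param gray_method Passed to [to_gray8()] for colour pages.
#' @return A `"zstack"`.
#' @export
read_zstack <- function(path, spacing_um = 1, gray_method = "weighted") {
  pages <- tiff::readTIFF(path, all = TRUE)
  layers <- lapply(pages, function(p) {
    vals <- round_half_up(p * 255)
    if (length(dim(vals)) == 3L) {
      to_gray8(new_rgb_image(vals[, , 1:3, drop = FALSE]), method = gray_method)
    } else {
      new_gray_image(vals)
    }
  })
  zstack(layers, spacing_um = spacing_um)
}

#' Write a Z-stack as a multi-page TIFF
#'
#' @param stack A `"zstack"`.
#' @param path Output `.tif`/`.tiff` path; bottom page first.
#' @return `path`, invisibly.
#' @export
write_zstack <- function(stack, path) {
  pages <- lapply(stack$layers, function(l) unclass(l) / 255)
  tiff::writeTIFF(pages, where = path, bits.per.sample = 8L)
  invisible(path)
}

# Variance of the 4-neighbour discrete Laplacian over member pixels.
# The Laplacian is defined on interior pixels only; the mask is restricted
# accordingly. Returns 0 when fewer than 2 member pixels carry a value.
laplacian_variance <- function(layer, mask) {
  x <- unclass(layer)
  h <- nrow(x)
  w <- ncol(x)
  if (h < 3L || w < 3L) {
    return(0)
  }
  ci <- 2:(h - 1L)
  cj <- 2:(w - 1L)
  lap <- 4 * x[ci, cj] -
    x[ci - 1L, cj] - x[ci + 1L, cj] -
    x[ci, cj - 1L] - x[ci, cj + 1L]
  m <- mask[ci, cj]
  v <- lap[m]
  if (length(v) < 2L) {
    return(0)
  }
  var(v)
}

#' Depth-from-focus profile of a Z-stack
#'
#' Scores the sharpness of every focal layer inside the region of interest by
#' the variance of the 4-neighbour discrete Laplacian — a standard,
#' parameter-free focus operator that peaks where structure is in focus and
#' collapses under defocus blur. It operationalises the visual "in focus"
#' judgement used when measuring cluster thickness at the eyepiece.
#'
#' @param stack A `"zstack"`.
#' @param mask A `"roi_mask"` (or logical matrix) matching layer dimensions.
#' @return A tibble of class `"focus_profile"` with columns `layer` (1-based,
#'   bottom first) and `score` (>= 0), carrying `spacing_um` as an attribute.
#' @export
focus_profile <- function(stack, mask) {
  stopifnot(inherits(stack, "zstack"))
  if (!identical(dim(stack$layers[[1L]]), dim(mask))) {
    stop_hcg("mask dimensions do not match Z-stack layers", "hcg_error_shape")
  }
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  scores <- map_dbl(stack$layers, laplacian_variance, mask = mask)
  out <- tibble(layer = seq_along(scores), score = scores)
  attr(out, "spacing_um") <- stack$spacing_um
  class(out) <- c("focus_profile", class(out))
  out
}

#' Measure cluster thickness from a focus profile
#'
#' A layer is "in focus" when its sharpness score reaches `rel_threshold`
#' times the profile maximum. Thickness is the focal distance from the
#' deepest in-focus layer (cells at the slide surface) to the topmost
#' in-focus layer (upper cluster surface):
#' `(top_layer - bottom_layer) * spacing_um` — the exclusive span, so a
#' cluster confined to a single plane reads 0 µm.
#'
#' @param profile A `"focus_profile"` from [focus_profile()].
#' @param rel_threshold In-focus threshold as a fraction of the maximal
#'   score, in (0, 1); default 0.5.
#' @return A one-row tibble: `bottom_layer`, `top_layer` (1-based indices)
#'   and `thickness_um`.
#' @export
measure_thickness <- function(profile, rel_threshold = 0.5) {
  if (!(rel_threshold > 0 && rel_threshold < 1)) {
    stop_hcg("rel_threshold must be in (0, 1)", "hcg_error_threshold")
  }
  scores <- profile$score
  spacing <- attr(profile, "spacing_um")
  smax <- max(scores)
  if (!is.finite(smax) || smax <= 0) {
    stop_hcg("focus profile has no content (all scores zero)",
             "hcg_error_no_content")
  }
  in_focus <- which(scores >= rel_threshold * smax)
  bottom <- min(in_focus)
  top <- max(in_focus)
  tibble(
    bottom_layer = bottom,
    top_layer = top,
    thickness_um = (top - bottom) * spacing
  )
}
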