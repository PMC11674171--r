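# Small in-code fixtures.

rgb_raster <- function(r, g, b) {
  stopifnot(identical(dim(r), dim(g)), identical(dim(r), dim(b)))
  arr <- array(0L, dim = c(nrow(r), ncol(r), 3L))
  arr[, , 1L] <- r
  arr[, , 2L] <- g
  arr[, , 3L] <- b
  structure(array(as.integer(arr), dim(arr)), class = "rgb_image")
}

gray_raster <- function(m) {
  structure(matrix(as.integer(m), nrow(m), ncol(m)), class = "gray_image")
}

uniform_gray <- function(value, h = 4L, w = 4L) {
  gray_raster(matrix(value, h, w))
}

full_mask <- function(h, w) {
  structure(matrix(TRUE, h, w), class = "roi_mask")
}

histogram_of <- function(values) {
  masked_histogram(
    gray_raster(matrix(values, nrow = 1L)),
    full_mask(1L, length(values))
  )
}

# A focus profile built directly (bypassing a stack) for index arithmetic
# tests.
profile_of <- function(scores, spacing_um = 1) {
  out <- tibble::tibble(layer = seq_along(scores), score = scores)
  attr(out, "spacing_um") <- spacing_um
  class(out) <- c("focus_profile", class(out))
  out
}

quiet_study_config <- function(...) {
  study_config(..., write_figures = FALSE)
}
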