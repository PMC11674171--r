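#' Read an 8-bit raster image
#'
#' Reads a PNG or TIFF raster and returns it as an integer array on the 0-255
#' scale. 24-bit colour images become a `height x width x 3` array of class
#' `"rgb_image"`; single-channel images become an integer matrix of class
#' `"gray_image"`. An alpha channel, if present, is dropped. Rasters stored at
#' more than 8 bits per channel are rejected: the downstream gray-level
#' histogram is defined on the 256-level scale only.
#'
#' @param path Path to a PNG or TIFF file, 8 bits per channel.
#' @return An integer array of class `"rgb_image"` (`h x w x 3`) or an integer
#'   matrix of class `"gray_image"`, values in `[0, 255]`.
#' @seealso [write_image()], [to_gray8()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop_hcg(paste0("image file not found: ", path), "hcg_error_missing_file")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    # PNG bit depth lives at byte 25 of the file (after the 8-byte signature
    # and the IHDR length/type/width/height fields).
    hdr <- readBin(path, "raw", n = 26L)
    depth <- as.integer(hdr[25L])
    if (depth > 8L) {
      stop_hcg(
        paste0("unsupported PNG bit depth ", depth, " (8 bits/channel required)"),
        "hcg_error_bit_depth"
      )
    }
    arr <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    meta <- tiff::readTIFF(path, payload = FALSE)
    if (is.list(meta) && !is.null(meta[["bits.per.sample"]])) {
      bits <- meta[["bits.per.sample"]]
    } else {
      bits <- attr(meta, "bits.per.sample") %||% 8L
    }
    if (any(bits > 8L)) {
      stop_hcg(
        paste0("unsupported TIFF bit depth ", max(bits), " (8 bits/channel required)"),
        "hcg_error_bit_depth"
      )
    }
    arr <- tiff::readTIFF(path)
  } else {
    stop_hcg(paste0("unsupported image format: .", ext), "hcg_error_format")
  }
  vals <- round_half_up(arr * 255)
  if (length(dim(vals)) == 2L) {
    return(new_gray_image(vals))
  }
  nch <- dim(vals)[3L]
  if (nch == 1L) {
    return(new_gray_image(vals[, , 1L]))
  }
  if (nch %in% c(2L, 4L)) {
    vals <- vals[, , seq_len(nch - 1L), drop = FALSE]  # drop alpha
    nch <- nch - 1L
  }
  if (nch == 1L) {
    return(new_gray_image(vals[, , 1L]))
  }
  new_rgb_image(vals)
}

#' Write an 8-bit raster image
#'
#' Writes a `"gray_image"` or `"rgb_image"` to PNG or TIFF (format chosen by
#' the file extension). Round-trips through [read_image()] pixel-identically.
#'
#' @param img A `"gray_image"` matrix or `"rgb_image"` array, values 0-255.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  arr <- unclass(img) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(arr, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, where = path, bits.per.sample = 8L)
  } else {
    stop_hcg(paste0("unsupported image format: .", ext), "hcg_error_format")
  }
  invisible(path)
}

new_rgb_image <- function(vals) {
  vals <- array(as.integer(vals), dim = dim(vals))
  stopifnot(length(dim(vals)) == 3L, dim(vals)[3L] == 3L)
  if (any(vals < 0L | vals > 255L)) {
    stop_hcg("RGB values outside [0, 255]", "hcg_error_range")
  }
  structure(vals, class = "rgb_image")
}

new_gray_image <- function(vals) {
  vals <- matrix(as.integer(vals), nrow = nrow(vals), ncol = ncol(vals))
  if (any(vals < 0L | vals > 255L)) {
    stop_hcg("gray values outside [0, 255]", "hcg_error_range")
  }
  structure(vals, class = "gray_image")
}

#' Convert a 24-bit colour image to 8-bit gray scale
#'
#' Per-pixel conversion with half-up rounding so results are bit-reproducible
#' across platforms:
#' * `"weighted"` (default): `round(0.299 R + 0.587 G + 0.114 B)` (Rec. 601
#'   luma, ImageJ's weighted option);
#' * `"mean"`: `round((R + G + B) / 3)` (ImageJ's unweighted option).
#'
#' @param img An `"rgb_image"` array (or an already-gray `"gray_image"`, which
#'   is returned unchanged).
#' @param method `"weighted"` or `"mean"`.
#' @return A `"gray_image"` integer matrix, values in `[0, 255]`.
#' @examples
#' px <- array(c(255L, 0L, 0L), dim = c(1, 1, 3))
#' to_gray8(structure(px, class = "rgb_image"))  # 76
#' @export
to_gray8 <- function(img, method = c("weighted", "mean")) {
  method <- match.arg(method)
  if (inherits(img, "gray_image")) {
    return(img)
  }
  if (!inherits(img, "rgb_image")) {
    stop_hcg("to_gray8() expects an rgb_image or gray_image", "hcg_error_type")
  }
  d <- dim(img)
  r <- matrix(img[, , 1L], d[1L], d[2L])
  g <- matrix(img[, , 2L], d[1L], d[2L])
  b <- matrix(img[, , 3L], d[1L], d[2L])
  gray <- switch(method,
    weighted = round_half_up(0.299 * r + 0.587 * g + 0.114 * b),
    mean = round_half_up((r + g + b) / 3)
  )
  new_gray_image(clamp8(gray))
}

#' Load a region-of-interest mask
#'
#' Masks stand in for the manual freehand trimming of the target cluster.
#' Two on-disk forms are accepted:
#' * a single-channel raster (PNG/TIFF) where any nonzero pixel is a member;
#' * a JSON polygon sidecar `{"vertices": [[x, y], ...]}` with 0-based
#'   continuous coordinates (`x` = column, `y` = row). A pixel belongs to the
#'   mask when its centre (at integer coordinates) falls strictly inside the
#'   polygon by the even-odd rule; centres exactly on the boundary are
#'   excluded, so membership is deterministic.
#'
#' @param path Path to the mask raster or JSON polygon file.
#' @param shape Integer vector `c(height, width)` the mask must match.
#' @return A logical matrix of class `"roi_mask"` with at least one member.
#' @export
load_mask <- function(path, shape) {
  if (!file.exists(path)) {
    stop_hcg(paste0("mask file not found: ", path), "hcg_error_missing_file")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    poly <- jsonlite::fromJSON(path)
    verts <- poly$vertices
    if (is.null(verts) || nrow(verts) < 3L) {
      stop_hcg("polygon sidecar needs a 'vertices' array with >= 3 points",
               "hcg_error_mask")
    }
    mask <- polygon_mask(verts[, 1L], verts[, 2L], shape[1L], shape[2L])
  } else {
    img <- read_image(path)
    if (inherits(img, "rgb_image")) {
      mask <- apply(unclass(img) != 0L, c(1L, 2L), any)
    } else {
      mask <- unclass(img) != 0L
    }
  }
  as_roi_mask(mask, shape)
}

as_roi_mask <- function(mask, shape = dim(mask)) {
  if (!identical(as.integer(dim(mask)), as.integer(shape[1:2]))) {
    stop_hcg(
      sprintf("mask is %dx%d but image is %dx%d",
              nrow(mask), ncol(mask), shape[1L], shape[2L]),
      "hcg_error_shape"
    )
  }
  if (!any(mask)) {
    stop_hcg("mask has no member pixels", "hcg_error_empty_mask")
  }
  structure(matrix(as.logical(mask), nrow(mask), ncol(mask)), class = "roi_mask")
}

# Crossing-number point-in-polygon, vectorised over query points. Centres
# lying exactly on a polygon edge are excluded explicitly, so boundary ties
# are deterministic (never members).
polygon_mask <- function(vx, vy, height, width) {
  px <- rep(0:(width - 1L), each = height)   # column coordinate of each centre
  py <- rep(0:(height - 1L), times = width)  # row coordinate
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  nv <- length(vx)
  j <- nv
  for (i in seq_len(nv)) {
    cross <- (px - vx[j]) * (vy[i] - vy[j]) - (py - vy[j]) * (vx[i] - vx[j])
    in_bbox <- px >= pmin(vx[i], vx[j]) & px <= pmax(vx[i], vx[j]) &
      py >= pmin(vy[i], vy[j]) & py <= pmax(vy[i], vy[j])
    on_edge <- on_edge | (cross == 0 & in_bbox)
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  matrix(inside & !on_edge, nrow = height, ncol = width)
}

#' Gray-level histogram of a masked region
#'
#' Counts, for every gray level 0-255, the member pixels holding that value.
#' This 256-bin distribution is the object all per-cluster texture metrics
#' are computed from.
#'
#' @param img A `"gray_image"` matrix.
#' @param mask A `"roi_mask"` (or logical matrix) of the same dimensions.
#' @return An object of class `"gray_histogram"`: a list with `counts`
#'   (integer vector of length 256, bin `v + 1` holds gray level `v`) and
#'   `n_total` (member pixel count). `sum(counts) == n_total` always.
#' @export
masked_histogram <- function(img, mask) {
  if (!identical(dim(img), dim(mask))) {
    stop_hcg(
      sprintf("image is %dx%d but mask is %dx%d",
              nrow(img), ncol(img), nrow(mask), ncol(mask)),
      "hcg_error_shape"
    )
  }
  if (!any(mask)) {
    stop_hcg("mask has no member pixels", "hcg_error_empty_mask")
  }
  vals <- unclass(img)[as.logical(mask)]
  counts <- tabulate(vals + 1L, nbins = 256L)
  new_gray_histogram(counts)
}

new_gray_histogram <- function(counts) {
  counts <- as.integer(counts)
  stopifnot(length(counts) == 256L, all(counts >= 0L))
  n_total <- sum(counts)
  if (n_total < 1L) {
    stop_hcg("histogram is empty", "hcg_error_empty_histogram")
  }
  structure(list(counts = counts, n_total = n_total), class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  cat("<gray_histogram> n_total =", x$n_total,
      " mode =", gray_mode(x), "\n")
  invisible(x)
}

#' Tidy a gray-level histogram into a tibble
#'
#' @param x A `"gray_histogram"`.
#' @param ... Unused.
#' @return A tibble with columns `gray` (0-255) and `count`.
#' @method tidy gray_histogram
#' @export
tidy.gray_histogram <- function(x, ...) {
  tibble(gray = 0:255, count = x$counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
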