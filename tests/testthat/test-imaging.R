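test_that("gray conversion reproduces the documented per-pixel formulas", {
  white <- rgb_raster(matrix(255L, 2, 2), matrix(255L, 2, 2), matrix(255L, 2, 2))
  black <- rgb_raster(matrix(0L, 2, 2), matrix(0L, 2, 2), matrix(0L, 2, 2))
  expect_true(all(to_gray8(white) == 255L))
  expect_true(all(to_gray8(black) == 0L))

  red <- rgb_raster(matrix(255L, 1, 1), matrix(0L, 1, 1), matrix(0L, 1, 1))
  expect_equal(to_gray8(red, "weighted")[1, 1], 76L)  # 0.299*255 = 76.245

  px <- rgb_raster(matrix(30L, 1, 1), matrix(60L, 1, 1), matrix(90L, 1, 1))
  expect_equal(to_gray8(px, "mean")[1, 1], 60L)
})

test_that("gray conversion is monotone in each channel", {
  set.seed(101)
  for (i in 1:50) {
    base <- sapply(1:3, function(...) sample(0:254, 1L))
    ch <- sample(1:3, 1L)
    bumped <- base
    bumped[ch] <- bumped[ch] + sample.int(255L - base[ch], 1L)
    as_img <- function(v) {
      rgb_raster(matrix(v[1L], 1, 1), matrix(v[2L], 1, 1), matrix(v[3L], 1, 1))
    }
    for (m in c("weighted", "mean")) {
      expect_gte(to_gray8(as_img(bumped), m)[1, 1],
                 to_gray8(as_img(base), m)[1, 1])
    }
  }
})

test_that("write/read round-trips are pixel-identical for PNG and TIFF", {
  set.seed(7)
  gray <- gray_raster(matrix(sample(0:255, 48, replace = TRUE), 6, 8))
  rgb <- rgb_raster(matrix(sample(0:255, 24, replace = TRUE), 4, 6),
                    matrix(sample(0:255, 24, replace = TRUE), 4, 6),
                    matrix(sample(0:255, 24, replace = TRUE), 4, 6))
  for (ext in c("png", "tif")) {
    pg <- withr::local_tempfile(fileext = paste0(".", ext))
    write_image(gray, pg)
    expect_equal(unclass(read_image(pg)), unclass(gray))
    pc <- withr::local_tempfile(fileext = paste0(".", ext))
    write_image(rgb, pc)
    expect_equal(unclass(read_image(pc)), unclass(rgb))
  }
})

test_that("deep-bit-depth rasters and missing files are rejected", {
  p16 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(16), 4, 4), p16, bits.per.sample = 16L)
  expect_error(read_image(p16), class = "hcg_error_bit_depth")
  expect_error(read_image(file.path(tempdir(), "absent.png")),
               class = "hcg_error_missing_file")
})

test_that("raster masks mark nonzero pixels and reject empty or mismatched ones", {
  p <- withr::local_tempfile(fileext = ".png")
  write_image(uniform_gray(255L, 3, 3), p)
  m <- load_mask(p, c(3L, 3L))
  expect_true(all(m))

  expect_error(load_mask(p, c(4L, 4L)), class = "hcg_error_shape")

  p0 <- withr::local_tempfile(fileext = ".png")
  write_image(uniform_gray(0L, 3, 3), p0)
  expect_error(load_mask(p0, c(3L, 3L)), class = "hcg_error_empty_mask")
})

test_that("polygon masks follow the pixel-centre-inside rule", {
  # Rectangle (0.5,0.5)-(2.5,2.5) on a 4x4 grid: centres at rows/cols 1-2
  # (0-based) are inside, all others out.
  p <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(vertices = list(c(0.5, 0.5), c(2.5, 0.5), c(2.5, 2.5), c(0.5, 2.5))),
    p, auto_unbox = FALSE
  )
  m <- load_mask(p, c(4L, 4L))
  expect_equal(sum(m), 4L)
  expect_true(all(m[2:3, 2:3]))
  # boundary ties excluded: integer-vertex square through the centres
  pb <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(vertices = list(c(0, 0), c(2, 0), c(2, 2), c(0, 2))),
    pb, auto_unbox = FALSE
  )
  mb <- load_mask(pb, c(4L, 4L))
  expect_equal(sum(mb), 1L)  # only the centre at (1,1) is strictly inside
})

test_that("masked histograms count member pixels and conserve totals", {
  h <- masked_histogram(uniform_gray(42L, 2, 5), full_mask(2L, 5L))
  expect_equal(h$counts[43L], 10L)
  expect_equal(sum(h$counts), 10L)

  img <- gray_raster(matrix(c(0L, 0L, 255L), 1, 3))
  h2 <- masked_histogram(img, full_mask(1L, 3L))
  expect_equal(h2$counts[1L], 2L)
  expect_equal(h2$counts[256L], 1L)

  set.seed(11)
  for (i in 1:25) {
    hgt <- sample(2:12, 1L)
    wid <- sample(2:12, 1L)
    img <- gray_raster(matrix(sample(0:255, hgt * wid, TRUE), hgt, wid))
    mask <- matrix(runif(hgt * wid) < 0.6, hgt, wid)
    if (!any(mask)) mask[1, 1] <- TRUE
    h <- masked_histogram(img, mask)
    expect_equal(sum(h$counts), sum(mask))
    expect_equal(h$n_total, sum(mask))
  }

  expect_error(masked_histogram(uniform_gray(1L, 2, 2), full_mask(3L, 3L)),
               class = "hcg_error_shape")
})
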