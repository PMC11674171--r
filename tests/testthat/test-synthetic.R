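masked_mean_gray <- function(cl) {
  mean(unclass(to_gray8(cl$composite))[cl$mask])
}

test_that("rendering is bit-identical under a fixed seed", {
  spec <- cluster_spec(n_layers = 6L, seed = 77L, image_px = 48L)
  a <- sample_cluster(spec)
  b <- sample_cluster(spec)
  expect_identical(unclass(a$composite), unclass(b$composite))
  for (l in seq_along(a$stack$layers)) {
    expect_identical(unclass(a$stack$layers[[l]]), unclass(b$stack$layers[[l]]))
  }
  expect_identical(a$mask, b$mask)
})

test_that("a single absorbing cell darkens exactly its own footprint", {
  cl <- sample_cluster(cluster_spec(
    n_layers = 1L, cells_per_layer = 1L, noise_sd = 0,
    n_stack_layers = 2L, seed = 9L
  ))
  gray <- unclass(to_gray8(cl$composite))
  bg <- cl$spec$background_level
  expect_true(all(gray[cl$mask] < bg))
  expect_true(all(gray[!cl$mask] == unclass(to_gray8(sample_cluster(cluster_spec(
    n_layers = 1L, cells_per_layer = 1L, noise_sd = 0,
    n_stack_layers = 2L, seed = 9L
  ))$composite))[!cl$mask]))  # deterministic background
  # background itself stays at the weighted-gray of the unstained field
  corner <- gray[1, 1]
  expect_gte(corner, bg - 1L)
})

test_that("stacking more layers compounds darkness", {
  m1 <- masked_mean_gray(sample_cluster(cluster_spec(
    n_layers = 1L, noise_sd = 0, n_stack_layers = 2L, seed = 12L
  )))
  m10 <- masked_mean_gray(sample_cluster(cluster_spec(
    n_layers = 10L, noise_sd = 0, seed = 12L
  )))
  expect_lt(m10, m1)
})

test_that("mean masked gray responds monotonically to density and transmittance", {
  # averaged over seeds: darker with more cells, brighter with higher
  # transmittance
  mean_over_seeds <- function(cells, t_nuc) {
    mean(sapply(1:10, function(s) {
      masked_mean_gray(sample_cluster(cluster_spec(
        n_layers = 6L, cells_per_layer = cells,
        nucleus_transmittance = t_nuc, cytoplasm_transmittance = 0.95,
        noise_sd = 0, seed = 1000L + s
      )))
    }))
  }
  dens <- sapply(c(2L, 6L, 12L), mean_over_seeds, t_nuc = 0.8)
  expect_true(all(diff(dens) < 0))
  trans <- sapply(c(0.7, 0.8, 0.9), function(t) mean_over_seeds(6L, t))
  expect_true(all(diff(trans) > 0))
})

test_that("study sampling is deterministic and validates its inputs", {
  expect_error(sample_study(0L), class = "hcg_error_spec")
  expect_error(sample_study(2L, presets = list()), class = "hcg_error_spec")

  s1 <- sample_study(2L, seed = 5L)
  s2 <- sample_study(2L, seed = 5L)
  expect_identical(s1$cluster_id, s2$cluster_id)
  expect_identical(s1$truth_thickness_um, s2$truth_thickness_um)
  expect_identical(unclass(s1$cluster[[4L]]$composite),
                   unclass(s2$cluster[[4L]]$composite))
})

test_that("preset populations order ground-truth thickness as designed", {
  s <- sample_study(15L, seed = 8L, noise_sd = 0)
  med <- tapply(s$truth_thickness_um, s$group, median)
  expect_gt(med[["HSIL-like"]], med[["AGC-like"]])
  expect_gt(med[["HSIL-like"]], med[["NILM-like"]])
  expect_lt(abs(med[["AGC-like"]] - med[["NILM-like"]]), 5)
})

test_that("invalid cluster specifications are rejected", {
  expect_error(cluster_spec(n_layers = 0L), class = "hcg_error_spec")
  expect_error(cluster_spec(nucleus_transmittance = 0), class = "hcg_error_spec")
  expect_error(cluster_spec(nucleus_transmittance = 0.9,
                            cytoplasm_transmittance = 0.8),
               class = "hcg_error_spec")
  expect_error(cluster_spec(n_layers = 41L), class = "hcg_error_spec")
  expect_error(cluster_spec(n_layers = 10L, bottom_layer = 35L),
               class = "hcg_error_spec")
})

test_that("cluster files round-trip through disk", {
  cl <- sample_cluster(cluster_spec(n_layers = 3L, n_stack_layers = 5L,
                                    image_px = 32L, seed = 4L))
  stem <- file.path(withr::local_tempdir(), "cl")
  paths <- write_cluster(cl, stem)
  img <- read_image(paths[["composite"]])
  expect_equal(unclass(img), unclass(cl$composite))
  mask <- load_mask(paths[["mask"]], dim(cl$mask))
  expect_equal(unclass(mask), unclass(cl$mask))
})
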