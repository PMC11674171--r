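# Synthetic brightfield cluster simulator.
#
# A cluster is a contiguous run of occupied 1 µm focal planes inside a fixed
# 40-plane stack. Each occupied plane holds a set of stained cells (nucleus
# disc inside a cytoplasm disc) placed uniformly at random in a circular
# footprint. Light transmission is multiplicative (Beer-Lambert style): every
# traversed nucleus multiplies the transmitted intensity by the nuclear
# transmittance, every traversed cytoplasm-only region by the cytoplasmic
# transmittance. Stacking therefore compounds darkness toward gray level 0 and
# produces the long-tailed, high-kurtosis gray histograms seen in thick dense
# clusters. Defocus is modelled as Gaussian blur of each plane's transmittance
# map with sigma proportional to the focal distance, which is what makes the
# focus-span thickness estimator meaningful.

# --- separable Gaussian blur with per-(size, sigma) kernel cache ------------

.blur_cache <- new.env(parent = emptyenv())

blur_kernel <- function(n, sigma) {
  key <- paste0(n, "_", format(sigma, digits = 10))
  k <- .blur_cache[[key]]
  if (!is.null(k)) {
    return(k)
  }
  idx <- seq_len(n)
  d <- outer(idx, idx, "-")
  k <- exp(-d^2 / (2 * sigma^2))
  k[abs(d) > ceiling(4 * sigma) + 1] <- 0
  k <- k / rowSums(k)  # renormalised truncation = reflect-free mass keep
  .blur_cache[[key]] <- k
  k
}

gaussian_blur <- function(x, sigma) {
  if (sigma < 1e-8) {
    return(x)
  }
  k <- blur_kernel(nrow(x), sigma)
  k %*% x %*% t(k)
}

# --- cluster specification ---------------------------------------------------

#' Specify a synthetic cell cluster
#'
#' Collects every parameter of the simulated transmitted-light cluster.
#' Defaults describe a generic mid-size cluster; the study presets in
#' [default_presets()] override the structural parameters per group.
#'
#' @param group_preset Label carried through as ground-truth group identity.
#' @param n_layers Number of occupied focal planes (>= 1); ground-truth
#'   thickness is `(n_layers - 1) * spacing_um`.
#' @param cells_per_layer Cells placed in each occupied plane.
#' @param nucleus_radius_um,cell_radius_um Nucleus and whole-cell radii (µm);
#'   `cell_radius_um >= nucleus_radius_um > 0`.
#' @param nucleus_transmittance,cytoplasm_transmittance Fraction of light
#'   transmitted per traversal, in (0, 1];
#'   `nucleus_transmittance <= cytoplasm_transmittance` (nuclei stain darker).
#' @param background_level Gray level of empty field (0-255).
#' @param noise_sd Additive Gaussian camera noise, gray levels; 0 disables.
#' @param defocus_sigma_per_um Gaussian blur sigma (µm) per µm of focal
#'   distance.
#' @param pixel_size_um µm per pixel.
#' @param footprint_radius_um Radius of the disc cell centres are drawn from.
#' @param image_px Square image side in pixels.
#' @param n_stack_layers Total focal planes in the stack (default 40).
#' @param spacing_um Focal step (default 1 µm).
#' @param bottom_layer 1-based stack index of the deepest occupied plane;
#'   `NULL` (default) centres the occupied run in the stack.
#' @param seed Integer seed; identical specs render bit-identical clusters.
#' @return A validated list of class `"cluster_spec"`.
#' @export
cluster_spec <- function(group_preset = "generic",
                         n_layers = 10L,
                         cells_per_layer = 6L,
                         nucleus_radius_um = 3.2,
                         cell_radius_um = 5.5,
                         nucleus_transmittance = 0.84,
                         cytoplasm_transmittance = 0.94,
                         background_level = 230L,
                         noise_sd = 2,
                         defocus_sigma_per_um = 1.5,
                         pixel_size_um = 1,
                         footprint_radius_um = 18,
                         image_px = 64L,
                         n_stack_layers = 40L,
                         spacing_um = 1,
                         bottom_layer = NULL,
                         seed = 1L) {
  spec <- list(
    group_preset = group_preset,
    n_layers = as.integer(n_layers),
    cells_per_layer = as.integer(cells_per_layer),
    nucleus_radius_um = nucleus_radius_um,
    cell_radius_um = cell_radius_um,
    nucleus_transmittance = nucleus_transmittance,
    cytoplasm_transmittance = cytoplasm_transmittance,
    background_level = as.integer(background_level),
    noise_sd = noise_sd,
    defocus_sigma_per_um = defocus_sigma_per_um,
    pixel_size_um = pixel_size_um,
    footprint_radius_um = footprint_radius_um,
    image_px = as.integer(image_px),
    n_stack_layers = as.integer(n_stack_layers),
    spacing_um = spacing_um,
    bottom_layer = if (is.null(bottom_layer)) NULL else as.integer(bottom_layer),
    seed = as.integer(seed)
  )
  validate_cluster_spec(spec)
  structure(spec, class = "cluster_spec")
}

validate_cluster_spec <- function(s) {
  ok <- function(cond, msg) if (!cond) stop_hcg(msg, "hcg_error_spec")
  ok(s$n_layers >= 1L, "n_layers must be >= 1")
  ok(s$cells_per_layer >= 1L, "cells_per_layer must be >= 1")
  ok(s$nucleus_radius_um > 0 && s$cell_radius_um > 0, "radii must be > 0")
  ok(s$cell_radius_um >= s$nucleus_radius_um,
     "cell_radius_um must be >= nucleus_radius_um")
  ok(s$nucleus_transmittance > 0 && s$nucleus_transmittance <= 1,
     "nucleus_transmittance must be in (0, 1]")
  ok(s$cytoplasm_transmittance > 0 && s$cytoplasm_transmittance <= 1,
     "cytoplasm_transmittance must be in (0, 1]")
  ok(s$nucleus_transmittance <= s$cytoplasm_transmittance,
     "nucleus must transmit no more than cytoplasm")
  ok(s$background_level >= 0 && s$background_level <= 255,
     "background_level must be a gray level 0-255")
  ok(s$noise_sd >= 0, "noise_sd must be >= 0")
  ok(s$defocus_sigma_per_um >= 0, "defocus_sigma_per_um must be >= 0")
  ok(s$pixel_size_um > 0 && s$spacing_um > 0, "scales must be > 0")
  ok(s$n_layers <= s$n_stack_layers, "occupied layers exceed the stack")
  if (!is.null(s$bottom_layer)) {
    ok(s$bottom_layer >= 1L &&
         s$bottom_layer + s$n_layers - 1L <= s$n_stack_layers,
       "occupied run does not fit in the stack")
  }
  invisible(s)
}

# Per-channel stain exponents applied to the gray transmittances when
# rendering the 24-bit composite: hematoxylin-stained nuclei absorb green and
# red more than blue (blue-violet cast); EA/OG cytoplasm absorbs green most
# (pink cast). The gray channel used by the analysis has exponent 1.
.stain_exponents <- list(
  nucleus = c(r = 1.1, g = 1.5, b = 0.6),
  cytoplasm = c(r = 0.5, g = 1.4, b = 0.9)
)

# --- rendering ---------------------------------------------------------------

#' Render one synthetic cluster
#'
#' Places cells, computes per-plane transmittance maps, and renders the
#' all-in-focus 24-bit composite plus the full defocused Z-stack. All
#' randomness (cell placement, noise) flows from `spec$seed`; the same spec
#' renders bit-identically.
#'
#' @param spec A [cluster_spec()].
#' @return A list of class `"synthetic_cluster"`: `stack` (a [zstack()]),
#'   `composite` (`"rgb_image"`), `mask` (`"roi_mask"`: the union of all cell
#'   traversals, i.e. every pixel at least one cell covers),
#'   `truth_thickness_um`, `truth_label`, and `spec`.
#' @export
sample_cluster <- function(spec) {
  stopifnot(inherits(spec, "cluster_spec"))
  withr::with_seed(spec$seed, render_cluster(spec))
}

render_cluster <- function(s) {
  n_px <- s$image_px
  # pixel-centre coordinates in µm, image centred on the optical axis
  u <- (seq_len(n_px) - (n_px + 1) / 2) * s$pixel_size_um

  n_nuc <- vector("list", s$n_layers)
  n_cyt <- vector("list", s$n_layers)
  for (l in seq_len(s$n_layers)) {
    nuc <- matrix(0L, n_px, n_px)
    cyt <- matrix(0L, n_px, n_px)
    rad <- s$footprint_radius_um * sqrt(runif(s$cells_per_layer))
    ang <- runif(s$cells_per_layer, 0, 2 * pi)
    cx <- rad * cos(ang)
    cy <- rad * sin(ang)
    for (c_i in seq_len(s$cells_per_layer)) {
      rows <- which(abs(u - cy[c_i]) <= s$cell_radius_um)
      cols <- which(abs(u - cx[c_i]) <= s$cell_radius_um)
      if (length(rows) == 0L || length(cols) == 0L) next
      d2 <- outer((u[rows] - cy[c_i])^2, (u[cols] - cx[c_i])^2, "+")
      in_nuc <- d2 <= s$nucleus_radius_um^2
      in_cell <- d2 <= s$cell_radius_um^2
      nuc[rows, cols] <- nuc[rows, cols] + in_nuc
      cyt[rows, cols] <- cyt[rows, cols] + (in_cell & !in_nuc)
    }
    n_nuc[[l]] <- nuc
    n_cyt[[l]] <- cyt
  }

  total_nuc <- Reduce(`+`, n_nuc)
  total_cyt <- Reduce(`+`, n_cyt)
  # The trim mask is the union of all cell traversals — the analogue of a
  # manual trim following the cluster outline, excluding clean background.
  coverage <- total_nuc + total_cyt
  mask <- as_roi_mask(coverage >= 1L)

  # all-in-focus 24-bit composite with stain colour model
  bg <- s$background_level
  chan <- function(part) {
    wn <- .stain_exponents$nucleus[[part]]
    wc <- .stain_exponents$cytoplasm[[part]]
    bg * s$nucleus_transmittance^(wn * total_nuc) *
      s$cytoplasm_transmittance^(wc * total_cyt)
  }
  comp <- array(0, dim = c(n_px, n_px, 3L))
  comp[, , 1L] <- chan("r")
  comp[, , 2L] <- chan("g")
  comp[, , 3L] <- chan("b")
  if (s$noise_sd > 0) {
    comp <- comp + rnorm(length(comp), sd = s$noise_sd)
  }
  composite <- new_rgb_image(clamp8(round_half_up(comp)))

  # defocused Z-stack: each occupied plane's gray transmittance map is
  # blurred by its focal distance, then combined multiplicatively
  bottom <- s$bottom_layer %||%
    (floor((s$n_stack_layers - s$n_layers) / 2) + 1L)
  plane_abs <- bottom + seq_len(s$n_layers) - 1L
  t_gray <- map(seq_len(s$n_layers), function(l) {
    s$nucleus_transmittance^n_nuc[[l]] *
      s$cytoplasm_transmittance^n_cyt[[l]]
  })
  layers <- vector("list", s$n_stack_layers)
  for (f in seq_len(s$n_stack_layers)) {
    prod_map <- matrix(1, n_px, n_px)
    for (l in seq_len(s$n_layers)) {
      dist_um <- abs(f - plane_abs[l]) * s$spacing_um
      sigma_px <- s$defocus_sigma_per_um * dist_um / s$pixel_size_um
      prod_map <- prod_map * gaussian_blur(t_gray[[l]], sigma_px)
    }
    img <- bg * prod_map
    if (s$noise_sd > 0) {
      img <- img + rnorm(length(img), sd = s$noise_sd)
    }
    layers[[f]] <- new_gray_image(clamp8(round_half_up(img)))
  }

  structure(
    list(
      stack = zstack(layers, spacing_um = s$spacing_um),
      composite = composite,
      mask = mask,
      truth_thickness_um = (s$n_layers - 1L) * s$spacing_um,
      truth_label = s$group_preset,
      bottom_layer = bottom,
      spec = s
    ),
    class = "synthetic_cluster"
  )
}

#' @export
print.synthetic_cluster <- function(x, ...) {
  cat("<synthetic_cluster>", x$truth_label,
      " truth thickness =", x$truth_thickness_um, "um,",
      sum(x$mask), "mask pixels\n")
  invisible(x)
}

# --- study-level sampling ----------------------------------------------------

#' Default group presets for a synthetic study
#'
#' Three cluster populations mirroring the qualitative structure of the
#' clinical groups:
#' * **HSIL-like** — thick (occupied layers 11-23), densely packed, darkly
#'   staining nuclei with scant cytoplasm;
#' * **AGC-like** — thinner (8-14 layers), moderate density, preserved
#'   cytoplasm;
#' * **NILM-like** — thin (8-13 layers), sparse.
#'
#' Layer-count ranges set the ground-truth thickness ordering; transmittance
#' and density values are chosen so the group *orderings* of gray mode,
#' skewness and kurtosis match the clinical pattern, not any exact clinical
#' medians (which depend on data the simulator does not possess).
#'
#' @return A named list of preset parameter lists, one per group.
#' @export
default_presets <- function() {
  list(
    "HSIL-like" = list(
      n_layers_range = c(11L, 23L),
      cells_per_layer_range = c(10L, 16L),
      nucleus_radius_um = 3.2,
      cell_radius_um = 4.2,
      nucleus_transmittance = 0.70,
      cytoplasm_transmittance = 0.95,
      footprint_radius_um = 16
    ),
    "AGC-like" = list(
      n_layers_range = c(8L, 14L),
      cells_per_layer_range = c(6L, 10L),
      nucleus_radius_um = 3.2,
      cell_radius_um = 6.5,
      nucleus_transmittance = 0.84,
      cytoplasm_transmittance = 0.95,
      footprint_radius_um = 16
    ),
    "NILM-like" = list(
      n_layers_range = c(8L, 13L),
      cells_per_layer_range = c(5L, 8L),
      nucleus_radius_um = 3.2,
      cell_radius_um = 5.5,
      nucleus_transmittance = 0.80,
      cytoplasm_transmittance = 0.95,
      footprint_radius_um = 16
    )
  )
}

# Deterministic per-cluster seed scheme: a fixed multiplier of the study seed
# plus a prime-stepped counter, reduced modulo 2^31 - 1. Documented so that
# any single cluster of a study can be re-rendered in isolation.
derive_seed <- function(study_seed, index) {
  as.integer((as.double(study_seed) * 100003 + index * 7919) %% 2147483647)
}

#' Sample a synthetic three-group study
#'
#' Draws `n_per_group` independent clusters per preset. Per-cluster
#' structural parameters (occupied layer count, cells per layer) are sampled
#' uniformly from the preset ranges; every cluster gets its own seed derived
#' deterministically from the study seed and a counter, so the same study
#' seed reproduces the identical cluster list and any cluster can be
#' re-rendered piecewise.
#'
#' @param n_per_group Clusters per preset (>= 1).
#' @param presets Named list of presets as in [default_presets()].
#' @param seed Study-level integer seed.
#' @param noise_sd Camera noise passed to every cluster (gray levels).
#' @return A tibble with one row per cluster: `cluster_id`, `group`,
#'   `truth_thickness_um`, `n_layers`, `cells_per_layer`, and `cluster`
#'   (list-column of `"synthetic_cluster"` objects).
#' @export
sample_study <- function(n_per_group, presets = default_presets(), seed = 1L,
                         noise_sd = 2) {
  if (length(presets) < 1L) {
    stop_hcg("at least one preset is required", "hcg_error_spec")
  }
  if (n_per_group < 1L) {
    stop_hcg("n_per_group must be >= 1", "hcg_error_spec")
  }
  idx <- 0L
  rows <- list()
  for (gname in names(presets)) {
    p <- presets[[gname]]
    for (i in seq_len(n_per_group)) {
      idx <- idx + 1L
      cseed <- derive_seed(seed, idx)
      params <- withr::with_seed(cseed, list(
        n_layers = sample(p$n_layers_range[1L]:p$n_layers_range[2L], 1L),
        cells = sample(p$cells_per_layer_range[1L]:p$cells_per_layer_range[2L], 1L),
        render_seed = sample.int(2147483646L, 1L)
      ))
      spec <- cluster_spec(
        group_preset = gname,
        n_layers = params$n_layers,
        cells_per_layer = params$cells,
        nucleus_radius_um = p$nucleus_radius_um,
        cell_radius_um = p$cell_radius_um,
        nucleus_transmittance = p$nucleus_transmittance,
        cytoplasm_transmittance = p$cytoplasm_transmittance,
        footprint_radius_um = p$footprint_radius_um,
        noise_sd = noise_sd,
        seed = params$render_seed
      )
      cl <- sample_cluster(spec)
      rows[[idx]] <- tibble(
        cluster_id = sprintf("%s_%03d", gname, i),
        group = gname,
        truth_thickness_um = cl$truth_thickness_um,
        n_layers = params$n_layers,
        cells_per_layer = params$cells,
        cluster = list(cl)
      )
    }
  }
  bind_rows(rows)
}

#' Write a synthetic cluster to disk
#'
#' Emits the composite (PNG), the Z-stack (multi-page TIFF, bottom first),
#' and the footprint mask (PNG) under a common file stem.
#'
#' @param cluster A `"synthetic_cluster"`.
#' @param stem Path stem; files `<stem>_composite.png`, `<stem>_stack.tif`,
#'   `<stem>_mask.png` are written.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cluster <- function(cluster, stem) {
  paths <- c(
    composite = paste0(stem, "_composite.png"),
    stack = paste0(stem, "_stack.tif"),
    mask = paste0(stem, "_mask.png")
  )
  write_image(cluster$composite, paths[["composite"]])
  write_zstack(cluster$stack, paths[["stack"]])
  write_image(new_gray_image(ifelse(cluster$mask, 255L, 0L)), paths[["mask"]])
  invisible(paths)
}
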