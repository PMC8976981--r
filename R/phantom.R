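#' Configuration for the synthetic mpMRI phantom generator
#'
#' Describes a prostate-like three-channel phantom: an ellipsoidal gland with
#' zero or more ellipsoidal intra-gland lesions on a uniform background. The
#' three channels emulate a co-registered mpMRI study: a T2-like channel
#' (lesion hypointense relative to gland), an ADC map (lesion markedly
#' reduced), and a synthetic high-b diffusion image computed from the
#' mono-exponential forward model. Two tumor ground truths are produced: the
#' lesion mask itself ("radiologist-style") and a smoothly deformed copy
#' ("histology-style"), emulating the non-rigid discrepancy between MRI
#' contours and registered whole-mount histology contours.
#'
#' Tissue parameter defaults are plausibility choices for prostate tissue at
#' clinical field strengths (ADC 2.0e-3 / 1.4e-3 / 0.7e-3 mm^2/s for
#' background / gland / lesion) and are fully overridable.
#'
#' @param grid_shape voxel grid, each dimension divisible by 8 (three pooling
#'   levels downstream).
#' @param voxel_spacing mm, default the standard in-plane protocol
#'   0.78 x 0.78 x 3.
#' @param gland_semiaxes_range mm range the three gland semiaxes are drawn
#'   from.
#' @param n_lesions_range inclusive integer interval for the lesion count.
#' @param lesion_semiaxes_range mm range for lesion semiaxes; must be strictly
#'   below the gland range minimum.
#' @param tissue_params per-tissue list with `t2` (mean T2-like intensity),
#'   `adc` (mm^2/s) and `s0` (unweighted diffusion signal).
#' @param noise_sigma Gaussian noise level as a fraction of the local tissue
#'   mean signal of each channel.
#' @param histology_deform_magnitude mean displacement (mm) of the smooth
#'   random warp applied to derive the histology-style tumor mask.
#' @param hb_b_value b-value (s/mm^2) of the synthetic high-b channel.
#' @param border_smooth_sigma Gaussian sigma (voxels) used to soften tissue
#'   borders in the generated parameter fields; 0 disables smoothing.
#' @param seed integer seed; the same configuration and seed give a bitwise
#'   identical phantom.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 16),
                           voxel_spacing = c(0.78, 0.78, 3),
                           gland_semiaxes_range = c(12, 18),
                           n_lesions_range = c(1, 2),
                           lesion_semiaxes_range = c(3, 6),
                           tissue_params = list(
                             background = list(t2 = 200, adc = 2.0e-3, s0 = 800),
                             gland      = list(t2 = 400, adc = 1.4e-3, s0 = 1200),
                             lesion     = list(t2 = 250, adc = 0.7e-3, s0 = 1300)),
                           noise_sigma = 0.05,
                           histology_deform_magnitude = 2,
                           hb_b_value = 1400,
                           border_smooth_sigma = 1,
                           seed = 1L) {
  assert_that(is_int_triple(grid_shape) && all(grid_shape %% 8 == 0),
              "grid_shape dimensions must be positive and divisible by 8")
  assert_that(is.numeric(voxel_spacing) && all(voxel_spacing > 0),
              "voxel_spacing must be positive")
  assert_that(length(gland_semiaxes_range) == 2L &&
                diff(gland_semiaxes_range) >= 0 && gland_semiaxes_range[1] > 0,
              "gland_semiaxes_range must be an increasing positive range")
  assert_that(length(lesion_semiaxes_range) == 2L &&
                diff(lesion_semiaxes_range) >= 0 && lesion_semiaxes_range[1] > 0,
              "lesion_semiaxes_range must be an increasing positive range")
  assert_that(lesion_semiaxes_range[2] < gland_semiaxes_range[1],
              "lesion semiaxes must be strictly smaller than gland semiaxes")
  assert_that(length(n_lesions_range) == 2L && all(n_lesions_range >= 0) &&
                n_lesions_range[1] <= n_lesions_range[2],
              "n_lesions_range must be a non-negative integer interval")
  for (tt in c("background", "gland", "lesion")) {
    p <- tissue_params[[tt]]
    assert_that(!is.null(p) && all(unlist(p[c("t2", "adc", "s0")]) > 0),
                "tissue_params$%s must provide positive t2, adc and s0", tt)
  }
  assert_that(noise_sigma >= 0, "noise_sigma must be >= 0")
  assert_that(histology_deform_magnitude >= 0 && hb_b_value >= 0 &&
                border_smooth_sigma >= 0, "magnitudes must be >= 0")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 gland_semiaxes_range = as.numeric(gland_semiaxes_range),
                 n_lesions_range = as.integer(n_lesions_range),
                 lesion_semiaxes_range = as.numeric(lesion_semiaxes_range),
                 tissue_params = tissue_params,
                 noise_sigma = as.numeric(noise_sigma),
                 histology_deform_magnitude = as.numeric(histology_deform_magnitude),
                 hb_b_value = as.numeric(hb_b_value),
                 border_smooth_sigma = as.numeric(border_smooth_sigma),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Physical voxel-center coordinates (mm), n x 3 matrix for the whole grid.
voxel_centers <- function(grid_shape, spacing) {
  grid_coords(grid_shape, c(1, 1, 1)) %*% diag(spacing)
}

# Logical mask of an axially-rotated ellipsoid given physical coords (n x 3).
ellipsoid_mask <- function(coords, center, semiaxes, theta) {
  dx <- coords[, 1] - center[1]
  dy <- coords[, 2] - center[2]
  dz <- coords[, 3] - center[3]
  rx <- cos(theta) * dx + sin(theta) * dy
  ry <- -sin(theta) * dx + cos(theta) * dy
  (rx / semiaxes[1])^2 + (ry / semiaxes[2])^2 + (dz / semiaxes[3])^2 <= 1
}

#' Generate a synthetic multi-channel prostate-like phantom
#'
#' Draws an ellipsoidal gland (jittered center, random axial orientation) and
#' intra-gland ellipsoidal lesions, builds per-tissue T2-like / ADC / S0
#' parameter fields (optionally smoothed at tissue borders), computes the
#' synthetic high-b channel through the mono-exponential forward model, adds
#' Gaussian noise scaled to the local tissue mean, and derives the
#' histology-style tumor mask by warping the radiologist-style mask with a
#' smooth random displacement field.
#'
#' @param config a [phantom_config].
#' @return An object of class `phantom_case`: `image`
#'   ([multichannel_volume] with channels `t2`, `adc`, `highb`), `labels`
#'   ([label_volume]) and `truth_params` (the noiseless ADC and S0 fields
#'   used for generation, plus gland/lesion geometry).
#' @export
generate_phantom <- function(config) {
  assert_that(inherits(config, "phantom_config"),
              "config must be a phantom_config")
  with_seed(config$seed, generate_phantom_impl(config))
}

generate_phantom_impl <- function(config) {
  gs <- config$grid_shape
  sp <- config$voxel_spacing
  tp <- config$tissue_params
  coords <- voxel_centers(gs, sp)
  extent <- gs * sp

  gland_center <- extent / 2 + stats::runif(3, -2, 2)
  gland_axes <- stats::runif(3, config$gland_semiaxes_range[1],
                             config$gland_semiaxes_range[2])
  gland_theta <- stats::runif(1, 0, 2 * pi)
  gland_mask <- array(ellipsoid_mask(coords, gland_center, gland_axes,
                                     gland_theta), gs)
  assert_that(sum(gland_mask) > 0, "gland ellipsoid fell outside the grid")

  n_lesions <- if (config$n_lesions_range[1] == config$n_lesions_range[2]) {
    config$n_lesions_range[1]
  } else {
    sample(config$n_lesions_range[1]:config$n_lesions_range[2], 1L)
  }
  tumor_mask <- array(FALSE, gs)
  lesions <- list()
  for (i in seq_len(n_lesions)) {
    placed <- FALSE
    for (try in 1:100) {
      axes <- stats::runif(3, config$lesion_semiaxes_range[1],
                           config$lesion_semiaxes_range[2])
      theta <- stats::runif(1, 0, 2 * pi)
      center <- gland_center + (gland_axes - max(axes)) * stats::runif(3, -1, 1)
      m <- ellipsoid_mask(coords, center, axes, theta)
      if (any(m) && !any(m & !gland_mask)) {
        tumor_mask <- tumor_mask | array(m, gs)
        lesions[[length(lesions) + 1L]] <-
          list(center = center, semiaxes = axes, theta = theta)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop_sx(paste("lesion placement failed after 100 retries: could not fit",
                    "an ellipsoid of semiaxes in [%g, %g] mm fully inside the",
                    "gland (semiaxes %s mm)"),
              config$lesion_semiaxes_range[1], config$lesion_semiaxes_range[2],
              paste(signif(gland_axes, 3), collapse = ", "))
    }
  }

  class_map <- array(0L, gs)
  class_map[gland_mask] <- 1L
  class_map[tumor_mask] <- 2L

  field_for <- function(key) {
    f <- array(tp$background[[key]], gs)
    f[gland_mask] <- tp$gland[[key]]
    f[tumor_mask] <- tp$lesion[[key]]
    f
  }
  t2_mean <- field_for("t2")
  adc_mean <- field_for("adc")
  s0_mean <- field_for("s0")
  bss <- config$border_smooth_sigma
  t2_true <- gaussian_smooth3d(t2_mean, bss)
  adc_true <- gaussian_smooth3d(adc_mean, bss)
  s0_true <- gaussian_smooth3d(s0_mean, bss)
  hb_true <- s0_true * exp(-config$hb_b_value * adc_true)

  ns <- config$noise_sigma
  noisy <- function(truth, local_scale) {
    truth + array(stats::rnorm(prod(gs)), gs) * ns * local_scale
  }
  t2_chan <- noisy(t2_true, t2_mean)
  adc_chan <- noisy(adc_true, adc_mean)
  hb_chan <- noisy(hb_true, hb_true)

  # histology-style tumor mask: warp by a smooth random displacement field
  tumor_histo <- tumor_mask
  if (any(tumor_mask) && config$histology_deform_magnitude > 0) {
    for (attempt in 1:5) {
      disp <- lapply(1:3, function(i) {
        gaussian_smooth3d(array(stats::rnorm(prod(gs)), gs), sigma = 3)
      })
      mag <- sqrt(disp[[1]]^2 + disp[[2]]^2 + disp[[3]]^2)
      scale <- config$histology_deform_magnitude / mean(mag)
      src <- grid_coords(gs, c(1, 1, 1))
      for (i in 1:3) src[, i] <- src[, i] - scale * as.numeric(disp[[i]]) / sp[i]
      warped <- array(sample_at(tumor_mask * 1, src, mode = "nearest") > 0.5, gs)
      if (any(warped & tumor_mask)) {
        tumor_histo <- warped
        break
      }
    }
  }

  labels <- label_volume(class_map, gland_mask = gland_mask,
                         tumor_mask_rad = tumor_mask,
                         tumor_mask_histo = tumor_histo, spacing = sp)
  image <- multichannel_volume(list(t2 = t2_chan, adc = adc_chan,
                                    highb = hb_chan), spacing = sp)
  structure(list(image = image, labels = labels,
                 truth_params = list(adc = adc_true, s0 = s0_true,
                                     t2 = t2_true,
                                     gland = list(center = gland_center,
                                                  semiaxes = gland_axes,
                                                  theta = gland_theta),
                                     lesions = lesions,
                                     seed = config$seed)),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("phantom_case: grid %dx%dx%d, %d lesion(s), gland %d vox, tumor %d vox\n",
              d[1], d[2], d[3], length(x$truth_params$lesions),
              sum(x$labels$gland_mask), sum(x$labels$tumor_mask_rad)))
  invisible(x)
}

#' Forward-simulate a multi-b-value DWI series from a phantom
#'
#' Evaluates the mono-exponential signal model `S0 * exp(-b * ADC)` at each
#' requested b-value using the phantom's noiseless truth parameter fields and
#' optionally adds Gaussian noise. With `sigma_mode = "relative"` (default)
#' the noise standard deviation at each voxel is `noise_sigma` times the
#' local noiseless signal of that b-volume; with `"absolute"` it is
#' `noise_sigma` times the local S0, i.e. a constant thermal-noise floor
#' across b-values.
#'
#' @param case a [phantom_case].
#' @param b_values at least two distinct non-negative b-values (s/mm^2).
#' @param noise_sigma noise fraction (0 = noiseless, exactly consistent with
#'   `case$truth_params`).
#' @param sigma_mode `"relative"` or `"absolute"` (see above).
#' @param seed optional integer; when given, the noise draw is reproducible
#'   independent of the caller's RNG state.
#' @return A [dwi_series].
#' @export
generate_dwi_series <- function(case, b_values = c(0, 400, 800),
                                noise_sigma = 0,
                                sigma_mode = c("relative", "absolute"),
                                seed = NULL) {
  assert_that(inherits(case, "phantom_case"), "case must be a phantom_case")
  sigma_mode <- match.arg(sigma_mode)
  assert_that(is.numeric(b_values) && all(b_values >= 0),
              "b-values must be non-negative")
  assert_that(length(unique(b_values)) >= 2L,
              "fewer than 2 distinct b-values: the downstream ADC fit would be impossible")
  gen <- function() {
    adc <- case$truth_params$adc
    s0 <- case$truth_params$s0
    vols <- lapply(b_values, function(b) {
      S <- s0 * exp(-b * adc)
      if (noise_sigma > 0) {
        sd_field <- if (sigma_mode == "relative") noise_sigma * S else noise_sigma * s0
        S <- S + array(stats::rnorm(length(S)), dim(S)) * sd_field
      }
      S
    })
    dwi_series(b_values, vols, spacing = case$image$spacing)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
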