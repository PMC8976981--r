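#' Multi-channel 3-D volume
#'
#' Container for a set of co-registered scalar 3-D fields (e.g. a T2-like
#' channel, an ADC map and a synthetic high-b diffusion image) that share a
#' voxel grid and spacing. This is the network input \eqn{I(x)}.
#'
#' @param channels named list of 3-D numeric arrays, all the same shape.
#' @param spacing voxel spacing in mm, length-3 numeric.
#' @param origin physical position of the first voxel, length-3 numeric (mm).
#' @return An object of class `multichannel_volume`.
#' @export
multichannel_volume <- function(channels, spacing, origin = c(0, 0, 0)) {
  assert_that(is.list(channels) && length(channels) >= 1L,
              "channels must be a non-empty named list of 3-D arrays")
  assert_that(!is.null(names(channels)) && all(nzchar(names(channels))),
              "every channel must be named")
  dims <- lapply(channels, dim)
  assert_that(all(vapply(dims, length, 1L) == 3L),
              "every channel must be a 3-D array")
  for (i in seq_along(channels)) {
    if (!identical(dims[[i]], dims[[1]])) {
      stop_sx("channel '%s' has shape %s but channel '%s' has shape %s",
              names(channels)[i], paste(dims[[i]], collapse = "x"),
              names(channels)[1], paste(dims[[1]], collapse = "x"))
    }
  }
  assert_that(is.numeric(spacing) && length(spacing) == 3L && all(spacing > 0),
              "spacing must be 3 positive numbers (mm)")
  structure(list(channels = channels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "multichannel_volume")
}

#' @export
dim.multichannel_volume <- function(x) dim(x$channels[[1]])

#' @export
print.multichannel_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("multichannel_volume: %d channel(s) [%s], grid %dx%dx%d, spacing %.3gx%.3gx%.3g mm\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

# Stack channels into an (X, Y, Z, C) array.
as_chan_array <- function(vol) {
  d <- dim(vol)
  arr <- array(0, c(d, length(vol$channels)))
  for (i in seq_along(vol$channels)) arr[, , , i] <- vol$channels[[i]]
  arr
}

#' Label volume with class map and ground-truth masks
#'
#' Holds the per-voxel class map (0 background, 1 prostate gland, 2 tumor)
#' together with the full gland mask and the two tumor ground truths: the
#' radiologist-style mask and the histology-style (deformed) mask. The class
#' map gives tumor precedence over gland; the gland mask always contains the
#' tumor, matching how a whole-gland contour is drawn clinically.
#'
#' @param class_map integer 3-D array with values in {0, 1, 2}.
#' @param gland_mask,tumor_mask_rad,tumor_mask_histo logical 3-D arrays,
#'   same shape as `class_map`. Missing masks are derived from the class map.
#' @param spacing voxel spacing in mm.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(class_map, gland_mask = NULL, tumor_mask_rad = NULL,
                         tumor_mask_histo = NULL, spacing = c(1, 1, 1)) {
  assert_that(length(dim(class_map)) == 3L, "class_map must be a 3-D array")
  vals <- unique(as.integer(class_map))
  assert_that(all(vals %in% 0:2), "class_map values must be in {0,1,2}")
  d <- dim(class_map)
  cm <- array(as.integer(class_map), d)
  if (is.null(tumor_mask_rad)) tumor_mask_rad <- cm == 2L
  if (is.null(gland_mask)) gland_mask <- cm >= 1L
  if (is.null(tumor_mask_histo)) tumor_mask_histo <- tumor_mask_rad
  for (m in list(gland_mask, tumor_mask_rad, tumor_mask_histo)) {
    assert_that(is.logical(m) && identical(dim(m), d),
                "masks must be logical arrays with the class_map shape")
  }
  assert_that(!any(tumor_mask_rad & !gland_mask),
              "tumor mask must be contained in the gland mask")
  structure(list(class_map = cm, gland_mask = gland_mask,
                 tumor_mask_rad = tumor_mask_rad,
                 tumor_mask_histo = tumor_mask_histo,
                 spacing = as.numeric(spacing)),
            class = "label_volume")
}

#' @export
dim.label_volume <- function(x) dim(x$class_map)

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("label_volume: grid %dx%dx%d | gland %d vox, tumor(rad) %d vox, tumor(histo) %d vox\n",
              d[1], d[2], d[3], sum(x$gland_mask), sum(x$tumor_mask_rad),
              sum(x$tumor_mask_histo)))
  invisible(x)
}

# ---- spatial resampling primitives ------------------------------------------

# Sample a 3-D array at fractional voxel coordinates (1-based, matrix n x 3).
# mode "linear": trilinear interpolation; "nearest": nearest neighbour.
# Out-of-grid coordinates return `fill`.
sample_at <- function(arr, coords, mode = c("linear", "nearest"), fill = 0) {
  mode <- match.arg(mode)
  d <- dim(arr)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  if (mode == "nearest") {
    xi <- round(x); yi <- round(y); zi <- round(z)
    ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
    out <- rep(fill, nrow(coords))
    idx <- (zi[ok] - 1) * d[1] * d[2] + (yi[ok] - 1) * d[1] + xi[ok]
    out[ok] <- arr[idx]
    return(out)
  }
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  out <- numeric(nrow(coords))
  for (dxi in 0:1) for (dyi in 0:1) for (dzi in 0:1) {
    w <- (if (dxi) fx else 1 - fx) * (if (dyi) fy else 1 - fy) *
      (if (dzi) fz else 1 - fz)
    xi <- x0 + dxi; yi <- y0 + dyi; zi <- z0 + dzi
    ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
    v <- rep(fill, nrow(coords))
    idx <- (zi[ok] - 1) * d[1] * d[2] + (yi[ok] - 1) * d[1] + xi[ok]
    v[ok] <- arr[idx]
    out <- out + w * v
  }
  out
}

# Regular grid of 1-based voxel coordinates for an output grid of shape
# `out_dim` whose voxel size relative to the source grid is `scale` (length 3):
# source_coord = (out_index - 0.5) * scale + 0.5 (voxel-center alignment).
grid_coords <- function(out_dim, scale) {
  cx <- (seq_len(out_dim[1]) - 0.5) * scale[1] + 0.5
  cy <- (seq_len(out_dim[2]) - 0.5) * scale[2] + 0.5
  cz <- (seq_len(out_dim[3]) - 0.5) * scale[3] + 0.5
  cbind(rep(cx, times = out_dim[2] * out_dim[3]),
        rep(rep(cy, each = out_dim[1]), times = out_dim[3]),
        rep(cz, each = out_dim[1] * out_dim[2]))
}

# Resample a 3-D array onto a grid with a different shape, voxel centers
# aligned. Used for spacing changes and heat-map upsampling.
resample_array <- function(arr, out_dim, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  d <- dim(arr)
  if (identical(as.integer(out_dim), as.integer(d))) return(arr)
  scale <- d / out_dim
  vals <- sample_at(arr, grid_coords(out_dim, scale), mode = mode)
  array(vals, out_dim)
}

# Separable Gaussian smoothing with zero-padded, border-renormalized window.
gaussian_smooth3d <- function(arr, sigma, radius = NULL) {
  if (all(sigma <= 0)) return(arr)
  sigma <- rep(sigma, length.out = 3)
  out <- arr
  wsum <- array(1, dim(arr))
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    r <- radius %||% max(1L, as.integer(round(3 * sigma[ax])))
    k <- exp(-((-r:r)^2) / (2 * sigma[ax]^2))
    k <- k / sum(k)
    out <- conv_axis(out, k, ax)
    wsum <- conv_axis(wsum, k, ax)
  }
  out / wsum
}

# 1-D convolution of a 3-D array along axis `ax` with zero padding.
conv_axis <- function(arr, k, ax) {
  d <- dim(arr)
  r <- (length(k) - 1L) / 2L
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  n <- da[1]
  res <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    res[ok, ] <- res[ok, ] + k[j] * m[src[ok], ]
  }
  a <- array(res, da)
  aperm(a, order(perm))
}
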