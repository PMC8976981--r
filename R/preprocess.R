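#' Patch sampling specification
#'
#' Controls class-balanced patch extraction and rotation augmentation for
#' patch-based training. The defaults follow the standard protocol for this
#' task: 64 x 64 x 16 patches, the patch center drawn from each class
#' (background / gland / tumor) with probability 1/3 to counter class
#' imbalance, and a 70% chance of a random 2-D rotation in the axial plane.
#'
#' @param patch_size voxel triple, each dimension divisible by 8.
#' @param class_center_probs probability that the patch center voxel belongs
#'   to class 0, 1, 2; must sum to 1. Classes absent from a volume are
#'   renormalized away at sampling time.
#' @param rotation_prob probability that [augment_rotation] rotates a patch.
#' @param seed integer seed used by the training loop's sampling stream.
#' @return An object of class `patch_spec`.
#' @export
patch_spec <- function(patch_size = c(64, 64, 16),
                       class_center_probs = c(1, 1, 1) / 3,
                       rotation_prob = 0.70,
                       seed = 1L) {
  assert_that(is_int_triple(patch_size) && all(patch_size %% 8 == 0),
              "patch_size dimensions must be positive and divisible by 8")
  assert_that(length(class_center_probs) == 3L && all(class_center_probs >= 0) &&
                abs(sum(class_center_probs) - 1) < 1e-8,
              "class_center_probs must be 3 non-negative values summing to 1")
  assert_that(rotation_prob >= 0 && rotation_prob <= 1,
              "rotation_prob must be in [0, 1]")
  structure(list(patch_size = as.integer(patch_size),
                 class_center_probs = as.numeric(class_center_probs),
                 rotation_prob = as.numeric(rotation_prob),
                 seed = as.integer(seed)),
            class = "patch_spec")
}

#' Crop image and labels to the gland region of interest
#'
#' Restricts the field of view to the bounding box of the gland mask dilated
#' by `margin` (mm, converted to voxels by ceiling) and clipped to the grid.
#' Image and labels are cropped by the identical box; spacing is preserved.
#'
#' @param image a [multichannel_volume].
#' @param labels a [label_volume] with a non-empty gland mask.
#' @param margin margin in mm added on every side of the gland bounding box.
#' @return A list with cropped `image` and `labels`.
#' @export
crop_to_roi <- function(image, labels, margin = 0) {
  assert_that(inherits(image, "multichannel_volume") &&
                inherits(labels, "label_volume"), "need image + labels")
  assert_that(any(labels$gland_mask), "gland mask is empty; nothing to crop to")
  assert_that(margin >= 0, "margin must be >= 0")
  d <- dim(labels)
  idx <- which(labels$gland_mask, arr.ind = TRUE)
  mv <- ceiling(margin / image$spacing)
  lo <- pmax(apply(idx, 2, min) - mv, 1)
  hi <- pmin(apply(idx, 2, max) + mv, d)
  sub <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  img <- multichannel_volume(lapply(image$channels, sub), image$spacing,
                             origin = image$origin + (lo - 1) * image$spacing)
  lab <- label_volume(sub(labels$class_map), sub(labels$gland_mask),
                      sub(labels$tumor_mask_rad), sub(labels$tumor_mask_histo),
                      spacing = labels$spacing)
  list(image = img, labels = lab)
}

#' Resample image and labels to a target voxel spacing
#'
#' The image channels are interpolated trilinearly and the label volumes with
#' nearest-neighbour interpolation so label values stay closed under
#' resampling. The output grid shape is `ceiling(extent / target_spacing)`.
#' The default target is the standard 0.78 x 0.78 x 3 mm protocol spacing.
#'
#' @param image a [multichannel_volume].
#' @param labels a [label_volume] on the same grid.
#' @param target_spacing mm triple.
#' @return A list with resampled `image` and `labels`.
#' @export
resample <- function(image, labels, target_spacing = c(0.78, 0.78, 3)) {
  assert_that(all(target_spacing > 0), "target_spacing must be positive")
  d <- dim(image)
  out_dim <- as.integer(ceiling(d * image$spacing / target_spacing))
  img <- multichannel_volume(
    lapply(image$channels, resample_array, out_dim = out_dim, mode = "linear"),
    spacing = target_spacing, origin = image$origin)
  rs_mask <- function(m) {
    array(resample_array(m * 1L, out_dim, mode = "nearest") > 0.5, out_dim)
  }
  cm <- array(as.integer(round(resample_array(labels$class_map, out_dim,
                                              mode = "nearest"))), out_dim)
  lab <- label_volume(cm, rs_mask(labels$gland_mask),
                      rs_mask(labels$tumor_mask_rad),
                      rs_mask(labels$tumor_mask_histo),
                      spacing = target_spacing)
  list(image = img, labels = lab)
}

# Extract a zero-padded sub-array of `size` centered at voxel `center`
# from an (X,Y,Z) or (X,Y,Z,C) array.
extract_patch_array <- function(arr, center, size, fill = 0) {
  d <- dim(arr)
  has_c <- length(d) == 4L
  dc <- d[1:3]
  lo <- center - floor((size - 1) / 2)
  hi <- lo + size - 1
  src_lo <- pmax(lo, 1); src_hi <- pmin(hi, dc)
  dst_lo <- src_lo - lo + 1; dst_hi <- dst_lo + (src_hi - src_lo)
  out <- array(fill, c(size, if (has_c) d[4] else NULL))
  if (all(src_lo <= src_hi)) {
    if (has_c) {
      out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3], ] <-
        arr[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3], ,
            drop = FALSE]
    } else {
      out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
        arr[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3],
            drop = FALSE]
    }
  }
  out
}

#' Draw a class-balanced training patch
#'
#' First draws the class of the patch center voxel from
#' `spec$class_center_probs` (renormalized over the classes actually present
#' in the volume), then picks a uniformly random voxel of that class as the
#' patch center. The patch is extracted with zero padding where it extends
#' past the grid, so the returned shapes always equal `spec$patch_size`.
#'
#' Randomness is taken from the current RNG stream; seed the stream (e.g.
#' via `set.seed`) for reproducible draws.
#'
#' @param image a [multichannel_volume].
#' @param labels a [label_volume] on the same grid.
#' @param spec a [patch_spec].
#' @return An object of class `patch` with `image` (X,Y,Z,C array), `labels`
#'   (integer array), `center_voxel` and `center_class`.
#' @export
sample_patch <- function(image, labels, spec) {
  assert_that(inherits(spec, "patch_spec"), "spec must be a patch_spec")
  cm <- labels$class_map
  probs <- spec$class_center_probs
  present <- vapply(0:2, function(k) any(cm == k), TRUE)
  usable <- probs > 0 & present
  if (!any(usable)) {
    stop_sx("no voxel of any class with positive center probability is present")
  }
  p <- probs * present
  p <- p / sum(p)
  cls <- sample(0:2, 1L, prob = p)
  vox <- which(cm == cls)
  center_lin <- if (length(vox) == 1L) vox else vox[sample.int(length(vox), 1L)]
  center <- as.integer(arrayInd(center_lin, dim(cm)))
  img_arr <- extract_patch_array(as_chan_array(image), center, spec$patch_size)
  lab_arr <- array(as.integer(extract_patch_array(cm, center, spec$patch_size)),
                   spec$patch_size)
  structure(list(image = img_arr, labels = lab_arr, center_voxel = center,
                 center_class = cls, channel_names = names(image$channels),
                 spacing = image$spacing, rotation = NULL),
            class = "patch")
}

#' @export
print.patch <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("patch %dx%dx%d, center class %d at voxel (%s)%s\n",
              d[1], d[2], d[3], x$center_class,
              paste(x$center_voxel, collapse = ", "),
              if (is.null(x$rotation)) "" else
                sprintf(", rotated %.1f deg", x$rotation * 180 / pi)))
  invisible(x)
}

# Rotate an (X,Y,Z) or (X,Y,Z,C) array by `theta` in the axial (x-y) plane
# about the patch center; bilinear for images, nearest for labels.
rotate_axial <- function(arr, theta, mode) {
  d <- dim(arr)
  has_c <- length(d) == 4L
  dc <- d[1:3]
  cx <- (dc[1] + 1) / 2; cy <- (dc[2] + 1) / 2
  g <- grid_coords(dc, c(1, 1, 1))
  dx <- g[, 1] - cx; dy <- g[, 2] - cy
  src <- cbind(cos(theta) * dx + sin(theta) * dy + cx,
               -sin(theta) * dx + cos(theta) * dy + cy, g[, 3])
  if (has_c) {
    out <- array(0, d)
    for (k in seq_len(d[4])) {
      out[, , , k] <- array(sample_at(arr[, , , k, drop = TRUE], src,
                                      mode = mode), dc)
    }
    out
  } else {
    array(sample_at(arr, src, mode = mode), dc)
  }
}

#' Random axial rotation augmentation
#'
#' With probability `spec$rotation_prob` the patch's image and labels are
#' rotated by one uniformly drawn angle in [0, 360) degrees in the axial
#' plane (image channels trilinear, labels nearest-neighbour, identical
#' spatial map for both); otherwise the patch is returned unchanged. The
#' applied angle (radians) is recorded in the `rotation` field, `NULL` when
#' no rotation was applied.
#'
#' @param patch a [patch][sample_patch].
#' @param spec a [patch_spec].
#' @return The (possibly rotated) patch.
#' @export
augment_rotation <- function(patch, spec) {
  assert_that(inherits(patch, "patch") && inherits(spec, "patch_spec"),
              "need a patch and a patch_spec")
  if (stats::runif(1) >= spec$rotation_prob) return(patch)
  theta <- stats::runif(1, 0, 2 * pi)
  patch$image <- rotate_axial(patch$image, theta, "linear")
  patch$labels <- array(as.integer(round(rotate_axial(patch$labels, theta,
                                                      "nearest"))),
                        dim(patch$labels))
  patch$rotation <- theta
  patch
}
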