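#' Dice-Sorensen coefficient
#'
#' `2|A n B| / (|A| + |B|)` for two binary masks of the same shape. Two empty
#' masks score 1: correctly predicting the absence of a structure counts as
#' perfect agreement.
#'
#' @param mask_a,mask_b logical (or 0/1) arrays of identical shape.
#' @return A value in `[0, 1]`.
#' @examples
#' a <- array(c(rep(TRUE, 4), rep(FALSE, 4)), c(2, 2, 2))
#' dice(a, a)  # 1
#' @export
dice <- function(mask_a, mask_b) {
  assert_that(identical(dim(mask_a), dim(mask_b)),
              "mask shapes differ: %s vs %s",
              paste(dim(mask_a), collapse = "x"),
              paste(dim(mask_b), collapse = "x"))
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Threshold a normalized heat map
#'
#' Binarizes a min-max-normalized heat map at delta using a strict `>`:
#' at delta = 0 this selects the support of the (ReLU, hence non-negative)
#' heat map rather than the entire volume, and delta = 1 gives an empty mask.
#'
#' @param normalized_heat_map array with values in `[0, 1]`.
#' @param delta threshold in `[0, 1]`.
#' @return Logical array `L^c(delta)`.
#' @export
threshold_heatmap <- function(normalized_heat_map, delta) {
  assert_that(is.numeric(delta) && length(delta) == 1L &&
                delta >= 0 && delta <= 1, "delta must be in [0, 1]")
  assert_that(min(normalized_heat_map) >= 0 && max(normalized_heat_map) <= 1,
              "heat map must be min-max normalized to [0, 1]")
  normalized_heat_map > delta
}

#' Localization IOU of a thresholded heat map
#'
#' Intersection-over-union between the binarized heat map `L^c(delta)` and a
#' class ground-truth mask: `|L n gt| / |L u gt|`. An empty union scores 0
#' (conservative guard of the 0/0 case).
#'
#' @param normalized_heat_map array in `[0, 1]`, same shape as `gt_mask`
#'   (upsample the heat map first if needed).
#' @param gt_mask logical ground-truth mask.
#' @param delta threshold in `[0, 1]`.
#' @return An object of class `localization_result` with fields `delta`,
#'   `binary_map`, `gt_mask` and `iou`.
#' @export
localization_iou <- function(normalized_heat_map, gt_mask, delta) {
  assert_that(identical(dim(normalized_heat_map), dim(gt_mask)),
              "heat map shape %s does not match ground truth shape %s",
              paste(dim(normalized_heat_map), collapse = "x"),
              paste(dim(gt_mask), collapse = "x"))
  L <- threshold_heatmap(normalized_heat_map, delta)
  gt <- as.logical(gt_mask)
  uni <- sum(L | gt)
  iou <- if (uni == 0) 0 else sum(L & gt) / uni
  structure(list(delta = delta, binary_map = L, gt_mask = gt, iou = iou),
            class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf("Loc(delta=%.2f) = %.4f  (|L|=%d, |gt|=%d)\n", x$delta, x$iou,
              sum(x$binary_map), sum(x$gt_mask)))
  invisible(x)
}

#' Localization IOU over a threshold grid
#'
#' Applies [localization_iou] at each delta; the default grid
#' `c(0, 0.25, 0.5)` matches the standard reporting protocol for
#' class-conditional heat-map localization.
#'
#' @inheritParams localization_iou
#' @param deltas numeric vector of thresholds.
#' @return A data.frame with columns `delta` and `iou`.
#' @export
localization_curve <- function(normalized_heat_map, gt_mask,
                               deltas = c(0, 0.25, 0.5)) {
  data.frame(delta = deltas,
             iou = vapply(deltas, function(d) {
               localization_iou(normalized_heat_map, gt_mask, d)$iou
             }, 0))
}

#' Evaluate a predicted segmentation (and optional heat maps) on one case
#'
#' Computes per-class Dice against both ground truths: the gland score uses
#' the full gland mask (tumor included) against predicted classes {1, 2},
#' since a whole-gland contour contains the tumor; the tumor score uses
#' predicted class 2 against the radiologist-style and the histology-style
#' tumor masks. When normalized heat maps are supplied (named list, e.g.
#' `list(tumor = ..., gland = ...)` with entries matching grid shape),
#' localization IOUs are added for each delta.
#'
#' @param class_map predicted integer class map.
#' @param labels a [label_volume] ground truth.
#' @param heatmaps optional named list of min-max-normalized heat maps.
#' @param heatmap_gt named list mapping heat-map names to ground-truth masks;
#'   defaults to `tumor -> tumor_mask_rad`, `gland -> gland_mask`.
#' @param deltas thresholds for [localization_curve].
#' @return A one-row data.frame of metrics.
#' @export
evaluate_case <- function(class_map, labels, heatmaps = NULL,
                          heatmap_gt = NULL, deltas = c(0, 0.25, 0.5)) {
  assert_that(inherits(labels, "label_volume"), "labels must be a label_volume")
  row <- data.frame(
    dsc_gland = dice(class_map >= 1L, labels$gland_mask),
    dsc_tumor_rad = dice(class_map == 2L, labels$tumor_mask_rad),
    dsc_tumor_histo = dice(class_map == 2L, labels$tumor_mask_histo))
  if (!is.null(heatmaps)) {
    default_gt <- list(tumor = labels$tumor_mask_rad,
                       gland = labels$gland_mask)
    for (nm in names(heatmaps)) {
      gt <- (heatmap_gt %||% default_gt)[[nm]]
      assert_that(!is.null(gt), "no ground-truth mask for heat map '%s'", nm)
      cv <- localization_curve(heatmaps[[nm]], gt, deltas)
      for (i in seq_len(nrow(cv))) {
        row[[sprintf("loc_%s_d%g", nm, cv$delta[i])]] <- cv$iou[i]
      }
    }
  }
  row
}

#' Aggregate a per-case evaluation table
#'
#' @param report data.frame of per-case rows (e.g. rbind of [evaluate_case]).
#' @return data.frame with one row per metric: mean, sd, median.
#' @export
aggregate_report <- function(report) {
  num <- report[vapply(report, is.numeric, TRUE)]
  data.frame(metric = names(num),
             mean = vapply(num, mean, 0),
             sd = vapply(num, stats::sd, 0),
             median = vapply(num, stats::median, 0),
             row.names = NULL)
}
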