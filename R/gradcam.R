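#' Grad-CAM configuration for segmentation networks
#'
#' For a segmentation network the class score is not a single scalar, so the
#' pre-softmax class scores are averaged over a voxel set (the score mask) to
#' obtain the scalar whose gradients are taken. The default score mask is the
#' network's own predicted mask for the target class, so that an explanation
#' does not presuppose ground truth; a ground-truth mode is provided for
#' evaluation studies, plus whole-volume and custom-mask modes.
#'
#' @param target_class class id (0 background, 1 gland, 2 tumor; default 2).
#' @param target_block block whose post-activation feature maps are used;
#'   default `"D3"`, the last decoder convolution block (the last
#'   convolutional layer before the head).
#' @param score_mask_mode one of `"predicted"`, `"ground-truth"`,
#'   `"whole-volume"`, `"custom"`.
#' @param mask logical array (input grid) for `"custom"` mode.
#' @param upsample trilinearly interpolate the heat map to the input grid
#'   (a no-op when the target block is already at input resolution).
#' @return An object of class `gradcam_config`.
#' @export
gradcam_config <- function(target_class = 2L, target_block = "D3",
                           score_mask_mode = c("predicted", "ground-truth",
                                               "whole-volume", "custom"),
                           mask = NULL, upsample = TRUE) {
  score_mask_mode <- match.arg(score_mask_mode)
  assert_that(target_class >= 0, "target_class must be a class id >= 0")
  if (score_mask_mode == "custom") {
    assert_that(is.logical(mask), "custom mode needs a logical mask")
  }
  structure(list(target_class = as.integer(target_class),
                 target_block = target_block,
                 score_mask_mode = score_mask_mode, mask = mask,
                 upsample = isTRUE(upsample)),
            class = "gradcam_config")
}

#' Mask-averaged pre-softmax class score
#'
#' The scalar whose gradients drive segmentation Grad-CAM: the arithmetic
#' mean of the pre-softmax score of class `class_id` over the voxel set
#' `mask`.
#'
#' @param class_scores (X,Y,Z,C) array of pre-softmax scores.
#' @param mask logical (X,Y,Z) array, non-empty.
#' @param class_id class id (0-based).
#' @return A single number.
#' @export
mask_averaged_score <- function(class_scores, mask, class_id) {
  d <- dim(class_scores)
  assert_that(length(d) == 4L && class_id < d[4],
              "class_scores must be (X,Y,Z,C) with class_id < C")
  assert_that(is.logical(mask) && identical(dim(mask), d[1:3]),
              "mask must be logical with the score grid shape")
  if (!any(mask)) {
    stop_sx("score mask is empty; fall back to score_mask_mode = 'whole-volume'")
  }
  mean(class_scores[, , , class_id + 1L][mask])
}

min_max_normalize <- function(h) {
  r <- range(h)
  if (r[2] > r[1]) (h - r[1]) / (r[2] - r[1]) else array(0, dim(h))
}

resolve_score_mask <- function(cfg, class_map, gt_labels, grid) {
  m <- switch(cfg$score_mask_mode,
    "predicted" = class_map == cfg$target_class,
    "ground-truth" = {
      assert_that(!is.null(gt_labels),
                  "ground-truth mask mode needs gt_labels (a label_volume)")
      switch(as.character(cfg$target_class),
             "0" = gt_labels$class_map == 0L,
             "1" = gt_labels$gland_mask,
             "2" = gt_labels$tumor_mask_rad,
             gt_labels$class_map == cfg$target_class)
    },
    "whole-volume" = array(TRUE, grid),
    "custom" = cfg$mask)
  assert_that(identical(dim(m), grid),
              "score mask shape does not match the image grid")
  if (!any(m)) {
    stop_sx("score mask for class %d is empty; fall back to score_mask_mode = 'whole-volume'",
            cfg$target_class)
  }
  m
}

#' Compute a segmentation Grad-CAM heat map
#'
#' Runs an inference-mode forward pass, averages the pre-softmax score of the
#' target class over the score mask, backpropagates that scalar to the target
#' block's post-activation feature maps \eqn{A^k} to obtain the gradients
#' \eqn{G^{c,k}}, global-average-pools them over all N feature-grid voxels
#' into kernel weights \eqn{\omega^{c,k}}, and forms the heat map
#' \eqn{H^c = \mathrm{ReLU}(\sum_k \omega^{c,k} A^k)}, optionally upsampled
#' trilinearly to the input grid and min-max normalized. Gradients are pooled
#' raw (no rectification before pooling), i.e. plain Grad-CAM.
#'
#' @param net a `conv_net3d` network (trained or deliberately random).
#' @param image a [multichannel_volume] (for `unet3d`) or an (X,Y,Z,C) array
#'   (for [conv_chain] networks).
#' @param cfg a [gradcam_config].
#' @param gt_labels a [label_volume], required for
#'   `score_mask_mode = "ground-truth"`.
#' @return An object of class `gradcam_result`: `feature_maps` (A^k),
#'   `gradients` (G^{c,k}), `weights` (omega, one per kernel), `heat_map`
#'   (non-negative, input grid if upsampled), `normalized_heat_map` in [0,1],
#'   `N` (feature-grid voxel count), `score` (the mask-averaged class score)
#'   and `mask`.
#' @export
compute_gradcam <- function(net, image, cfg = gradcam_config(),
                            gt_labels = NULL) {
  assert_that(inherits(net, "conv_net3d"), "net must be a conv_net3d")
  assert_that(inherits(cfg, "gradcam_config"), "cfg must be a gradcam_config")
  if (!cfg$target_block %in% names(net$block_out)) {
    stop_sx("unknown target block '%s' (available: %s)", cfg$target_block,
            paste(names(net$block_out), collapse = ", "))
  }
  node_id <- net$block_out[[cfg$target_block]]
  if (inherits(image, "multichannel_volume")) {
    pf <- predict_forward(net, image)
  } else {
    assert_that(is.array(image) && length(dim(image)) == 4L,
                "image must be a multichannel_volume or an (X,Y,Z,C) array")
    fw <- net_forward(net, image, train = FALSE)
    pf <- list(fw = fw, x = image, orig = dim(image)[1:3],
               padded = dim(image)[1:3])
  }
  scores_pad <- pf$fw$out$HEAD
  dpad <- dim(scores_pad)
  assert_that(cfg$target_class < dpad[4],
              "target_class %d out of range for %d classes",
              cfg$target_class, dpad[4])
  scores <- crop_to(scores_pad, pf$orig)
  class_map <- array(
    max.col(softmax_rows(matrix(scores, prod(pf$orig), dpad[4])),
            ties.method = "first") - 1L, pf$orig)
  mask <- resolve_score_mask(cfg, class_map, gt_labels, pf$orig)
  score <- mask_averaged_score(scores, mask, cfg$target_class)

  # seed gradient: d(mean score over mask)/d(score voxel) on the padded grid
  mask_pad <- array(FALSE, dpad[1:3])
  mask_pad[seq_len(pf$orig[1]), seq_len(pf$orig[2]), seq_len(pf$orig[3])] <- mask
  d_head <- array(0, dpad)
  sl <- array(0, dpad[1:3])
  sl[mask_pad] <- 1 / sum(mask)
  d_head[, , , cfg$target_class + 1L] <- sl

  bw <- net_backward(net, pf$fw, d_head, train = FALSE, need_pgrads = FALSE)
  A <- pf$fw$out[[node_id]]
  G <- bw$gout[[node_id]]
  if (is.null(G)) G <- array(0, dim(A))
  dA <- dim(A)
  N <- prod(dA[1:3])
  omega <- colMeans(matrix(G, N, dA[4]))
  h <- array(matrix(A, N, dA[4]) %*% omega, dA[1:3])
  h <- pmax(h, 0)
  heat <- h
  if (cfg$upsample && !all(dA[1:3] == dpad[1:3])) {
    heat <- resample_array(heat, dpad[1:3], mode = "linear")
    heat <- pmax(heat, 0)
  }
  if (!all(pf$orig == dpad[1:3]) && all(dim(heat) == dpad[1:3])) {
    heat <- heat[seq_len(pf$orig[1]), seq_len(pf$orig[2]),
                 seq_len(pf$orig[3]), drop = TRUE]
    heat <- array(heat, pf$orig)
  }
  structure(list(feature_maps = A, gradients = G, weights = omega,
                 heat_map = heat, heat_map_feature_grid = h,
                 normalized_heat_map = min_max_normalize(heat),
                 N = N, score = score, mask = mask,
                 target_class = cfg$target_class,
                 target_block = cfg$target_block),
            class = "gradcam_result")
}

#' @export
print.gradcam_result <- function(x, ...) {
  cat(sprintf("gradcam_result: class %d @ block %s | K=%d kernels, N=%d voxels | score %.4g | heat max %.4g\n",
              x$target_class, x$target_block, length(x$weights), x$N,
              x$score, max(x$heat_map)))
  invisible(x)
}
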