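#' Randomize one network block
#'
#' Returns a copy of the network in which the convolution (and transposed
#' convolution) weights of the named block are re-drawn from the
#' initialization distribution, biases are zeroed, batch-norm affine
#' parameters are re-initialized (gamma 1, beta 0) and batch-norm running
#' statistics are reset to identity — i.e. the block is returned to its
#' untrained state. All other blocks are untouched.
#'
#' @param net a `conv_net3d`.
#' @param block_id block name (e.g. `"BL"`, `"D1"`, `"E3"`, `"HEAD"`).
#' @param seed integer seed; the same seed reproduces identical randomized
#'   weights.
#' @return The modified network, flagged as untrained.
#' @export
randomize_block <- function(net, block_id, seed = 1L) {
  assert_that(inherits(net, "conv_net3d"), "net must be a conv_net3d")
  ids <- net$blocks[[block_id]]
  if (is.null(ids)) {
    stop_sx("unknown block '%s' (available: %s)", block_id,
            paste(names(net$blocks), collapse = ", "))
  }
  with_seed(seed, {
    for (id in ids) {
      net$params[[id]] <- init_node_params(net$nodes[[id]])
    }
  })
  net$trained <- FALSE
  net
}

#' Normalized mutual information of two heat maps
#'
#' Symmetric normalized MI, `2 I(A;B) / (H(A) + H(B))`, estimated from a
#' joint histogram with `n_bins` bins per axis over `[0, 1]`. Identical
#' non-constant maps score 1; if either map is constant (zero entropy) the
#' score is 0 by convention.
#'
#' @param map_a,map_b arrays of identical shape with values in `[0, 1]`
#'   (min-max normalize first).
#' @param n_bins histogram bins per axis (default 64).
#' @return A value in `[0, 1]`.
#' @export
mutual_information <- function(map_a, map_b, n_bins = 64L) {
  assert_that(identical(dim(map_a), dim(map_b)),
              "map shapes differ: %s vs %s",
              paste(dim(map_a), collapse = "x"),
              paste(dim(map_b), collapse = "x"))
  assert_that(min(map_a) >= 0 && max(map_a) <= 1 &&
                min(map_b) >= 0 && max(map_b) <= 1,
              "maps must be min-max normalized to [0, 1]")
  ia <- pmin(floor(as.numeric(map_a) * n_bins) + 1L, n_bins)
  ib <- pmin(floor(as.numeric(map_b) * n_bins) + 1L, n_bins)
  joint <- tabulate((ib - 1L) * n_bins + ia, n_bins * n_bins) / length(ia)
  pj <- matrix(joint, n_bins, n_bins)
  pa <- rowSums(pj)
  pb <- colSums(pj)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  ha <- ent(pa)
  hb <- ent(pb)
  if (ha == 0 || hb == 0) return(0)
  mi <- ent(pa) + ent(pb) - ent(joint)
  max(0, min(1, 2 * mi / (ha + hb)))
}

#' Structural similarity index for 3-D volumes
#'
#' Mean local SSIM over the volume with a separable 3-D Gaussian window
#' (sigma 1.5, radius `round(3.5 * sigma)`) and the standard stabilization
#' constants K1 = 0.01, K2 = 0.03. Local weighted means and (biased)
#' covariances are computed by normalized convolution, i.e. border windows
#' are renormalized over the in-grid support, so identical maps score
#' exactly 1.
#'
#' @param map_a,map_b arrays of identical shape; values are expected on a
#'   unit data range after min-max normalization.
#' @param sigma Gaussian window sigma in voxels.
#' @param K1,K2 stabilization constants.
#' @param data_range dynamic range of the data (1 after normalization).
#' @return A value in `[-1, 1]`.
#' @export
ssim3d <- function(map_a, map_b, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                   data_range = 1) {
  assert_that(identical(dim(map_a), dim(map_b)),
              "map shapes differ: %s vs %s",
              paste(dim(map_a), collapse = "x"),
              paste(dim(map_b), collapse = "x"))
  r <- max(1L, as.integer(round(3.5 * sigma)))
  win <- 2L * r + 1L
  if (any(dim(map_a) < win)) {
    stop_sx("volume %s is smaller than the %d-voxel SSIM window; reduce sigma",
            paste(dim(map_a), collapse = "x"), win)
  }
  g <- function(v) gaussian_smooth3d(v, sigma, radius = r)
  mu_a <- g(map_a)
  mu_b <- g(map_b)
  va <- g(map_a * map_a) - mu_a^2
  vb <- g(map_b * map_b) - mu_b^2
  cab <- g(map_a * map_b) - mu_a * mu_b
  c1 <- (K1 * data_range)^2
  c2 <- (K2 * data_range)^2
  s <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  mean(s)
}

# Heat maps for a list of cases from one network, with a fixed per-case score
# mask so that comparisons across randomization stages are not confounded by
# changes in the predicted mask.
heatmaps_for_cases <- function(net, cases, cfg, masks) {
  lapply(seq_along(cases), function(i) {
    cc <- cfg
    cc$score_mask_mode <- "custom"
    cc$mask <- masks[[i]]
    compute_gradcam(net, cases[[i]]$image, cc)$normalized_heat_map
  })
}

# Fixed score masks from the trained network's own predictions (falling back
# to the whole volume when the trained network predicts no voxel of the
# class).
trained_masks <- function(net, cases, cfg) {
  lapply(cases, function(cs) {
    pred <- predict.unet3d(net, cs$image)
    m <- pred$class_map == cfg$target_class
    if (!any(m)) m <- array(TRUE, dim(pred$class_map))
    m
  })
}

randomization_report <- function(rows) {
  df <- do.call(rbind, rows)
  structure(df, class = c("randomization_report", "data.frame"))
}

#' @export
summary.randomization_report <- function(object, ...) {
  df <- as.data.frame(object)
  by <- if ("stage" %in% names(df)) "stage" else NULL
  if (is.null(by)) {
    data.frame(mi_mean = mean(df$mi), mi_sd = stats::sd(df$mi),
               ssim_mean = mean(df$ssim), ssim_sd = stats::sd(df$ssim))
  } else {
    stages <- unique(df$stage)
    do.call(rbind, lapply(stages, function(s) {
      d <- df[df$stage == s, ]
      data.frame(stage = s, mi_mean = mean(d$mi), mi_sd = stats::sd(d$mi),
                 ssim_mean = mean(d$ssim), ssim_sd = stats::sd(d$ssim))
    }))
  }
}

#' Model randomization sanity check
#'
#' Compares heat maps from the trained network against heat maps from a fully
#' random network of the same architecture (fresh initialization), per case,
#' scored by normalized mutual information and SSIM. A faithful explanation
#' method must be sensitive to the learned weights, so trained-vs-random
#' scores should fall well below the self-comparison value of 1. The score
#' mask is fixed to the trained network's predicted mask for both networks.
#'
#' @param net a trained `unet3d`.
#' @param cases list of [phantom_case] objects.
#' @param cfg a [gradcam_config].
#' @param seed seed for the random network's initialization.
#' @return A `randomization_report` data.frame with one row per case
#'   (`case`, `mi`, `ssim`); see [summary.randomization_report].
#' @export
model_randomization_test <- function(net, cases, cfg = gradcam_config(),
                                     seed = 1L) {
  assert_that(inherits(net, "unet3d"), "net must be a unet3d")
  rand_net <- unet_build(net$spec, seed = derive_seed(seed, "model-rand"))
  masks <- trained_masks(net, cases, cfg)
  hm_t <- heatmaps_for_cases(net, cases, cfg, masks)
  hm_r <- heatmaps_for_cases(rand_net, cases, cfg, masks)
  randomization_report(lapply(seq_along(cases), function(i) {
    data.frame(case = i, mi = mutual_information(hm_t[[i]], hm_r[[i]]),
               ssim = ssim3d(hm_t[[i]], hm_r[[i]]))
  }))
}

#' Cascaded randomization sanity check
#'
#' Randomizes network blocks stage by stage, from the top of the decoder path
#' to the bottom of the encoder path by default, and tracks how the heat maps
#' degrade relative to the trained network. Stages: `TN` (trained network,
#' self-comparison), one stage per block in `block_order`, and `RN` (all
#' blocks random). In `"independent"` mode each stage randomizes exactly one
#' block of the trained network; in `"cumulative"` mode each stage randomizes
#' that block and all blocks of earlier stages.
#'
#' @param net a trained `unet3d`.
#' @param cases list of [phantom_case] objects.
#' @param cfg a [gradcam_config].
#' @param block_order block names, top to bottom.
#' @param mode `"independent"` (one block at a time) or `"cumulative"`.
#' @param seed randomization seed.
#' @return A `randomization_report` data.frame with columns `stage`, `case`,
#'   `mi`, `ssim`.
#' @export
cascaded_randomization_test <- function(net, cases, cfg = gradcam_config(),
                                        block_order = c("BL", "D1", "D2",
                                                        "D3", "E1", "E2",
                                                        "E3"),
                                        mode = c("independent", "cumulative"),
                                        seed = 1L) {
  mode <- match.arg(mode)
  assert_that(inherits(net, "unet3d"), "net must be a unet3d")
  unknown <- setdiff(block_order, names(net$blocks))
  assert_that(length(unknown) == 0, "unknown block(s): %s",
              paste(unknown, collapse = ", "))
  masks <- trained_masks(net, cases, cfg)
  hm_t <- heatmaps_for_cases(net, cases, cfg, masks)
  stage_nets <- list(TN = net)
  cur <- net
  for (k in seq_along(block_order)) {
    b <- block_order[k]
    sd_k <- derive_seed(seed, paste0("stage-", b))
    stage_nets[[b]] <- if (mode == "independent") {
      randomize_block(net, b, seed = sd_k)
    } else {
      cur <- randomize_block(cur, b, seed = sd_k)
      cur
    }
  }
  rn <- net
  for (b in names(net$blocks)) {
    rn <- randomize_block(rn, b, seed = derive_seed(seed, paste0("rn-", b)))
  }
  stage_nets[["RN"]] <- rn
  rows <- list()
  for (s in names(stage_nets)) {
    hm_s <- if (identical(s, "TN")) hm_t else {
      heatmaps_for_cases(stage_nets[[s]], cases, cfg, masks)
    }
    for (i in seq_along(cases)) {
      rows[[length(rows) + 1L]] <- data.frame(
        stage = s, case = i,
        mi = mutual_information(hm_t[[i]], hm_s[[i]]),
        ssim = ssim3d(hm_t[[i]], hm_s[[i]]))
    }
  }
  randomization_report(rows)
}
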