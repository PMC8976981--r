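#' Training configuration
#'
#' The learning rate default (0.001) and patch geometry follow the reported
#' optimum for this task; epoch count and patches per epoch default to
#' desk-scale values so that a full study runs in minutes on one CPU. The
#' full-scale setting (150 epochs) is available by configuration.
#'
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs.
#' @param patches_per_epoch patches drawn per epoch (one case picked
#'   uniformly per patch).
#' @param class_weights `"balanced"` (median-frequency weighting computed
#'   from the training labels, capped at 10) or a numeric vector of one
#'   weight per class for the weighted cross-entropy loss.
#' @param bn_momentum exponential-moving-average momentum for batch-norm
#'   running statistics.
#' @param seed seed for the patch-sampling / augmentation stream.
#' @param verbose print per-epoch losses.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 25L,
                         patches_per_epoch = 12L,
                         class_weights = "balanced", bn_momentum = 0.1,
                         seed = 1L, verbose = FALSE) {
  assert_that(learning_rate > 0 && epochs >= 0 && patches_per_epoch > 0 &&
                bn_momentum > 0 && bn_momentum <= 1,
              "training configuration values must be positive")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 patches_per_epoch = as.integer(patches_per_epoch),
                 class_weights = class_weights, bn_momentum = bn_momentum,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

# Per-channel z-score of a multichannel volume; returns (X,Y,Z,C) array.
normalize_image <- function(image) {
  arr <- as_chan_array(image)
  for (k in seq_len(dim(arr)[4])) {
    ch <- arr[, , , k]
    s <- stats::sd(ch)
    arr[, , , k] <- if (s > 0) (ch - mean(ch)) / s else ch - mean(ch)
  }
  arr
}

balanced_class_weights <- function(cases, n_classes, cap = 10) {
  counts <- numeric(n_classes)
  for (cs in cases) {
    counts <- counts + tabulate(cs$labels$class_map + 1L, n_classes)
  }
  freq <- counts / sum(counts)
  w <- ifelse(freq > 0, stats::median(freq[freq > 0]) / freq, 0)
  pmin(w, cap)
}

# Weighted softmax cross-entropy; returns loss and gradient wrt scores.
wce_loss <- function(scores, labels, w) {
  d <- dim(scores)
  V <- prod(d[1:3])
  s <- matrix(scores, V, d[4])
  p <- softmax_rows(s)
  y <- as.integer(labels) + 1L
  wv <- w[y]
  sw <- sum(wv)
  idx <- cbind(seq_len(V), y)
  loss <- -sum(wv * log(pmax(p[idx], 1e-12))) / sw
  dp <- p * wv / sw
  dp[idx] <- dp[idx] - wv / sw
  list(loss = loss, dscores = array(dp, d))
}

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    lapply(p[intersect(names(p), c("W", "b", "gamma", "beta"))],
           function(v) list(m = v * 0, v = v * 0))
  })
}

adam_step <- function(params, pgrads, state, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  for (id in names(pgrads)) {
    for (nm in names(pgrads[[id]])) {
      g <- pgrads[[id]][[nm]]
      if (is.null(g)) next
      st <- state[[id]][[nm]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g * g
      mhat <- st$m / (1 - b1^t)
      vhat <- st$v / (1 - b2^t)
      params[[id]][[nm]] <- params[[id]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[id]][[nm]] <- st
    }
  }
  list(params = params, state = state)
}

#' Train a 3-D U-Net on phantom cases
#'
#' Patch-based training: per iteration one case is drawn uniformly, a
#' class-balanced patch is sampled ([sample_patch]) and rotation-augmented
#' ([augment_rotation]), and one Adam step on the class-weighted
#' cross-entropy loss is taken (batch size 1; batch-norm statistics are
#' computed over the patch voxels). Input volumes are z-scored per channel
#' once before sampling; [predict.unet3d] applies the same normalization.
#'
#' @param net a [unet_build] network (or a previously trained one).
#' @param cases list of [phantom_case] objects (or lists with `image` and
#'   `labels`).
#' @param cfg a [train_config].
#' @param spec a [patch_spec] controlling sampling and augmentation.
#' @return The trained network, with `training_log` (data.frame of per-epoch
#'   mean loss) attached.
#' @export
unet_train <- function(net, cases, cfg = train_config(),
                       spec = patch_spec()) {
  assert_that(inherits(net, "unet3d"), "net must be a unet3d network")
  assert_that(inherits(cfg, "train_config"), "cfg must be a train_config")
  assert_that(length(cases) >= 1L, "need at least one training case")
  if (cfg$epochs == 0L) {
    net$training_log <- data.frame(epoch = integer(), loss = numeric())
    return(net)
  }
  w <- if (identical(cfg$class_weights, "balanced")) {
    balanced_class_weights(cases, net$spec$n_classes)
  } else {
    assert_that(is.numeric(cfg$class_weights) &&
                  length(cfg$class_weights) == net$spec$n_classes,
                "class_weights must be one weight per class")
    cfg$class_weights
  }
  imgs <- lapply(cases, function(cs) normalize_image(cs$image))
  # pre-normalized channel arrays wrapped back into volumes for sample_patch
  vols <- lapply(seq_along(cases), function(i) {
    chn <- names(cases[[i]]$image$channels)
    multichannel_volume(
      stats::setNames(lapply(seq_along(chn), function(k) imgs[[i]][, , , k]),
                      chn),
      spacing = cases[[i]]$image$spacing)
  })
  state <- adam_init(net$params)
  t_step <- 0L
  log <- data.frame(epoch = seq_len(cfg$epochs), loss = NA_real_)
  with_seed(derive_seed(cfg$seed, "train"), {
    for (ep in seq_len(cfg$epochs)) {
      losses <- numeric(cfg$patches_per_epoch)
      for (it in seq_len(cfg$patches_per_epoch)) {
        ci <- sample.int(length(cases), 1L)
        pt <- sample_patch(vols[[ci]], cases[[ci]]$labels, spec)
        pt <- augment_rotation(pt, spec)
        fw <- net_forward(net, pt$image, train = TRUE)
        scores <- fw$out$HEAD
        ls <- wce_loss(scores, pt$labels, w)
        if (!is.finite(ls$loss)) {
          stop_sx("loss became non-finite at epoch %d, iteration %d; lower the learning rate",
                  ep, it)
        }
        losses[it] <- ls$loss
        bw <- net_backward(net, fw, ls$dscores, train = TRUE)
        t_step <- t_step + 1L
        upd <- adam_step(net$params, bw$pgrads, state, cfg$learning_rate,
                         t_step)
        net$params <- upd$params
        state <- upd$state
        # batch-norm running statistics
        for (id in names(fw$caches)) {
          bu <- fw$caches[[id]]$bn_update
          if (is.null(bu)) next
          m <- cfg$bn_momentum
          net$params[[id]]$r_mean <- (1 - m) * net$params[[id]]$r_mean +
            m * bu$mean
          net$params[[id]]$r_var <- (1 - m) * net$params[[id]]$r_var +
            m * bu$var
        }
      }
      log$loss[ep] <- mean(losses)
      if (cfg$verbose) {
        message(sprintf("epoch %3d | loss %.4f", ep, log$loss[ep]))
      }
    }
  })
  net$trained <- TRUE
  net$training_log <- if (is.null(net$training_log)) log else
    rbind(net$training_log, log)
  net$class_weights <- w
  net
}

# Zero-pad (high side) spatial dims to multiples of 2^levels; returns padded
# array and the original dims.
pad_to_multiple <- function(arr, levels) {
  d <- dim(arr)
  mult <- 2^levels
  target <- as.integer(ceiling(d[1:3] / mult) * mult)
  if (all(target == d[1:3])) return(list(arr = arr, orig = d[1:3]))
  out <- array(0, c(target, d[4]))
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- arr
  list(arr = out, orig = d[1:3])
}

crop_to <- function(arr, orig) {
  arr[seq_len(orig[1]), seq_len(orig[2]), seq_len(orig[3]), , drop = FALSE]
}

# Shared forward used by predict and Grad-CAM: z-score, pad, inference-mode
# forward with full activation cache.
predict_forward <- function(net, image) {
  assert_that(inherits(image, "multichannel_volume"),
              "image must be a multichannel_volume")
  assert_that(length(image$channels) == net$spec$in_channels,
              "image has %d channels but the network expects %d",
              length(image$channels), net$spec$in_channels)
  x <- normalize_image(image)
  pad <- pad_to_multiple(x, net$spec$n_levels)
  fw <- net_forward(net, pad$arr, train = FALSE)
  list(fw = fw, x = pad$arr, orig = pad$orig, padded = dim(pad$arr)[1:3])
}

#' Predict a segmentation from a trained network
#'
#' Applies per-channel z-scoring, zero-pads the grid to a multiple of 8 if
#' needed, runs an inference-mode forward pass (batch-norm running
#' statistics, hence deterministic and batch-independent) and crops back.
#'
#' @param object a `unet3d` network.
#' @param image a [multichannel_volume].
#' @param ... unused.
#' @return An object of class `unet_prediction`: `class_map` (argmax labels,
#'   integer array), `scores` (pre-softmax class scores, X,Y,Z,C),
#'   `probs` (softmax), and `padded` (logical).
#' @export
predict.unet3d <- function(object, image, ...) {
  pf <- predict_forward(object, image)
  scores <- crop_to(pf$fw$out$HEAD, pf$orig)
  d <- dim(scores)
  p <- softmax_rows(matrix(scores, prod(d[1:3]), d[4]))
  labels <- max.col(p, ties.method = "first") - 1L
  structure(list(class_map = array(as.integer(labels), d[1:3]),
                 scores = scores, probs = array(p, d),
                 padded = !all(pf$orig == pf$padded)),
            class = "unet_prediction")
}

#' @export
print.unet_prediction <- function(x, ...) {
  tab <- table(factor(x$class_map, levels = 0:(dim(x$scores)[4] - 1)))
  cat("unet_prediction: voxels per class:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
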