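test_that("mask-averaged score is the arithmetic mean over the mask", {
  scores <- array(0, c(2, 2, 1, 2))
  scores[, , , 2] <- c(1, 2, 3, 6)
  mask <- array(TRUE, c(2, 2, 1))
  expect_identical(mask_averaged_score(scores, mask, 1L), 3)
  one <- array(FALSE, c(2, 2, 1))
  one[2, 1, 1] <- TRUE
  expect_identical(mask_averaged_score(scores, one, 1L), 2)
  const <- array(7, c(2, 2, 1, 2))
  expect_identical(mask_averaged_score(const, mask, 0L), 7)
  expect_error(mask_averaged_score(scores, one & FALSE, 1L), "whole-volume")
})

test_that("reverse-mode gradients match central finite differences", {
  set.seed(42)
  net <- conv_chain(in_channels = 2, hidden = 4, n_classes = 2, bn = TRUE,
                    seed = 3)
  expect_lte(n_parameters(net), 1000)
  x <- array(stats::rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2))
  mask <- array(stats::runif(6 * 6 * 4) > 0.5, c(6, 6, 4))
  cls <- 1L
  fscore <- function(over = NULL) {
    fw <- net_forward(net, x, override = over)
    mask_averaged_score(fw$out$HEAD, mask, cls)
  }
  res <- compute_gradcam(net, x,
                         gradcam_config(target_class = cls,
                                        target_block = "C1",
                                        score_mask_mode = "custom",
                                        mask = mask))
  A <- res$feature_maps
  G <- res$gradients
  eps <- 1e-5
  idx <- sample(length(A), 50)
  fd <- vapply(idx, function(i) {
    Ap <- A; Ap[i] <- A[i] + eps
    Am <- A; Am[i] <- A[i] - eps
    (fscore(list(C1 = Ap)) - fscore(list(C1 = Am))) / (2 * eps)
  }, 0)
  nz <- abs(fd) > 1e-10
  expect_gt(sum(nz), 10)
  expect_lt(max(abs(fd[nz] - G[idx][nz]) / abs(fd[nz])), 1e-6)
})

test_that("kernel weights equal the voxel mean of the gradients", {
  net <- conv_chain(in_channels = 2, hidden = 3, n_classes = 2, seed = 5)
  set.seed(6)
  x <- array(stats::rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  res <- compute_gradcam(net, x,
                         gradcam_config(target_class = 0, target_block = "C1",
                                        score_mask_mode = "whole-volume"))
  G <- res$gradients
  brute <- vapply(seq_len(dim(G)[4]),
                  function(k) sum(G[, , , k]) / prod(dim(G)[1:3]), 0)
  expect_equal(res$weights, brute, tolerance = 1e-14)
  expect_identical(res$N, prod(dim(G)[1:3]))
})

test_that("heat maps are non-negative and min-max normalized", {
  for (seed in 1:3) {
    net <- conv_chain(in_channels = 2, hidden = 4, n_classes = 2, bn = TRUE,
                      seed = seed)
    set.seed(seed)
    x <- array(stats::rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2))
    res <- compute_gradcam(net, x,
                           gradcam_config(target_class = 1,
                                          target_block = "C1",
                                          score_mask_mode = "whole-volume"))
    expect_gte(min(res$heat_map), 0)
    nh <- res$normalized_heat_map
    if (max(res$heat_map) > min(res$heat_map)) {
      expect_identical(range(nh), c(0, 1))
    } else {
      expect_true(all(nh == 0))
    }
  }
})

test_that("zero final-layer weights give an identically zero heat map", {
  net <- conv_chain(in_channels = 2, hidden = 4, n_classes = 2, seed = 7)
  net$params$HEAD$W[] <- 0
  net$params$HEAD$b[] <- 0
  set.seed(8)
  x <- array(stats::rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  res <- compute_gradcam(net, x,
                         gradcam_config(target_class = 1, target_block = "C1",
                                        score_mask_mode = "whole-volume"))
  expect_true(all(res$gradients == 0))
  expect_true(all(res$heat_map == 0))
})

test_that("pre-ReLU map scales linearly with the gradients", {
  # scaling the head weights by a > 0 scales G, omega and hence H by a
  net <- conv_chain(in_channels = 2, hidden = 4, n_classes = 2, seed = 9)
  set.seed(10)
  x <- array(stats::rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  cfg <- gradcam_config(target_class = 0, target_block = "C1",
                        score_mask_mode = "whole-volume")
  r1 <- compute_gradcam(net, x, cfg)
  net2 <- net
  net2$params$HEAD$W <- 2 * net$params$HEAD$W
  r2 <- compute_gradcam(net2, x, cfg)
  expect_equal(r2$gradients, 2 * r1$gradients, tolerance = 1e-12)
  expect_equal(r2$heat_map, 2 * r1$heat_map, tolerance = 1e-12)
})

test_that("a one-voxel grid reduces to classification Grad-CAM", {
  # with a linear 1x1x1 head, d(score_c)/dA_k is exactly the head weight, so
  # the heat map has the closed form ReLU(sum_k W[k,c] A_k): an independent
  # oracle for the degenerate single-voxel, whole-volume case
  net <- conv_chain(in_channels = 3, hidden = 5, n_classes = 2, seed = 11)
  set.seed(12)
  x <- array(stats::rnorm(3), c(1, 1, 1, 3))
  cfg <- gradcam_config(target_class = 1, target_block = "C1",
                        score_mask_mode = "whole-volume")
  res <- compute_gradcam(net, x, cfg)
  A <- res$feature_maps
  w_head <- net$params$HEAD$W[, 2]
  oracle <- max(0, sum(w_head * A))
  expect_equal(as.numeric(res$heat_map), oracle, tolerance = 1e-12)
  expect_equal(as.numeric(res$gradients), w_head, tolerance = 1e-12)
})

test_that("score-mask modes resolve and validate correctly", {
  net <- tiny_trained_net()
  case <- tiny_test_case(604)
  pred <- compute_gradcam(net, case$image,
                          gradcam_config(target_class = 1,
                                         score_mask_mode = "predicted"))
  expect_s3_class(pred, "gradcam_result")
  gt <- compute_gradcam(net, case$image,
                        gradcam_config(target_class = 2,
                                       score_mask_mode = "ground-truth"),
                        gt_labels = case$labels)
  expect_identical(gt$mask, case$labels$tumor_mask_rad)
  expect_error(compute_gradcam(net, case$image,
                               gradcam_config(target_class = 2,
                                              score_mask_mode = "ground-truth")),
               "gt_labels")
  expect_error(compute_gradcam(net, case$image,
                               gradcam_config(target_block = "nope")),
               "unknown target block")
  # bottleneck heat maps are upsampled to the image grid
  bl <- compute_gradcam(net, case$image,
                        gradcam_config(target_class = 1, target_block = "BL",
                                       score_mask_mode = "whole-volume"))
  expect_identical(dim(bl$heat_map), dim(case$image))
  expect_identical(dim(bl$feature_maps)[1:3], as.integer(dim(case$image) / 8))
})
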