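# Direct (non-separable) reference SSIM: explicit Gaussian-weighted window
# sums at every voxel, border windows renormalized over in-grid support.
# Independent computational path from the package's separable implementation.
ssim3d_brute <- function(a, b, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  r <- as.integer(round(3.5 * sigma))
  d <- dim(a)
  k1d <- exp(-((-r:r)^2) / (2 * sigma^2))
  k1d <- k1d / sum(k1d)
  w3 <- outer(outer(k1d, k1d), k1d)
  c1 <- K1^2; c2 <- K2^2
  total <- 0
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    xs <- max(1, x - r):min(d[1], x + r)
    ys <- max(1, y - r):min(d[2], y + r)
    zs <- max(1, z - r):min(d[3], z + r)
    w <- w3[xs - x + r + 1, ys - y + r + 1, zs - z + r + 1]
    w <- w / sum(w)
    av <- a[xs, ys, zs]; bv <- b[xs, ys, zs]
    mu_a <- sum(w * av); mu_b <- sum(w * bv)
    va <- sum(w * av^2) - mu_a^2
    vb <- sum(w * bv^2) - mu_b^2
    cab <- sum(w * av * bv) - mu_a * mu_b
    total <- total + ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
      ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  }
  total / prod(d)
}

test_that("ssim3d agrees with a direct windowed reference implementation", {
  set.seed(21)
  for (i in 1:2) {
    a <- array(stats::runif(12 * 12 * 12), c(12, 12, 12))
    b <- if (i == 1) array(stats::runif(12^3), c(12, 12, 12)) else
      array(pmin(1, pmax(0, a + stats::rnorm(12^3, sd = 0.1))), c(12, 12, 12))
    expect_equal(ssim3d(a, b), ssim3d_brute(a, b), tolerance = 1e-6)
  }
})

test_that("ssim3d honours its contracts", {
  set.seed(22)
  a <- array(stats::runif(16 * 16 * 12), c(16, 16, 12))
  expect_equal(ssim3d(a, a), 1, tolerance = 1e-12)
  expect_lt(ssim3d(a, 1 - a), 1)
  expect_error(ssim3d(array(0, c(8, 8, 8)), array(0, c(8, 8, 8))),
               "window")
  expect_error(ssim3d(a, array(0, c(4, 4, 4))), "shapes differ")
})

test_that("normalized mutual information behaves at its extremes", {
  set.seed(23)
  a <- array(stats::runif(20 * 20 * 10), c(20, 20, 10))
  expect_identical(mutual_information(a, a), 1)
  # constant map: zero entropy convention
  expect_identical(mutual_information(array(0.5, dim(a)), a), 0)
  # independent maps: near zero on a large sample
  b <- array(stats::runif(100000), c(100, 100, 10))
  c2 <- array(stats::runif(100000), c(100, 100, 10))
  expect_lt(mutual_information(b, c2, n_bins = 64), 0.05)
  expect_error(mutual_information(a, array(0.1, c(2, 2, 2))), "shapes differ")
})

test_that("randomize_block touches exactly the named block", {
  net <- unet_build(unet_spec(3, 3, 2), seed = 30)
  rnd <- randomize_block(net, "D2", seed = 31)
  changed <- vapply(names(net$params), function(id) {
    !identical(net$params[[id]], rnd$params[[id]])
  }, TRUE)
  expect_identical(sort(names(which(changed))), sort(net$blocks$D2))
  # same seed gives identical randomized weights
  rnd2 <- randomize_block(net, "D2", seed = 31)
  expect_identical(rnd$params, rnd2$params)
  # batch-norm state is reset to the untrained identity
  first_conv <- net$blocks$D2[2]
  expect_true(all(rnd$params[[first_conv]]$r_mean == 0))
  expect_true(all(rnd$params[[first_conv]]$r_var == 1))
  expect_true(all(rnd$params[[first_conv]]$gamma == 1))
  expect_error(randomize_block(net, "nope"), "unknown block")
  # a randomized copy still produces valid softmax output
  case <- tiny_test_case(606)
  pred <- predict(rnd, case$image)
  expect_lt(max(abs(apply(pred$probs, c(1, 2, 3), sum) - 1)), 1e-5)
})

test_that("randomized weights follow the initialization distribution", {
  net <- unet_build(unet_spec(3, 3, 4), seed = 32)
  trained_like <- net
  # push weights far from initialization to emulate training
  for (id in net$blocks$E2) {
    trained_like$params[[id]]$W <- trained_like$params[[id]]$W + 1
  }
  rnd <- randomize_block(trained_like, "E2", seed = 33)
  w <- rnd$params[[net$blocks$E2[1]]]$W
  sd_init <- net$nodes[[net$blocks$E2[1]]]$init_sd
  # mean near 0 and spread near the He sd: no leakage of the +1 shift
  expect_lt(abs(mean(w)), 5 * sd_init / sqrt(length(w)))
  expect_lt(abs(stats::sd(w) - sd_init) / sd_init, 0.15)
})

test_that("model randomization separates trained from random networks", {
  net <- tiny_trained_net()
  cases <- lapply(701:703, tiny_test_case)
  cfg <- gradcam_config(target_class = 1)
  rep <- model_randomization_test(net, cases, cfg, seed = 34)
  expect_identical(nrow(as.data.frame(rep)), length(cases))
  expect_true(all(rep$mi < 1 & rep$ssim < 1))
  s <- summary(rep)
  expect_equal(s$mi_mean, mean(rep$mi))
})

test_that("cascaded randomization reports all stages with TN at unity", {
  net <- tiny_trained_net()
  cases <- list(tiny_test_case(704))
  cfg <- gradcam_config(target_class = 1)
  rep <- cascaded_randomization_test(net, cases, cfg,
                                     block_order = c("BL", "D3"),
                                     mode = "independent", seed = 35)
  df <- as.data.frame(rep)
  expect_identical(unique(df$stage), c("TN", "BL", "D3", "RN"))
  tn <- df[df$stage == "TN", ]
  expect_equal(tn$mi, 1)
  expect_equal(tn$ssim, 1, tolerance = 1e-9)
  rn <- df[df$stage == "RN", ]
  expect_true(all(rn$mi <= tn$mi & rn$ssim <= tn$ssim))
  # cumulative mode also runs
  rep2 <- cascaded_randomization_test(net, cases, cfg,
                                      block_order = c("BL", "D3"),
                                      mode = "cumulative", seed = 36)
  expect_identical(unique(as.data.frame(rep2)$stage),
                   c("TN", "BL", "D3", "RN"))
})
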