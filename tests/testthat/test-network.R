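# Closed-form parameter count for the U-Net layout: independent shape
# arithmetic against n_parameters().
expected_param_count <- function(in_ch, n_cls, f, npb) {
  conv <- function(cin, cout) 27 * cin * cout + cout + 2 * cout  # W + b + BN
  block <- function(cin, cout) {
    conv(cin, cout) + (npb - 1) * conv(cout, cout)
  }
  upconv <- function(cin, cout) cin * 8 * cout + cout
  total <- block(in_ch, f) + block(f, 2 * f) + block(2 * f, 4 * f) +
    block(4 * f, 8 * f) +
    upconv(8 * f, 4 * f) + block(8 * f, 4 * f) +
    upconv(4 * f, 2 * f) + block(4 * f, 2 * f) +
    upconv(2 * f, f) + block(2 * f, f) +
    f * n_cls + n_cls + 2 * n_cls  # 1x1x1 head + BN
  total
}

test_that("parameter count matches the closed-form layer arithmetic", {
  for (f in c(2, 4, 8)) {
    net <- unet_build(unet_spec(3, 3, base_channels = f, convs_per_block = 2),
                      seed = 1)
    expect_identical(n_parameters(net), as.integer(expected_param_count(3, 3, f, 2)))
  }
  net1 <- unet_build(unet_spec(2, 4, base_channels = 2, convs_per_block = 1),
                     seed = 1)
  expect_identical(n_parameters(net1),
                   as.integer(expected_param_count(2, 4, 2, 1)))
})

test_that("initialization is deterministic under the seed", {
  a <- unet_build(unet_spec(3, 3, 2), seed = 5)
  b <- unet_build(unet_spec(3, 3, 2), seed = 5)
  expect_identical(a$params, b$params)
  c <- unet_build(unet_spec(3, 3, 2), seed = 6)
  expect_false(identical(a$params, c$params))
})

test_that("softmax output is normalized per voxel and argmax-consistent", {
  net <- unet_build(unet_spec(3, 3, 2), seed = 2)
  case <- tiny_test_case(601)
  pred <- predict(net, case$image)
  sums <- apply(pred$probs, c(1, 2, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  # the labelled class attains the maximal probability everywhere
  d <- dim(pred$probs)
  pm <- matrix(pred$probs, prod(d[1:3]), d[4])
  expect_identical(as.integer(max.col(pm, ties.method = "first") - 1L),
                   as.integer(pred$class_map))
})

test_that("prediction is deterministic and validates its input", {
  net <- unet_build(unet_spec(3, 3, 2), seed = 3)
  case <- tiny_test_case(602)
  expect_identical(predict(net, case$image), predict(net, case$image))
  bad <- multichannel_volume(case$image$channels[1:2], case$image$spacing)
  expect_error(predict(net, bad), "channels")
  # direct forward on a grid not divisible by 8 raises a shape error
  expect_error(net_forward(net, array(0, c(12, 12, 12, 3))), "divisible")
  # predict pads and crops such grids instead
  sub <- multichannel_volume(lapply(case$image$channels,
                                    function(a) a[1:20, 1:20, 1:12]),
                             case$image$spacing)
  p <- predict(net, sub)
  expect_identical(dim(p$class_map), c(20L, 20L, 12L))
  expect_true(p$padded)
})

test_that("training with zero epochs leaves the weights unchanged", {
  net <- unet_build(unet_spec(3, 3, 2), seed = 4)
  case <- tiny_test_case(603)
  out <- unet_train(net, list(case), train_config(epochs = 0))
  expect_identical(out$params, net$params)
})

test_that("the network overfits a single repeated patch", {
  cs <- single_patch_case()
  net <- unet_build(unet_spec(3, 3, base_channels = 4), seed = 8)
  spec <- patch_spec(patch_size = c(16, 16, 8),
                     class_center_probs = c(0, 0, 1), rotation_prob = 0)
  trained <- unet_train(net, list(cs),
                        train_config(epochs = 30, patches_per_epoch = 5,
                                     seed = 8),
                        spec)
  log <- trained$training_log
  expect_lt(log$loss[nrow(log)], 0.5 * log$loss[1])
})

test_that("non-finite loss aborts with a diagnostic", {
  cs <- single_patch_case()
  net <- unet_build(unet_spec(3, 3, 2), seed = 9)
  net$params$E1.1$W[1] <- NaN  # a corrupt weight propagates to the loss
  spec <- patch_spec(patch_size = c(16, 16, 8), rotation_prob = 0,
                     class_center_probs = c(0, 0, 1))
  expect_error(
    unet_train(net, list(cs),
               train_config(epochs = 1, patches_per_epoch = 1, seed = 9),
               spec),
    "non-finite")
})

test_that("captured gradients have exactly the feature-map shapes", {
  net <- unet_build(unet_spec(3, 3, 2), seed = 10)
  x <- array(stats::rnorm(16 * 16 * 8 * 3), c(16, 16, 8, 3))
  fw <- net_forward(net, x, train = FALSE)
  d_head <- array(0, dim(fw$out$HEAD))
  d_head[1, 1, 1, 1] <- 1
  bw <- net_backward(net, fw, d_head, train = FALSE)
  for (b in c("E1", "E2", "E3", "BL", "D1", "D2", "D3")) {
    nid <- net$block_out[[b]]
    expect_identical(dim(bw$gout[[nid]]), dim(fw$out[[nid]]))
  }
})
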