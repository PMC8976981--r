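make_box_case <- function(dim3 = c(32, 32, 32), lo = c(10, 10, 10),
                          hi = c(20, 20, 20), spacing = c(1, 1, 1)) {
  cm <- array(0L, dim3)
  cm[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  image <- multichannel_volume(list(a = array(stats::rnorm(prod(dim3)), dim3)),
                               spacing = spacing)
  list(image = image, labels = label_volume(cm, spacing = spacing))
}

test_that("crop_to_roi returns the dilated gland bounding box", {
  cs <- make_box_case()
  # margin 0: the gland box [10..20]^3 exactly
  out <- crop_to_roi(cs$image, cs$labels, margin = 0)
  expect_identical(dim(out$image), c(11L, 11L, 11L))
  expect_true(all(out$labels$gland_mask))
  # 1 mm margin at 1 mm spacing: box [9..21]^3
  out1 <- crop_to_roi(cs$image, cs$labels, margin = 1)
  expect_identical(dim(out1$labels), c(13L, 13L, 13L))
  expect_equal(out1$image$channels$a,
               cs$image$channels$a[9:21, 9:21, 9:21])
  # margin clipped at the grid boundary
  big <- crop_to_roi(cs$image, cs$labels, margin = 100)
  expect_identical(dim(big$image), dim(cs$image))
})

test_that("crop is the identity for a whole-grid gland and errors when empty", {
  cs <- make_box_case(lo = c(1, 1, 1), hi = c(32, 32, 32))
  out <- crop_to_roi(cs$image, cs$labels, margin = 0)
  expect_identical(out$image$channels$a, cs$image$channels$a)
  empty <- make_box_case()
  empty$labels$gland_mask[] <- FALSE
  expect_error(crop_to_roi(empty$image, empty$labels), "empty")
})

test_that("resampling follows the ceil shape rule and keeps labels closed", {
  cs <- make_box_case(spacing = c(1, 1, 1))
  same <- resample(cs$image, cs$labels, target_spacing = c(1, 1, 1))
  expect_identical(dim(same$image), dim(cs$image))
  # doubling the spacing halves each dimension (ceil of extent / target)
  half <- resample(cs$image, cs$labels, target_spacing = c(2, 2, 2))
  expect_identical(dim(half$image), c(16L, 16L, 16L))
  expect_true(all(unique(as.integer(half$labels$class_map)) %in%
                    unique(as.integer(cs$labels$class_map))))
  odd <- resample(cs$image, cs$labels, target_spacing = c(3, 3, 3))
  expect_identical(dim(odd$image), as.integer(ceiling(32 / 3)) * c(1L, 1L, 1L))
  expect_error(resample(cs$image, cs$labels, c(0, 1, 1)), "positive")
})

test_that("sampled patches are centered on the drawn class and zero-padded", {
  case <- generate_phantom(small_phantom_config(seed = 31))
  spec <- patch_spec(patch_size = c(16, 16, 8), rotation_prob = 0)
  set.seed(1)
  for (i in 1:20) {
    pt <- sample_patch(case$image, case$labels, spec)
    expect_identical(dim(pt$labels), c(16L, 16L, 8L))
    expect_identical(dim(pt$image), c(16L, 16L, 8L, 3L))
    ctr <- (dim(pt$labels) - 1L) %/% 2L + 1L
    expect_identical(pt$labels[ctr[1], ctr[2], ctr[3]],
                     as.integer(pt$center_class))
    expect_identical(pt$labels[ctr[1], ctr[2], ctr[3]],
                     case$labels$class_map[pt$center_voxel[1],
                                           pt$center_voxel[2],
                                           pt$center_voxel[3]])
  }
  # absent classes are renormalized away rather than failing
  no_tumor <- generate_phantom(small_phantom_config(seed = 32,
                                                    n_lesions_range = c(0, 0)))
  set.seed(2)
  pt <- sample_patch(no_tumor$image, no_tumor$labels, spec)
  expect_true(pt$center_class %in% 0:1)
  # but an impossible request errors
  only_tumor <- patch_spec(patch_size = c(16, 16, 8),
                           class_center_probs = c(0, 0, 1))
  expect_error(sample_patch(no_tumor$image, no_tumor$labels, only_tumor),
               "no voxel")
})

test_that("patch sampling is reproducible under a fixed seed", {
  case <- generate_phantom(small_phantom_config(seed = 33))
  spec <- patch_spec(patch_size = c(16, 16, 8))
  p1 <- with_seed(5, sample_patch(case$image, case$labels, spec))
  p2 <- with_seed(5, sample_patch(case$image, case$labels, spec))
  expect_identical(p1, p2)
})

test_that("rotation augmentation transforms image and labels together", {
  case <- generate_phantom(small_phantom_config(seed = 34))
  spec0 <- patch_spec(patch_size = c(16, 16, 8), rotation_prob = 0)
  spec1 <- patch_spec(patch_size = c(16, 16, 8), rotation_prob = 1)
  set.seed(3)
  pt <- sample_patch(case$image, case$labels, spec0)
  expect_identical(augment_rotation(pt, spec0), pt)
  set.seed(4)
  rot <- augment_rotation(pt, spec1)
  expect_false(is.null(rot$rotation))
  expect_identical(dim(rot$image), dim(pt$image))
  expect_true(all(rot$labels %in% 0:2))
  # gland stays roughly the same size under rotation (mass preservation)
  expect_lt(abs(sum(rot$labels >= 1) - sum(pt$labels >= 1)) /
              max(1, sum(pt$labels >= 1)), 0.25)
})
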