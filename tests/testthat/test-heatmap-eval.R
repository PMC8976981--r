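rand_mask <- function(p, d = c(8, 8, 4)) array(stats::runif(prod(d)) < p, d)

test_that("dice matches hand counts and conventions", {
  d <- c(4, 4, 1)
  a <- array(FALSE, d); b <- array(FALSE, d)
  a[1:4] <- TRUE                 # |A| = 4
  b[2:7] <- TRUE                 # |B| = 6, overlap 3
  expect_equal(dice(a, b), 2 * 3 / (4 + 6))  # 0.6
  expect_identical(dice(a, a), 1)
  expect_identical(dice(a, !a), 0)
  expect_identical(dice(a & FALSE, b & FALSE), 1)  # both empty
  expect_error(dice(a, array(FALSE, c(2, 2, 2))), "shapes differ")
})

test_that("thresholding is strict and validates delta", {
  m <- array(c(0, 0.3, 0.6, 1), c(4, 1, 1))
  expect_identical(as.logical(threshold_heatmap(m, 0.5)),
                   c(FALSE, FALSE, TRUE, TRUE))
  # delta = 0 selects the support of a ReLU map, not the whole volume
  expect_identical(as.logical(threshold_heatmap(m, 0)),
                   c(FALSE, TRUE, TRUE, TRUE))
  expect_false(any(threshold_heatmap(m, 1)))
  expect_error(threshold_heatmap(m, 1.5), "delta")
  expect_error(threshold_heatmap(m - 2, 0.5), "normalized")
})

test_that("localization IOU matches hand counts and conventions", {
  d <- c(10, 1, 1)
  hm <- array(0, d); hm[1:4] <- 1          # |L| = 4 at delta 0.5
  gt <- array(FALSE, d); gt[3:8] <- TRUE   # |gt| = 6, overlap 2
  r <- localization_iou(hm, gt, 0.5)
  expect_equal(r$iou, 2 / 8)  # 0.25
  # heat map equal to the gt indicator is perfect at delta 0.5
  perfect <- localization_iou(array(as.numeric(gt), d), gt, 0.5)
  expect_identical(perfect$iou, 1)
  # empty union convention
  expect_identical(localization_iou(hm, gt & FALSE, 1)$iou, 0)
  expect_error(localization_iou(hm, array(FALSE, c(2, 5, 1)), 0.5),
               "does not match")
})

test_that("localization curve uses the standard delta grid", {
  gt <- rand_mask(0.3)
  hm <- array(as.numeric(gt), dim(gt))
  cv <- localization_curve(hm, gt)
  expect_identical(cv$delta, c(0, 0.25, 0.5))
  expect_true(all(cv$iou == 1))  # perfect map at every delta < 1
  set.seed(2)
  cv2 <- localization_curve(array(stats::runif(prod(dim(gt))), dim(gt)), gt)
  expect_true(all(cv2$iou >= 0 & cv2$iou <= 1))
})

test_that("dice and IOU satisfy their algebraic identity on random masks", {
  set.seed(11)
  for (i in 1:100) {
    a <- rand_mask(stats::runif(1, 0.1, 0.9))
    b <- rand_mask(stats::runif(1, 0.1, 0.9))
    uni <- sum(a | b)
    iou <- if (uni == 0) 0 else sum(a & b) / uni
    expect_equal(dice(a, b), 2 * iou / (1 + iou), tolerance = 1e-12)
    # symmetry of the IOU in its two masks
    expect_identical(localization_iou(array(as.numeric(a), dim(a)), b, 0.5)$iou,
                     localization_iou(array(as.numeric(b), dim(b)), a, 0.5)$iou)
  }
})

test_that("Loc is non-decreasing in delta for a radially decaying heat map", {
  d <- c(21, 21, 1)
  ctr <- c(11, 11, 1)
  g <- grid_coords(d, c(1, 1, 1))
  dist <- sqrt((g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2)
  hm <- array(pmax(0, 1 - dist / max(dist)), d)
  gt <- array(dist <= 5, d)
  deltas <- seq(0, 0.95, by = 0.05)
  ious <- vapply(deltas, function(dd) localization_iou(hm, gt, dd)$iou, 0)
  inside <- vapply(deltas, function(dd) {
    L <- threshold_heatmap(hm, dd)
    all(gt[L])
  }, TRUE)
  upto <- which(inside)[1]  # first delta where L is contained in gt
  expect_true(all(diff(ious[seq_len(upto)]) >= -1e-12))
})

test_that("case evaluation reports DSC per ground truth and localization", {
  case <- tiny_test_case(605)
  hm <- array(as.numeric(case$labels$tumor_mask_rad), dim(case$labels))
  row <- evaluate_case(case$labels$class_map, case$labels,
                       heatmaps = list(tumor = hm))
  expect_identical(row$dsc_gland, 1)
  expect_identical(row$dsc_tumor_rad, 1)
  expect_lt(row$dsc_tumor_histo, 1)
  expect_identical(row$loc_tumor_d0.5, 1)
  agg <- aggregate_report(rbind(row, row))
  expect_identical(agg$mean[agg$metric == "dsc_gland"], 1)
  expect_identical(agg$sd[agg$metric == "dsc_gland"], 0)
})
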