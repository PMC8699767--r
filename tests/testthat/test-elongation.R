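params_nosm <- function(threshold = 50, ...) {
  elongation_params(smooth_sigma_px = 0, seg_threshold = threshold, ...)
}

test_that("segmentation thresholds strictly after optional smoothing", {
  p <- params_nosm(0)
  expect_false(any(segment_cells(calibrated_image(matrix(0, 8, 8), 0.5), p)))
  p50 <- params_nosm(50)
  expect_true(all(segment_cells(calibrated_image(matrix(100, 8, 8), 0.5), p50)))
})

test_that("the narrow residual equals input XOR opening and is anti-extensive", {
  p <- params_nosm()
  expect_false(any(narrow_residual(matrix(FALSE, 30, 30), p)))

  # a radius-20 diamond is open: empty residual
  ball <- diamond_ball(c(61L, 61L), c(31, 31), 20)
  expect_false(any(narrow_residual(ball, p)))

  # an 8x150 interior rectangle is annihilated: residual is the rectangle
  rect <- rect_mask(c(60L, 200L), 25L, 25L, 8L, 150L)
  expect_identical(narrow_residual(rect, p), rect)
  # oracle confirmation that the opening removes it entirely
  expect_false(any(sweep_iterate(sweep_iterate(rect, 8, sweep_erode), 8, sweep_dilate)))

  # residual is a subset of the foreground for arbitrary inputs
  withr::with_seed(51, {
    for (i in 1:5) {
      x <- random_grid(c(40L, 40L), 0.6)
      r <- narrow_residual(x, p)
      expect_false(any(r & !x))
    }
  })
})

test_that("masks produced by radius-8 dilation always leave an empty residual", {
  p <- params_nosm()
  withr::with_seed(52, {
    for (i in 1:8) {
      d <- matrix(FALSE, 80, 80)
      d[sample(20:60, 12, TRUE) + 80 * (sample(20:60, 12, TRUE) - 1)] <- TRUE
      x <- dilate_diamond(d, 8L)
      expect_false(any(narrow_residual(x, p)))
    }
  })
})

test_that("residual filters delete by strict smaller-than rules", {
  p <- params_nosm()
  # pixel-level area boundary: 8x120 = 960 px2 kept, one pixel fewer deleted
  kept <- rect_mask(c(40L, 140L), 10L, 10L, 8L, 120L)
  lost <- kept; lost[10, 10] <- FALSE # area 959
  expect_equal(n_objects(filter_residuals(kept, p)), 1L)
  expect_equal(n_objects(filter_residuals(lost, p)), 0L)

  # a large disc fails only the eccentricity filter (major axis of a disc
  # of radius R is about 2R, so R = 62 clears the 120 px filter)
  disc <- disc_mask_at(c(130L, 130L), c(65, 65), 62)
  f <- region_features(label_mask(label_components(disc)))$features
  expect_gt(f$area_px2, 960)
  expect_gt(f$major_axis_px, 120)
  expect_lt(f$eccentricity, 0.75)
  expect_equal(n_objects(filter_residuals(disc, p)), 0L)

  # deletion-rule boundaries on the three features, strict "smaller than"
  expect_identical(
    residual_object_kept(c(959, 960, 2000, 2000, 2000, 2000),
                         c(0.99, 0.99, 0.749, 0.75, 0.99, 0.99),
                         c(300, 300, 300, 300, 119.9, 120), p),
    c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
})

test_that("the index is the survivors' summed major axis over positive cells", {
  # blank image: index 0 regardless of the denominator
  p <- params_nosm()
  blank <- calibrated_image(matrix(0, 50, 50), 0.5)
  expect_equal(elongation_index(blank, 10, p)$index, 0)

  # analytic rod: single interior 8x150 rectangle at high contrast
  shape <- c(60L, 200L)
  rect <- rect_mask(shape, 25L, 25L, 8L, 150L)
  img <- calibrated_image(rect * 100, 0.5)
  r1 <- elongation_index(img, 1, p)
  oracle <- moment_oracle(rect)
  expect_equal(n_objects(r1$residual_objects), 1L)
  expect_equal(r1$index, oracle$major, tolerance = 1e-6)
  expect_equal(r1$sum_major_axis_px / r1$n_positive_cells, r1$index)

  # doubling the positive-cell denominator exactly halves the index
  r2 <- elongation_index(img, 2, p)
  expect_equal(r2$index, r1$index / 2)
  r5 <- elongation_index(img, 5, p)
  expect_equal(r5$index, r1$index / 5)

  expect_error(elongation_index(img, 0, p), "undefined")
})

test_that("planted capsules are segmented accurately at high SNR", {
  sp <- synth_spec(cell_morphology = "spindle", n_cells = 4L, snr = 50, seed = 53)
  g <- generate_cell_body_image(sp)
  p <- elongation_params(smooth_sigma_px = 2,
                         seg_threshold = background_offset(sp) + 0.5 * sp$peak_intensity)
  fg <- segment_cells(g$stain, p)
  expect_gte(jaccard(fg, g$truth$cell_body_mask), 0.9)
})

test_that("spindle fields score far above round fields", {
  idx <- function(morph, seed) {
    sp <- synth_spec(cell_morphology = morph, seed = seed)
    g <- generate_cell_body_image(sp)
    p <- elongation_params(seg_threshold = background_offset(sp) + 0.3 * sp$peak_intensity)
    elongation_index(g$stain, g$truth$n_cells, p)$index
  }
  spindle <- vapply(1:5, function(s) idx("spindle", s), numeric(1))
  round_ <- vapply(1:5, function(s) idx("round", s + 500), numeric(1))
  expect_gt(mean(spindle), 2 * mean(round_))
})
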