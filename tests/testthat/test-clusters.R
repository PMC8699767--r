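test_that("cluster segmentation recovers forced simple cases", {
  blank <- calibrated_image(matrix(0, 32, 32), 0.5)
  expect_equal(n_objects(segment_clusters(blank, 10)), 0L)

  m <- matrix(0, 32, 32); m[10:19, 5:14] <- 100
  cl <- segment_clusters(calibrated_image(m, 0.5), threshold = 50, min_area_px2 = 4)
  expect_equal(n_objects(cl), 1L)
  expect_equal(cl$features$area_px2, 100)
  expect_equal(cl$features$mean_intensity, 100)

  # the minimum-area filter drops specks
  m[2, 2] <- 100
  cl2 <- segment_clusters(calibrated_image(m, 0.5), threshold = 50, min_area_px2 = 4)
  expect_equal(n_objects(cl2), 1L)
  cl3 <- segment_clusters(calibrated_image(m, 0.5), threshold = 50, min_area_px2 = 0)
  expect_equal(n_objects(cl3), 2L)
})

test_that("planted clusters are recovered in count, area and intensity", {
  sp <- synth_spec(n_clusters = 25L, snr = 10, seed = 61)
  g <- generate_coculture_image(sp)
  bg <- background_offset(sp)
  cl <- segment_clusters(g$channels$btx, threshold = bg + 0.4 * sp$peak_intensity)
  expect_equal(n_objects(cl), 25L)
  # match recovered to planted by centroid and compare areas within 10%
  tr <- g$truth$cluster_records
  for (k in seq_len(25L)) {
    d <- sqrt((cl$features$centroid_row - tr$center_row[k])^2 +
              (cl$features$centroid_col - tr$center_col[k])^2)
    j <- which.min(d)
    expect_lte(d[j], sp$cluster_radius_px)
    expect_lte(abs(cl$features$area_px2[j] - tr$true_area_px2[k]) / tr$true_area_px2[k], 0.1)
  }
})

test_that("myotube normalization converts pixel counts to mm2 exactly", {
  # planted mask covering 40% of a 1000x1000 frame at 0.5 um/px -> 0.1 mm2
  m <- matrix(0, 1000, 1000)
  m[1:400, ] <- 100
  seg <- segment_myotubes_for_normalization(calibrated_image(m, 0.5),
                                            c(0, 100), threshold = 0.5)
  expect_equal(seg$total_area_px2, 400000)
  expect_equal(seg$total_area_mm2, 0.1)

  # degenerate constant image: empty mask, area 0
  flat <- segment_myotubes_for_normalization(calibrated_image(matrix(5, 64, 64), 0.5))
  expect_equal(flat$total_area_mm2, 0)
  expect_equal(n_objects(flat$mask), 0L)
})

test_that("cluster count normalization follows the analytic form", {
  lab <- label_mask(matrix(0L, 8, 8))
  empty <- cluster_table(region_features(lab), 0.5)
  expect_equal(normalize_cluster_count(empty, 2)$summary$clusters_per_mm2, 0)

  m <- matrix(0, 64, 64)
  for (c0 in c(5, 15, 25, 35, 45)) m[10:12, c0:(c0 + 1)] <- 100
  cl <- segment_clusters(calibrated_image(m, 0.5), 50, min_area_px2 = 4)
  ct <- cluster_table(cl, 0.5)
  expect_equal(normalize_cluster_count(ct, 0.5)$summary$clusters_per_mm2, 10)
  expect_error(normalize_cluster_count(ct, 0), "undefined")
})

test_that("secondary-channel scoring recovers the planted co-positive fraction", {
  lab <- matrix(0L, 32, 32); lab[5:8, 5:8] <- 1L; lab[20:23, 20:23] <- 2L
  clusters <- region_features(label_mask(lab))
  zero <- calibrated_image(matrix(0, 32, 32), 0.5)
  expect_equal(score_secondary_channel(clusters, zero, "mean_gt", 0)$fraction_positive, 0)
  mirror <- calibrated_image((lab > 0) * 100, 0.5)
  expect_equal(score_secondary_channel(clusters, mirror, "mean_gt", 50)$fraction_positive, 1)

  sp <- synth_spec(n_clusters = 25L, rapsyn_fraction = 0.6, snr = 10, seed = 62)
  g <- generate_coculture_image(sp)
  bg <- background_offset(sp)
  cl <- segment_clusters(g$channels$btx, bg + 0.4 * sp$peak_intensity)
  sc_mean <- score_secondary_channel(cl, g$channels$rapsyn, "mean_gt",
                                     threshold = bg + 0.5 * sp$peak_intensity)
  expect_lte(abs(sc_mean$fraction_positive - 0.6), 0.05)
  sc_ov <- score_secondary_channel(cl, g$channels$rapsyn, "overlap_frac",
                                   threshold = 0.25,
                                   secondary_threshold = bg + 0.5 * sp$peak_intensity)
  expect_lte(abs(sc_ov$fraction_positive - 0.6), 0.05)
})

test_that("cluster metrics obey translation and threshold monotonicity", {
  sp <- synth_spec(n_clusters = 10L, snr = 20, seed = 63)
  g <- generate_coculture_image(sp)
  bg <- background_offset(sp)
  thr <- bg + 0.4 * sp$peak_intensity
  m <- g$channels$btx$pixels

  # translating interior objects by a common offset leaves mean area unchanged
  base <- matrix(0, 128, 128)
  base[40:47, 40:45] <- 100; base[80:85, 90:99] <- 100; base[100:109, 30:33] <- 100
  shifted <- matrix(0, 128, 128)
  shifted[11:128, 11:128] <- base[1:118, 1:118]
  a0 <- cluster_table(segment_clusters(calibrated_image(base, 0.5), 50), 0.5)$summary$mean_area_um2
  a1 <- cluster_table(segment_clusters(calibrated_image(shifted, 0.5), 50), 0.5)$summary$mean_area_um2
  expect_equal(a0, a1)

  # raising the threshold never increases total segmented area
  areas <- vapply(seq(bg, bg + sp$peak_intensity, length.out = 8), function(t) {
    f <- segment_clusters(g$channels$btx, t, min_area_px2 = 0)$features
    sum(f$area_px2)
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))

  # clusters_per_mm2 scales inversely with the squared pixel size
  ct1 <- normalize_cluster_count(cluster_table(segment_clusters(g$channels$btx, thr), 0.5),
                                 g$truth$myotube_area_px2 * 0.5^2 / 1e6)
  ct2 <- normalize_cluster_count(cluster_table(segment_clusters(g$channels$btx, thr), 0.25),
                                 g$truth$myotube_area_px2 * 0.25^2 / 1e6)
  expect_equal(ct2$summary$clusters_per_mm2, 4 * ct1$summary$clusters_per_mm2)
})
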