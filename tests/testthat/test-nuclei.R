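test_that("blob detection finds planted nuclei and nothing on blank fields", {
  blank <- calibrated_image(matrix(0, 64, 64), 0.5)
  expect_equal(n_points(detect_nuclei(blank, 3, 6, detect_threshold = 1)), 0L)

  # single planted Gaussian blob at high SNR
  sp <- synth_spec(image_shape = c(128L, 128L), n_nuclei = 1L, snr = 50, seed = 31)
  g <- generate_nuclei_image(sp)
  det <- detect_nuclei(g$dapi, 3, 6, detect_threshold = 10)
  expect_equal(n_points(det), 1L)
  ctr <- as.matrix(g$truth$nucleus_centers$points)[1, ]
  got <- as.matrix(det$points[, c("row", "col")])[1, ]
  expect_lte(sqrt(sum((ctr - got)^2)), 2)
})

test_that("detection recall and precision reach 0.95 on dense fields", {
  sp <- synth_spec(n_nuclei = 200L, snr = 10, seed = 32)
  g <- generate_nuclei_image(sp)
  det <- detect_nuclei(g$dapi, 3, 6, detect_threshold = 10)
  m <- match_points(as.matrix(g$truth$nucleus_centers$points),
                    as.matrix(det$points[, c("row", "col")]),
                    radius = sp$nucleus_radius_px)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})

test_that("detections respect the 50% blob-overlap suppression rule", {
  sp <- synth_spec(n_nuclei = 100L, snr = 10, seed = 33)
  det <- detect_nuclei(generate_nuclei_image(sp)$dapi, 3, 6, detect_threshold = 10)
  pts <- as.matrix(det$points[, c("row", "col")])
  radii <- sqrt(2) * det$points$sigma_px
  expect_gt(nrow(pts), 0)
  # numeric overlap of two discs by grid integration, relative to the smaller
  num_overlap <- function(p1, r1, p2, r2) {
    step <- min(r1, r2) / 40
    xs <- seq(p1[1] - r1, p1[1] + r1, by = step)
    ys <- seq(p1[2] - r1, p1[2] + r1, by = step)
    gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
    in1 <- (gx - p1[1])^2 + (gy - p1[2])^2 <= r1^2
    in2 <- (gx - p2[1])^2 + (gy - p2[2])^2 <= r2^2
    sum(in1 & in2) * step^2 / (pi * min(r1, r2)^2)
  }
  for (i in seq_len(nrow(pts))) for (j in seq_len(nrow(pts))) {
    if (j <= i) next
    d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    if (d >= radii[i] + radii[j]) next
    expect_lte(num_overlap(pts[i, ], radii[i], pts[j, ], radii[j]), 0.5 + 0.02)
  }

  # two blobs planted closer than the 50%-overlap distance collapse to one
  m <- matrix(0, 64, 64)
  for (ctr in list(c(30, 30), c(30, 34))) {
    m <- m + 100 * outer(exp(-(seq_len(64) - ctr[1])^2 / 32),
                         exp(-(seq_len(64) - ctr[2])^2 / 32))
  }
  close_det <- detect_nuclei(calibrated_image(m, 0.5), 4, 4, detect_threshold = 10)
  expect_equal(n_points(close_det), 1L)
})

test_that("seeded segmentation partitions foreground one label per seed", {
  # one disc, one centered seed: the label recovers the disc pixel count
  m <- matrix(0, 64, 64)
  disc <- disc_mask_at(c(64L, 64L), c(32, 32), 10)
  m[disc] <- 100
  img <- calibrated_image(m, 0.5)
  seg1 <- segment_nuclei(img, point_set(rbind(c(32, 32)), c(64L, 64L)),
                         smooth_sigma_px = 0, fg_threshold = 50)
  expect_equal(n_objects(seg1), 1L)
  expect_equal(seg1$features$area_px2, sum(disc))

  # two disjoint discs, two seeds
  m2 <- matrix(0, 64, 96)
  d1 <- disc_mask_at(c(64L, 96L), c(32, 28), 8)
  d2 <- disc_mask_at(c(64L, 96L), c(32, 68), 8)
  m2[d1] <- 100; m2[d2] <- 100
  seg2 <- segment_nuclei(calibrated_image(m2, 0.5),
                         point_set(rbind(c(32, 28), c(32, 68)), c(64L, 96L)),
                         smooth_sigma_px = 0, fg_threshold = 50)
  expect_equal(n_objects(seg2), 2L)
  expect_equal(sort(seg2$features$area_px2), sort(c(sum(d1), sum(d2))))

  expect_error(segment_nuclei(img, point_set(rbind(c(200, 200)), c(500L, 500L))),
               "seed outside image")
})

test_that("recovered nuclear masks overlap planted ones at SNR 10", {
  sp <- synth_spec(n_nuclei = 150L, snr = 10, seed = 34)
  g <- generate_nuclei_image(sp)
  seg <- segment_nuclei(g$dapi, g$truth$nucleus_centers, smooth_sigma_px = 2,
                        fg_threshold = background_offset(sp) + 0.1 * sp$peak_intensity)
  expect_equal(n_objects(seg), 150L)
  truth_lab <- g$truth$nucleus_label_mask$labels
  pts <- as.matrix(g$truth$nucleus_centers$points)
  jac <- vapply(seq_len(150L), function(i) {
    l <- seg$labels[pts[i, 1], pts[i, 2]]
    if (l == 0L) return(0)
    jaccard(truth_lab == i, seg$labels == l)
  }, numeric(1))
  expect_gte(mean(jac), 0.7)
})
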