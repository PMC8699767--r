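test_that("nuclear fields honor counts, flags and determinism", {
  sp <- synth_spec(n_nuclei = 0L, seed = 3)
  g0 <- generate_nuclei_image(sp)
  expect_equal(n_points(g0$truth$nucleus_centers), 0L)
  expect_equal(max(g0$truth$noise_free$dapi), 0)

  sp <- synth_spec(n_nuclei = 200L, positive_fraction = 0.6, seed = 5)
  g <- generate_nuclei_image(sp)
  expect_equal(n_points(g$truth$nucleus_centers), 200L)
  expect_equal(sum(g$truth$nucleus_positive_flags), 120L)

  g2 <- generate_nuclei_image(sp)
  expect_identical(g$dapi$pixels, g2$dapi$pixels)
  expect_identical(g$marker$pixels, g2$marker$pixels)

  # minimum center separation
  pts <- as.matrix(g$truth$nucleus_centers$points)
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  expect_gte(min(d), 2 * sp$nucleus_radius_px)
})

test_that("infeasible placement densities raise a capacity error", {
  sp <- synth_spec(image_shape = c(96L, 96L), n_nuclei = 200L, seed = 1)
  expect_error(generate_nuclei_image(sp), "max feasible")
})

test_that("cell-body fields match their stated morphology", {
  sp <- synth_spec(cell_morphology = "spindle", n_cells = 1L, seed = 9, snr = Inf)
  g <- generate_cell_body_image(sp)
  expect_equal(g$truth$n_cells, 1L)
  # noise-free rendering: thresholding the signal recovers the planted mask
  expect_identical(g$stain$pixels > 0, g$truth$cell_body_mask)
  # one capsule of the spec's dimensions: reconstruct it independently
  ctr <- as.matrix(g$truth$nucleus_centers$points)[1, ]
  ref <- capsule_mask_at(sp$image_shape, ctr, sp$spindle_length_px,
                         sp$spindle_width_px, g$truth$orientations[1])
  expect_identical(g$truth$cell_body_mask, ref)

  # round bodies contain no narrow (sub-17 px) structures: the opening
  # residual after the radius-8 diamond opening is tiny rasterization fringe
  spr <- synth_spec(cell_morphology = "round", n_cells = 4L, seed = 10, snr = Inf)
  gr <- generate_cell_body_image(spr)
  resid <- gr$truth$cell_body_mask & !open_diamond(gr$truth$cell_body_mask, 8L)
  expect_lt(sum(resid) / sum(gr$truth$cell_body_mask), 0.1)

  gr2 <- generate_cell_body_image(spr)
  expect_identical(gr$stain$pixels, gr2$stain$pixels)
})

test_that("coculture fields place clusters on myotubes with known truth", {
  sp <- synth_spec(n_clusters = 0L, seed = 2)
  g0 <- generate_coculture_image(sp)
  expect_equal(max(g0$truth$noise_free$btx), 0)
  expect_equal(nrow(g0$truth$cluster_records), 0L)

  sp <- synth_spec(n_clusters = 25L, myotube_fraction = 0.4, seed = 4)
  g <- generate_coculture_image(sp)
  tr <- g$truth
  expect_equal(nrow(tr$cluster_records), 25L)
  # every cluster center on the myotube mask
  expect_true(all(tr$myotube_mask[cbind(tr$cluster_records$center_row,
                                        tr$cluster_records$center_col)]))
  # coverage within pixel rounding of the target fraction
  expect_equal(tr$myotube_area_px2 / prod(sp$image_shape), 0.4, tolerance = 1e-3)
  # analytic density equals count over converted ground-truth area
  dens <- nrow(tr$cluster_records) / (tr$myotube_area_px2 * sp$pixel_size_um^2 / 1e6)
  expect_equal(dens, 25 / (tr$myotube_area_px2 * 0.25 / 1e6))
  # component areas sum to the mask area
  expect_equal(sum(tr$myotube_areas_um2), tr$myotube_area_px2 * 0.25)
})

test_that("additive noise keeps its nominal sigma on blank regions", {
  sp <- synth_spec(n_nuclei = 20L, snr = 10, seed = 6)
  g <- generate_nuclei_image(sp)
  blank <- g$truth$noise_free$dapi == 0
  expect_gte(sum(blank), 1e4)
  measured <- stats::sd(g$dapi$pixels[blank])
  expect_lt(abs(measured - noise_sigma(sp)) / noise_sigma(sp), 0.05)

  # snr = Inf is exactly noise-free
  spn <- synth_spec(n_nuclei = 5L, snr = Inf, seed = 6)
  gn <- generate_nuclei_image(spn)
  expect_identical(gn$dapi$pixels, gn$truth$noise_free$dapi)
})
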