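#' Specification for a synthetic micrograph
#'
#' Parameterizes the synthetic fluorescence fields used to validate every
#' pipeline stage: DAPI-like nuclear blobs with a controllable
#' marker-positive fraction, bipolar spindle-shaped cell bodies versus flat
#' rounded ones, myotube-like large smooth regions, and punctate receptor
#' clusters planted on the myotube mask.
#'
#' Signal model: planted structures are rendered at `peak_intensity` (blobs
#' as isotropic Gaussians, bodies and clusters as uniform shapes), then a
#' constant background offset plus additive Gaussian noise of standard
#' deviation `peak_intensity / snr` is added and the result is clipped at 0.
#' The background offset is fixed at four noise standard deviations so that
#' clipping is negligible and the noise keeps its nominal sigma on blank
#' regions. `snr = Inf` produces noise-free images (zero background).
#'
#' @param image_shape `(rows, cols)` in pixels.
#' @param pixel_size_um Micrometers per pixel edge.
#' @param n_nuclei Number of nuclei for nuclear fields.
#' @param nucleus_radius_px Planted nucleus radius; blob sigma is half of it.
#' @param positive_fraction Fraction of nuclei flagged marker-positive;
#'   exactly `round(positive_fraction * n_nuclei)` are flagged.
#' @param cell_morphology `"spindle"` (bipolar capsule-shaped bodies) or
#'   `"round"` (discs of equal area).
#' @param n_cells Number of cell bodies for cell-body fields.
#' @param spindle_length_px,spindle_width_px Capsule dimensions; the width
#'   should stay below 17 px so bodies are narrow structures for the
#'   radius-8 diamond opening.
#' @param n_clusters Number of receptor clusters for coculture fields.
#' @param cluster_radius_px Planted cluster disc radius.
#' @param myotube_fraction Target fraction of the frame covered by the
#'   myotube mask (achieved exactly up to pixel rounding).
#' @param rapsyn_fraction Fraction of clusters co-positive in the rapsyn
#'   channel; exactly `round(rapsyn_fraction * n_clusters)` are co-positive.
#' @param snr Peak signal over noise standard deviation; `Inf` = noise-free.
#' @param peak_intensity Planted peak signal amplitude (arbitrary units).
#' @param seed Integer RNG seed; identical specs produce bit-identical
#'   images.
#' @return A validated list of class `synth_spec`.
#' @export
synth_spec <- function(image_shape = c(512L, 512L), pixel_size_um = 0.5,
                       n_nuclei = 200L, nucleus_radius_px = 8,
                       positive_fraction = 0.6,
                       cell_morphology = c("spindle", "round"), n_cells = 8L,
                       spindle_length_px = 150, spindle_width_px = 8,
                       n_clusters = 25L, cluster_radius_px = 6,
                       myotube_fraction = 0.4, rapsyn_fraction = 0.6,
                       snr = 10, peak_intensity = 100, seed = 1L) {
  cell_morphology <- match.arg(cell_morphology)
  spec <- list(image_shape = as.integer(image_shape),
               pixel_size_um = pixel_size_um, n_nuclei = as.integer(n_nuclei),
               nucleus_radius_px = nucleus_radius_px,
               positive_fraction = positive_fraction,
               cell_morphology = cell_morphology, n_cells = as.integer(n_cells),
               spindle_length_px = spindle_length_px,
               spindle_width_px = spindle_width_px,
               n_clusters = as.integer(n_clusters),
               cluster_radius_px = cluster_radius_px,
               myotube_fraction = myotube_fraction,
               rapsyn_fraction = rapsyn_fraction,
               snr = snr, peak_intensity = peak_intensity,
               seed = as.integer(seed))
  stopifnot(length(spec$image_shape) == 2L, all(spec$image_shape >= 1L),
            spec$pixel_size_um > 0,
            spec$n_nuclei >= 0L, spec$nucleus_radius_px > 0,
            spec$positive_fraction >= 0, spec$positive_fraction <= 1,
            spec$n_cells >= 0L, spec$spindle_length_px > 0,
            spec$spindle_width_px > 0,
            spec$n_clusters >= 0L, spec$cluster_radius_px > 0,
            spec$rapsyn_fraction >= 0, spec$rapsyn_fraction <= 1,
            spec$snr > 0, spec$peak_intensity > 0)
  class(spec) <- "synth_spec"
  spec
}

#' Noise standard deviation and background offset implied by a spec
#' @param spec A [synth_spec()].
#' @return Noise sigma (`peak_intensity / snr`; 0 for `snr = Inf`).
#' @export
noise_sigma <- function(spec) {
  if (is.infinite(spec$snr)) 0 else spec$peak_intensity / spec$snr
}

#' @rdname noise_sigma
#' @return `background_offset()`: the constant offset (four noise sigmas).
#' @export
background_offset <- function(spec) 4 * noise_sigma(spec)

add_noise <- function(signal, spec) {
  sig <- noise_sigma(spec)
  if (sig == 0) return(signal)
  out <- signal + background_offset(spec) +
    matrix(stats::rnorm(length(signal), 0, sig), nrow(signal), ncol(signal))
  pmax(out, 0)
}

as_image <- function(m, spec, channel) {
  calibrated_image(m, pixel_size_um = spec$pixel_size_um, channel = channel)
}

# Rejection-sample n points uniformly in the margin-inset box with pairwise
# distance >= min_dist. Errors with the number actually placed if the
# density is infeasible.
place_points <- function(n, shape, margin, min_dist, tries_per_point = 500L) {
  if (n == 0L) return(matrix(numeric(), 0L, 2L, dimnames = list(NULL, c("row", "col"))))
  lo <- c(1 + margin, 1 + margin)
  hi <- c(shape[1] - margin, shape[2] - margin)
  if (any(hi < lo)) stop("image too small for requested margin")
  pts <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("row", "col")))
  placed <- 0L
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(tries_per_point)) {
      cand <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
      if (placed == 0L ||
          min(sqrt((pts[seq_len(placed), 1] - cand[1])^2 +
                   (pts[seq_len(placed), 2] - cand[2])^2)) >= min_dist) {
        placed <- placed + 1L
        pts[placed, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf("cannot place %d points at min distance %.1f px; max feasible here was %d",
                   n, min_dist, placed))
    }
  }
  round(pts)
}

# Sum of isotropic Gaussian blobs rendered at pixel centers.
render_blobs <- function(shape, centers, amplitude, sigma) {
  out <- matrix(0, shape[1], shape[2])
  if (nrow(centers) == 0L) return(out)
  w <- ceiling(4 * sigma)
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]
    rs <- max(1, r0 - w):min(shape[1], r0 + w)
    cs <- max(1, c0 - w):min(shape[2], c0 + w)
    blob <- amplitude * outer(exp(-(rs - r0)^2 / (2 * sigma^2)),
                              exp(-(cs - c0)^2 / (2 * sigma^2)))
    out[rs, cs] <- out[rs, cs] + blob
  }
  out
}

# Binary disc (Euclidean, pixel centers) as index positions in a matrix.
disc_index <- function(shape, center, radius) {
  r0 <- center[1]; c0 <- center[2]
  rs <- max(1, floor(r0 - radius)):min(shape[1], ceiling(r0 + radius))
  cs <- max(1, floor(c0 - radius)):min(shape[2], ceiling(c0 + radius))
  grid <- expand.grid(r = rs, c = cs)
  keep <- (grid$r - r0)^2 + (grid$c - c0)^2 <= radius^2
  cbind(grid$r[keep], grid$c[keep])
}

mask_from_index <- function(shape, idx) {
  m <- matrix(FALSE, shape[1], shape[2])
  if (nrow(idx)) m[idx] <- TRUE
  m
}

# Capsule: all pixels within width/2 of the central segment; total length
# `length` including the semicircular caps.
capsule_mask <- function(shape, center, length, width, theta) {
  half_seg <- (length - width) / 2
  u <- c(cos(theta), sin(theta))
  r0 <- center[1]; c0 <- center[2]
  ext <- length / 2 + 1
  rs <- max(1, floor(r0 - ext)):min(shape[1], ceiling(r0 + ext))
  cs <- max(1, floor(c0 - ext)):min(shape[2], ceiling(c0 + ext))
  grid <- expand.grid(r = rs, c = cs)
  dr <- grid$r - r0; dc <- grid$c - c0
  t <- pmin(pmax(dr * u[1] + dc * u[2], -half_seg), half_seg)
  d2 <- (dr - t * u[1])^2 + (dc - t * u[2])^2
  keep <- d2 <= (width / 2)^2
  m <- matrix(FALSE, shape[1], shape[2])
  m[cbind(grid$r[keep], grid$c[keep])] <- TRUE
  m
}

#' Generate a synthetic nuclear field with a marker channel
#'
#' Nuclei are Gaussian blobs (sigma = `nucleus_radius_px / 2`) at centers
#' kept at least two nucleus radii apart; the marker channel contains blobs
#' only at the `round(positive_fraction * n_nuclei)` nuclei flagged
#' positive. Ground truth records centers, flags, planted nucleus disc
#' masks, and the noise-free signals.
#'
#' @param spec A [synth_spec()].
#' @return A list with elements `dapi` and `marker` ([calibrated_image()]s)
#'   and `truth` (class `ground_truth`).
#' @export
generate_nuclei_image <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  withr::with_seed(spec$seed, {
    shape <- spec$image_shape
    rad <- spec$nucleus_radius_px
    centers <- place_points(spec$n_nuclei, shape,
                            margin = 2 * rad, min_dist = 2 * rad + 2)
    n <- nrow(centers)
    k <- round(spec$positive_fraction * n)
    flags <- rep(FALSE, n)
    if (k > 0L) flags[sample.int(n, k)] <- TRUE
    sig_dapi <- render_blobs(shape, centers, spec$peak_intensity, rad / 2)
    sig_marker <- render_blobs(shape, centers[flags, , drop = FALSE],
                               spec$peak_intensity, rad / 2)
    dapi <- add_noise(sig_dapi, spec)
    marker <- add_noise(sig_marker, spec)
    lab <- matrix(0L, shape[1], shape[2])
    for (i in seq_len(n)) lab[disc_index(shape, centers[i, ], rad)] <- i
    truth <- structure(list(
      nucleus_centers = point_set(centers, shape),
      nucleus_positive_flags = flags,
      nucleus_label_mask = label_mask(lab),
      noise_free = list(dapi = sig_dapi, marker = sig_marker)
    ), class = "ground_truth")
    list(dapi = as_image(dapi, spec, "DAPI"),
         marker = as_image(marker, spec, "marker"),
         truth = truth)
  })
}

#' Generate a synthetic cell-body field (spindle or round morphology)
#'
#' Spindle bodies are capsules (rectangles with semicircular caps) of the
#' spec's length and width at random orientations; round bodies are discs
#' of equal area. Bodies are placed without overlap (at least an 8 px gap)
#' and at least 20 px from the borders, rendered at uniform peak intensity.
#' One nucleus center is planted per body.
#'
#' @param spec A [synth_spec()].
#' @return A list with `stain` (a [calibrated_image()]) and `truth` (class
#'   `ground_truth` with the union body mask, per-body masks and centers).
#' @export
generate_cell_body_image <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  withr::with_seed(spec$seed, {
    shape <- spec$image_shape
    L <- spec$spindle_length_px; w <- spec$spindle_width_px
    spindle <- spec$cell_morphology == "spindle"
    r_eq <- sqrt(((L - w) * w + pi * (w / 2)^2) / pi)
    margin <- if (spindle) L / 2 + 20 else r_eq + 20
    union_dil <- matrix(FALSE, shape[1], shape[2])
    body_masks <- list()
    centers <- matrix(numeric(), 0L, 2L)
    thetas <- numeric()
    for (i in seq_len(spec$n_cells)) {
      ok <- FALSE
      for (t in seq_len(200L)) {
        cand_center <- round(c(stats::runif(1, 1 + margin, shape[1] - margin),
                               stats::runif(1, 1 + margin, shape[2] - margin)))
        theta <- stats::runif(1, 0, pi)
        cand <- if (spindle) capsule_mask(shape, cand_center, L, w, theta)
                else mask_from_index(shape, disc_index(shape, cand_center, r_eq))
        cand_dil <- dilate_diamond(cand, 4L)
        if (!any(cand_dil & union_dil)) {
          union_dil <- union_dil | cand_dil
          body_masks[[length(body_masks) + 1L]] <- cand
          centers <- rbind(centers, cand_center)
          thetas <- c(thetas, theta)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf("cannot place %d non-overlapping cell bodies; max feasible here was %d",
                     spec$n_cells, length(body_masks)))
      }
    }
    body_mask <- Reduce(`|`, body_masks, matrix(FALSE, shape[1], shape[2]))
    sig <- spec$peak_intensity * body_mask
    stain <- add_noise(sig, spec)
    truth <- structure(list(
      cell_body_mask = body_mask,
      body_masks = body_masks,
      nucleus_centers = point_set(centers, shape),
      orientations = thetas,
      n_cells = length(body_masks),
      noise_free = list(stain = sig)
    ), class = "ground_truth")
    list(stain = as_image(stain, spec, "S100b"), truth = truth)
  })
}

#' Generate a synthetic coculture field (myotubes, receptor clusters, rapsyn)
#'
#' The myotube mask is a smooth random field thresholded at the quantile
#' that yields the requested coverage fraction, giving a few large smooth
#' blobs. `n_clusters` non-overlapping discs of `cluster_radius_px` are
#' planted entirely on the myotube mask, each with its own uniform
#' intensity; a seeded subset of `round(rapsyn_fraction * n_clusters)`
#' clusters is repeated in the rapsyn channel. Ground truth carries the
#' per-cluster records (center, radius, exact pixel-count area, planted
#' intensity, rapsyn flag), the myotube mask and its component areas in
#' square micrometers.
#'
#' @param spec A [synth_spec()].
#' @return A list with `channels` (named list of [calibrated_image()]s:
#'   `myotube`, `btx`, `rapsyn`) and `truth` (class `ground_truth`).
#' @export
generate_coculture_image <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  stopifnot(spec$myotube_fraction > 0, spec$myotube_fraction < 1)
  withr::with_seed(spec$seed, {
    shape <- spec$image_shape
    z <- gauss_smooth(matrix(stats::rnorm(prod(shape)), shape[1], shape[2]),
                      sigma = min(30, min(shape) / 8))
    thr <- stats::quantile(z, 1 - spec$myotube_fraction, names = FALSE)
    myo_mask <- z > thr
    rad <- spec$cluster_radius_px
    # candidate centers: myotube pixels where a Euclidean disc is sure to fit
    inner <- erode_diamond(myo_mask, ceiling(rad * sqrt(2)) + 1L)
    cand_idx <- which(inner)
    nr <- shape[1]
    centers <- matrix(numeric(), 0L, 2L)
    cluster_idx <- list()
    for (i in seq_len(spec$n_clusters)) {
      ok <- FALSE
      for (t in seq_len(500L)) {
        if (length(cand_idx) == 0L) break
        pick <- cand_idx[sample.int(length(cand_idx), 1L)]
        cc <- c(((pick - 1L) %% nr) + 1L, ((pick - 1L) %/% nr) + 1L)
        if (nrow(centers) &&
            min(sqrt((centers[, 1] - cc[1])^2 + (centers[, 2] - cc[2])^2)) < 2 * rad + 3) next
        di <- disc_index(shape, cc, rad)
        if (!all(myo_mask[di])) next
        centers <- rbind(centers, cc)
        cluster_idx[[length(cluster_idx) + 1L]] <- di
        ok <- TRUE
        break
      }
      if (!ok) {
        stop(sprintf("cannot place %d clusters on the myotube mask; max feasible here was %d",
                     spec$n_clusters, nrow(centers)))
      }
    }
    n_cl <- nrow(centers)
    amps <- spec$peak_intensity * stats::runif(n_cl, 0.8, 1.6)
    sig_btx <- matrix(0, shape[1], shape[2])
    for (i in seq_len(n_cl)) sig_btx[cluster_idx[[i]]] <- amps[i]
    k_rap <- round(spec$rapsyn_fraction * n_cl)
    rap_flags <- rep(FALSE, n_cl)
    if (k_rap > 0L) rap_flags[sample.int(n_cl, k_rap)] <- TRUE
    sig_rap <- matrix(0, shape[1], shape[2])
    for (i in which(rap_flags)) sig_rap[cluster_idx[[i]]] <- spec$peak_intensity
    sig_myo <- 0.8 * spec$peak_intensity * myo_mask
    myo_lab <- label_components(myo_mask)
    areas_um2 <- as.numeric(tabulate(myo_lab[myo_lab > 0L], nbins = max(myo_lab, 0L))) *
      spec$pixel_size_um^2
    truth <- structure(list(
      myotube_mask = myo_mask,
      myotube_areas_um2 = areas_um2,
      myotube_area_px2 = sum(myo_mask),
      cluster_records = tibble::tibble(
        center_row = centers[, 1], center_col = centers[, 2],
        radius_px = rad,
        true_area_px2 = vapply(cluster_idx, nrow, integer(1)),
        true_mean_intensity = amps,
        rapsyn_positive = rap_flags),
      noise_free = list(myotube = sig_myo, btx = sig_btx, rapsyn = sig_rap)
    ), class = "ground_truth")
    list(channels = list(
           myotube = as_image(add_noise(sig_myo, spec), spec, "MF20"),
           btx = as_image(add_noise(sig_btx, spec), spec, "aBTX"),
           rapsyn = as_image(add_noise(sig_rap, spec), spec, "rapsyn")),
         truth = truth)
  })
}
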