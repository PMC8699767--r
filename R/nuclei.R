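#' Set of detected nucleus center points
#'
#' @param points Two-column matrix or data frame of (row, col) pixel
#'   coordinates (1-based).
#' @param source_shape `(rows, cols)` of the image the points refer to.
#' @return An object of class `point_set` with fields `points` (a tibble
#'   with columns `row`, `col`) and `source_shape`.
#' @export
point_set <- function(points, source_shape) {
  pts <- if (is.null(points)) matrix(numeric(), 0L, 2L) else as.matrix(points)
  if (length(pts) == 0L) pts <- matrix(numeric(), 0L, 2L)
  stopifnot(ncol(pts) == 2L, length(source_shape) == 2L)
  colnames(pts) <- c("row", "col")
  if (nrow(pts)) {
    if (any(pts[, 1] < 1 | pts[, 1] > source_shape[1] |
            pts[, 2] < 1 | pts[, 2] > source_shape[2])) {
      stop("all points must lie inside source_shape")
    }
  }
  structure(list(points = tibble::as_tibble(pts),
                 source_shape = as.integer(source_shape)),
            class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %d points in %d x %d px\n",
              nrow(x$points), x$source_shape[1], x$source_shape[2]))
  invisible(x)
}

#' Number of points in a point set
#' @param ps A [point_set()].
#' @return Integer count.
#' @export
n_points <- function(ps) nrow(ps$points)

# Fraction of the smaller circle's area shared by two circles.
circle_overlap_frac <- function(d, r1, r2) {
  rs <- pmin(r1, r2); rl <- pmax(r1, r2)
  out <- numeric(length(d))
  inside <- d <= rl - rs
  out[inside] <- 1
  sep <- d >= r1 + r2
  mid <- !inside & !sep
  if (any(mid)) {
    dm <- d[mid]; a <- rs[mid]; b <- rl[mid]
    d1 <- (dm^2 - a^2 + b^2) / (2 * dm)
    d2 <- dm - d1
    lens <- b^2 * acos(pmin(pmax(d1 / b, -1), 1)) - d1 * sqrt(pmax(b^2 - d1^2, 0)) +
      a^2 * acos(pmin(pmax(d2 / a, -1), 1)) - d2 * sqrt(pmax(a^2 - d2^2, 0))
    out[mid] <- lens / (pi * a^2)
  }
  out
}

# 3x3 grayscale max via shifts (outside = -Inf).
local_max3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- pmax(out, shift_mat(m, dr, dc, -Inf))
  }
  out
}

#' Detect nucleus centers with a Laplacian-of-Gaussian blob detector
#'
#' Scale-normalized LoG responses are computed over a small set of scales
#' between `min_sigma_px` and `max_sigma_px`; local maxima of the response
#' stack above `detect_threshold` become candidate detections, which are
#' then greedily non-maximum-suppressed so that no two retained blobs (of
#' radius `sqrt(2) * sigma`) overlap by more than 50% of the smaller blob's
#' area. Deterministic given its inputs; a blank image yields an empty
#' point set.
#'
#' @param dapi A [calibrated_image()] of the nuclear stain.
#' @param min_sigma_px,max_sigma_px Scale range in pixels
#'   (`0 < min <= max`).
#' @param detect_threshold Minimum scale-normalized response (> 0), on the
#'   intensity scale of the image; for a Gaussian blob of amplitude A the
#'   matched-scale response is about A/2.
#' @param n_scales Number of scales spanning the range.
#' @return A [point_set()]; scores and scales are kept as attributes of the
#'   points tibble columns `sigma_px` and `response`.
#' @export
detect_nuclei <- function(dapi, min_sigma_px = 3, max_sigma_px = 6,
                          detect_threshold, n_scales = 5L) {
  stopifnot(min_sigma_px > 0, min_sigma_px <= max_sigma_px,
            detect_threshold > 0)
  m <- as_pixels(dapi)
  shape <- dim(m)
  sigmas <- if (min_sigma_px == max_sigma_px) min_sigma_px else
    seq(min_sigma_px, max_sigma_px, length.out = n_scales)
  cand <- vector("list", length(sigmas))
  resp_list <- vector("list", length(sigmas))
  for (s in seq_along(sigmas)) {
    sm <- gauss_smooth(m, sigmas[s])
    lap <- shift_mat(sm, 1L, 0L, NA) + shift_mat(sm, -1L, 0L, NA) +
      shift_mat(sm, 0L, 1L, NA) + shift_mat(sm, 0L, -1L, NA) - 4 * sm
    # replicate boundary for the Laplacian
    lap[is.na(lap)] <- 0
    resp_list[[s]] <- -sigmas[s]^2 * lap
  }
  for (s in seq_along(sigmas)) {
    resp <- resp_list[[s]]
    nb <- local_max3(resp)
    if (s > 1L) nb <- pmax(nb, local_max3(resp_list[[s - 1L]]), resp_list[[s - 1L]])
    if (s < length(sigmas)) nb <- pmax(nb, local_max3(resp_list[[s + 1L]]), resp_list[[s + 1L]])
    hit <- which(resp > detect_threshold & resp >= nb)
    if (length(hit)) {
      nr <- shape[1]
      cand[[s]] <- cbind(row = ((hit - 1L) %% nr) + 1L,
                         col = ((hit - 1L) %/% nr) + 1L,
                         sigma = sigmas[s], response = resp[hit])
    }
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0L) return(point_set(NULL, shape))
  ord <- order(-cand[, "response"], cand[, "row"], cand[, "col"])
  cand <- cand[ord, , drop = FALSE]
  keep <- integer()
  for (i in seq_len(nrow(cand))) {
    if (length(keep)) {
      d <- sqrt((cand[keep, "row"] - cand[i, "row"])^2 +
                (cand[keep, "col"] - cand[i, "col"])^2)
      ov <- circle_overlap_frac(d, sqrt(2) * cand[keep, "sigma"],
                                rep(sqrt(2) * cand[i, "sigma"], length(keep)))
      if (any(ov > 0.5)) next
    }
    keep <- c(keep, i)
  }
  sel <- cand[keep, , drop = FALSE]
  ps <- point_set(sel[, c("row", "col"), drop = FALSE], shape)
  ps$points$sigma_px <- sel[, "sigma"]
  ps$points$response <- sel[, "response"]
  ps
}

#' Segment individual nuclei around detected seeds
#'
#' Foreground is the Gaussian-smoothed nuclear stain above `fg_threshold`
#' (Otsu's threshold on the smoothed image when not supplied); the
#' foreground is then partitioned among the seed points by intensity-guided
#' propagation, so every seed yields exactly one label containing its seed
#' pixel (seed pixels are always included in the foreground).
#'
#' @param dapi A [calibrated_image()].
#' @param seeds A [point_set()] of nucleus centers.
#' @param smooth_sigma_px Smoothing sigma in pixels.
#' @param fg_threshold Foreground threshold on the smoothed intensity;
#'   `NULL` = Otsu.
#' @return A [label_mask()] with features populated against the original
#'   intensities.
#' @export
segment_nuclei <- function(dapi, seeds, smooth_sigma_px = 2, fg_threshold = NULL) {
  stopifnot(inherits(seeds, "point_set"))
  m <- as_pixels(dapi)
  pts <- as.matrix(seeds$points[, c("row", "col")])
  if (nrow(pts) &&
      (any(pts[, 1] < 1 | pts[, 1] > nrow(m) | pts[, 2] < 1 | pts[, 2] > ncol(m)))) {
    stop("seed outside image")
  }
  if (nrow(pts) == 0L) return(region_features(label_mask(matrix(0L, nrow(m), ncol(m))), m))
  sm <- gauss_smooth(m, smooth_sigma_px)
  if (is.null(fg_threshold)) fg_threshold <- otsu_threshold(sm)
  fg <- sm > fg_threshold
  fg[pts] <- TRUE
  seed_img <- matrix(0L, nrow(m), ncol(m))
  seed_img[pts] <- seq_len(nrow(pts))
  lab <- EBImage::propagate(sm, seeds = seed_img, mask = fg)
  lab <- matrix(as.integer(round(as.numeric(lab))), nrow(m), ncol(m))
  region_features(label_mask(lab), m)
}
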