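#' Per-nucleus marker-positivity classification result
#'
#' @param marker Marker name.
#' @param rule `"point_max"` or `"nuclear_mean"`.
#' @param threshold_used The threshold the calls were made against.
#' @param calls Logical vector, one call per nucleus.
#' @param scores Numeric per-nucleus scores the calls were derived from.
#' @return An object of class `classification_result` with counts and the
#'   positive fraction (`NaN` when there are no nuclei).
#' @export
classification_result <- function(marker, rule, threshold_used, calls,
                                  scores = NULL) {
  n <- length(calls)
  structure(list(marker = marker, rule = rule,
                 threshold_used = threshold_used,
                 calls = as.logical(calls), scores = scores,
                 n_total = n, n_positive = sum(calls),
                 fraction_positive = if (n > 0) sum(calls) / n else NaN),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s (%s rule, threshold %g): %d / %d positive (%.1f%%)\n",
              x$marker, x$rule, x$threshold_used, x$n_positive, x$n_total,
              100 * x$fraction_positive))
  invisible(x)
}

#' Classify nuclei by the point-maximum rule
#'
#' The marker channel is smoothed with a Gaussian filter (sigma 0.5 px by
#' default), and for each detected nucleus center the maximum value inside
#' a `window_px` x `window_px` window (3 x 3 by default) centered at the
#' point is compared to the threshold. A maximum strictly greater than the
#' threshold counts as a positive cell. Windows are clipped at image
#' borders rather than discarded.
#'
#' @param marker_img A [calibrated_image()] of the marker stain.
#' @param centers A [point_set()] of nucleus centers.
#' @param threshold User-defined intensity threshold (strict `>`).
#' @param smooth_sigma_px Gaussian sigma in pixels; 0 disables smoothing.
#' @param window_px Odd window edge length in pixels.
#' @param marker Marker name recorded in the result.
#' @return A [classification_result()].
#' @export
classify_point_max <- function(marker_img, centers, threshold,
                               smooth_sigma_px = 0.5, window_px = 3L,
                               marker = NULL) {
  stopifnot(inherits(centers, "point_set"), is.finite(threshold))
  window_px <- as.integer(window_px)
  if (window_px < 1L || window_px %% 2L == 0L) {
    stop("`window_px` must be a positive odd integer")
  }
  m <- as_pixels(marker_img)
  pts <- as.matrix(centers$points[, c("row", "col")])
  if (nrow(pts) && any(pts[, 1] < 1 | pts[, 1] > nrow(m) |
                       pts[, 2] < 1 | pts[, 2] > ncol(m))) {
    stop("nucleus centers outside the marker image")
  }
  sm <- gauss_smooth(m, smooth_sigma_px)
  h <- (window_px - 1L) %/% 2L
  scores <- vapply(seq_len(nrow(pts)), function(i) {
    r <- pts[i, 1]; cc <- pts[i, 2]
    max(sm[max(1L, r - h):min(nrow(m), r + h),
           max(1L, cc - h):min(ncol(m), cc + h)])
  }, numeric(1))
  if (is.null(marker)) {
    marker <- if (inherits(marker_img, "calibrated_image")) marker_img$channel else "marker"
  }
  classification_result(marker, "point_max", threshold,
                        calls = scores > threshold, scores = scores)
}

#' Classify nuclei by the nuclear-mean rule
#'
#' For each segmented nucleus, the mean marker intensity within the
#' segmented nuclear area is compared to the threshold; a mean strictly
#' greater than the threshold counts as a positive cell.
#'
#' @param marker_img A [calibrated_image()] of the marker stain.
#' @param nuclei A [label_mask()] of segmented nuclei.
#' @param threshold User-defined intensity threshold (strict `>`).
#' @param marker Marker name recorded in the result.
#' @return A [classification_result()].
#' @export
classify_nuclear_mean <- function(marker_img, nuclei, threshold, marker = NULL) {
  stopifnot(inherits(nuclei, "label_mask"), is.finite(threshold))
  check_same_shape(nuclei$labels, marker_img, "nuclei and marker image")
  feats <- region_features(nuclei, marker_img)$features
  if (is.null(marker)) {
    marker <- if (inherits(marker_img, "calibrated_image")) marker_img$channel else "marker"
  }
  classification_result(marker, "nuclear_mean", threshold,
                        calls = feats$mean_intensity > threshold,
                        scores = feats$mean_intensity)
}
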