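#' Labeled segmentation mask with per-object features
#'
#' Wraps an integer label grid (0 = background, objects 1..n) together with
#' a per-label feature table. Features follow the ellipse-of-equal-moments
#' convention: moments are computed over pixel-center coordinates with no
#' per-pixel variance correction, the major axis length is
#' `4 * sqrt(largest eigenvalue)` of the coordinate covariance, and
#' eccentricity is `sqrt(1 - (minor/major)^2)` (0 for a circle, approaching
#' 1 for a line). A single-pixel object therefore has major axis 0 and
#' eccentricity 0.
#'
#' @param labels Integer matrix of labels (0 background, consecutive 1..n).
#' @param features Optional feature tibble as produced by [region_features()].
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, features = NULL) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  n <- max(labels, 0L)
  present <- sort(unique(labels[labels > 0L]))
  if (length(present) && !identical(present, seq_len(n))) {
    stop("labels must be consecutive 1..n")
  }
  structure(list(labels = labels, features = features), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %d objects%s\n",
              nrow(x$labels), ncol(x$labels), n_objects(x),
              if (is.null(x$features)) " (features not computed)" else ""))
  invisible(x)
}

#' Number of objects in a label mask
#' @param mask A [label_mask()] or integer label matrix.
#' @return Integer count of labels.
#' @export
n_objects <- function(mask) {
  lab <- if (inherits(mask, "label_mask")) mask$labels else mask
  max(lab, 0L)
}

#' Compute per-object region features
#'
#' For every label: pixel-count area, centroid, second-moment ellipse
#' properties (major/minor axis length, eccentricity) and, when an intensity
#' image is supplied, the mean intensity over the object's pixels. The
#' moment convention is documented in [label_mask()].
#'
#' @param mask A [label_mask()] or integer label matrix.
#' @param intensity Optional [calibrated_image()] or matrix of the same
#'   shape whose values are averaged per object.
#' @return A `label_mask` with its `features` tibble populated (columns
#'   `label`, `area_px2`, `centroid_row`, `centroid_col`, `major_axis_px`,
#'   `minor_axis_px`, `eccentricity`, and `mean_intensity` when requested).
#' @export
region_features <- function(mask, intensity = NULL) {
  lab <- if (inherits(mask, "label_mask")) mask$labels else mask
  if (!is.null(intensity)) check_same_shape(lab, intensity, "labels and intensity")
  n <- max(lab, 0L)
  if (n == 0L) {
    feats <- tibble::tibble(label = integer(), area_px2 = numeric(),
                            centroid_row = numeric(), centroid_col = numeric(),
                            major_axis_px = numeric(), minor_axis_px = numeric(),
                            eccentricity = numeric())
    if (!is.null(intensity)) feats$mean_intensity <- numeric()
    return(label_mask(lab, feats))
  }
  idx <- which(lab > 0L)
  g <- lab[idx]
  nr <- nrow(lab)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  area <- as.numeric(tabulate(g, nbins = n))
  sr <- rowsum_by(r, g, n); sc <- rowsum_by(cc, g, n)
  srr <- rowsum_by(r * r, g, n); scc <- rowsum_by(cc * cc, g, n)
  src <- rowsum_by(r * cc, g, n)
  mr <- sr / area; mc <- sc / area
  mu20 <- srr / area - mr^2
  mu02 <- scc / area - mc^2
  mu11 <- src / area - mr * mc
  tr2 <- (mu20 + mu02) / 2
  disc <- sqrt(pmax(((mu20 - mu02) / 2)^2 + mu11^2, 0))
  lmax <- pmax(tr2 + disc, 0)
  lmin <- pmax(tr2 - disc, 0)
  major <- 4 * sqrt(lmax)
  minor <- 4 * sqrt(lmin)
  ecc <- ifelse(lmax > 0, sqrt(pmax(1 - lmin / lmax, 0)), 0)
  feats <- tibble::tibble(label = seq_len(n), area_px2 = area,
                          centroid_row = mr, centroid_col = mc,
                          major_axis_px = major, minor_axis_px = minor,
                          eccentricity = ecc)
  if (!is.null(intensity)) {
    v <- as_pixels(intensity)[idx]
    feats$mean_intensity <- rowsum_by(v, g, n) / area
  }
  label_mask(lab, feats)
}

rowsum_by <- function(v, g, n) {
  out <- numeric(n)
  s <- rowsum(as.numeric(v), g)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

# Relabel a mask so the labels in `keep` become consecutive 1..k, then
# recompute features.
relabel_keep <- function(lab, keep, intensity = NULL) {
  map <- integer(max(lab, 0L) + 1L) # map[label + 1]
  map[keep + 1L] <- seq_along(keep)
  out <- matrix(map[lab + 1L], nrow(lab), ncol(lab))
  region_features(label_mask(out), intensity)
}
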