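#' Segment acetylcholine-receptor clusters
#'
#' Thresholds the alpha-bungarotoxin channel and labels the 4-connected
#' components, dropping components below `min_area_px2` (the automated
#' surrogate for the manual artifact-selection step; the default of 4 px
#' excludes sub-diffraction specks). Features are populated against the
#' input intensities.
#'
#' @param btx A [calibrated_image()] of the receptor stain.
#' @param threshold Segmentation threshold (strict `>`).
#' @param min_area_px2 Minimum component area kept, in square pixels.
#' @return A [label_mask()] of clusters.
#' @export
segment_clusters <- function(btx, threshold, min_area_px2 = 4) {
  stopifnot(is.finite(threshold), min_area_px2 >= 0)
  m <- as_pixels(btx)
  lab <- label_components(m > threshold)
  lm <- region_features(label_mask(lab), m)
  keep <- lm$features$label[lm$features$area_px2 >= min_area_px2]
  relabel_keep(lm$labels, keep, m)
}

#' Build a cluster table from a segmented cluster mask
#'
#' Per-cluster areas (in square pixels and square micrometers), mean
#' intensities and centroids, plus the across-cluster summary (count, mean
#' area, mean intensity).
#'
#' @param clusters A [label_mask()] from [segment_clusters()] whose
#'   features were computed against the receptor intensities.
#' @param pixel_size_um Micrometers per pixel edge.
#' @return A list of class `cluster_table` with `clusters` (tibble) and
#'   `summary` (list with `n_clusters`, `mean_area_um2`,
#'   `mean_intensity_au`, and `NA` placeholders for the normalization
#'   fields until [normalize_cluster_count()] is applied).
#' @export
cluster_table <- function(clusters, pixel_size_um) {
  stopifnot(inherits(clusters, "label_mask"), pixel_size_um > 0)
  f <- clusters$features
  if (is.null(f)) stop("cluster mask has no features; run region_features() first")
  tbl <- tibble::tibble(
    label = f$label,
    area_px2 = f$area_px2,
    area_um2 = f$area_px2 * pixel_size_um^2,
    mean_intensity_au = if ("mean_intensity" %in% names(f)) f$mean_intensity else NA_real_,
    centroid_row = f$centroid_row,
    centroid_col = f$centroid_col)
  structure(list(
    clusters = tbl,
    summary = list(n_clusters = nrow(tbl),
                   mean_area_um2 = if (nrow(tbl)) mean(tbl$area_um2) else NA_real_,
                   mean_intensity_au = if (nrow(tbl)) mean(tbl$mean_intensity_au) else NA_real_,
                   myotube_area_mm2 = NA_real_,
                   clusters_per_mm2 = NA_real_,
                   fraction_rapsyn_positive = NA_real_)),
    class = "cluster_table")
}

#' @export
print.cluster_table <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cluster_table> %d clusters, mean area %.1f um2, mean intensity %.1f au",
              s$n_clusters, s$mean_area_um2, s$mean_intensity_au))
  if (!is.na(s$clusters_per_mm2)) {
    cat(sprintf(", %.1f per mm2 myotube", s$clusters_per_mm2))
  }
  cat("\n")
  invisible(x)
}

#' Segment myotubes for cluster-count normalization
#'
#' Visualizes whole myotubes by a linear contrast stretch (mapping the low
#' and high intensity percentiles to 0 and 1), thresholds the stretched
#' image and labels 4-connected components. The total myotube area in
#' square millimeters is the normalization denominator for cluster counts.
#' A constant (degenerate) image yields an empty mask with area 0.
#'
#' @param myotube_channel A [calibrated_image()] (e.g. myosin/desmin).
#' @param contrast_percentiles `(low, high)` percentiles in `[0, 100]`.
#' @param threshold Threshold on the stretched `[0, 1]` scale (strict `>`).
#' @return A list with `mask` (a [label_mask()]), `total_area_px2` and
#'   `total_area_mm2`.
#' @export
segment_myotubes_for_normalization <- function(myotube_channel,
                                               contrast_percentiles = c(1, 99),
                                               threshold = 0.5) {
  stopifnot(inherits(myotube_channel, "calibrated_image"),
            length(contrast_percentiles) == 2L,
            contrast_percentiles[1] >= 0, contrast_percentiles[2] <= 100,
            contrast_percentiles[1] < contrast_percentiles[2])
  m <- myotube_channel$pixels
  qs <- stats::quantile(m, contrast_percentiles / 100, names = FALSE)
  if (qs[2] <= qs[1]) {
    empty <- region_features(label_mask(matrix(0L, nrow(m), ncol(m))), m)
    return(list(mask = empty, total_area_px2 = 0, total_area_mm2 = 0))
  }
  stretched <- pmin(pmax((m - qs[1]) / (qs[2] - qs[1]), 0), 1)
  lab <- label_components(stretched > threshold)
  lm <- region_features(label_mask(lab), m)
  px <- sum(lab > 0L)
  list(mask = lm, total_area_px2 = px,
       total_area_mm2 = px * myotube_channel$pixel_size_um^2 / 1e6)
}

#' Normalize the cluster count to the myotube area
#'
#' @param clusters A [cluster_table()].
#' @param myotube_area_mm2 Total myotube area in square millimeters (> 0).
#' @return The `cluster_table` with `myotube_area_mm2` and
#'   `clusters_per_mm2 = n_clusters / myotube_area_mm2` filled in.
#' @export
normalize_cluster_count <- function(clusters, myotube_area_mm2) {
  stopifnot(inherits(clusters, "cluster_table"))
  if (!is.finite(myotube_area_mm2) || myotube_area_mm2 <= 0) {
    stop("`myotube_area_mm2` must be > 0: cluster density is undefined without myotube area")
  }
  clusters$summary$myotube_area_mm2 <- myotube_area_mm2
  clusters$summary$clusters_per_mm2 <- clusters$summary$n_clusters / myotube_area_mm2
  clusters
}

#' Score clusters against a secondary channel (rapsyn or neurite stains)
#'
#' Two explicit rules, selected by the caller (no silent default):
#' `"mean_gt"` calls a cluster positive when the mean secondary intensity
#' within the cluster mask is strictly greater than `threshold`;
#' `"overlap_frac"` calls a cluster positive when the fraction of its
#' pixels lying on the binarized secondary mask is at least `threshold`
#' (binarization at `secondary_threshold`, Otsu's threshold when `NULL`).
#' The overlap rule with threshold 0.25 is the automated analogue of the
#' manual colocalization counting; it is not equivalent to a by-eye count.
#'
#' @param clusters A [label_mask()] of segmented clusters.
#' @param secondary A [calibrated_image()] of the secondary stain.
#' @param rule `"mean_gt"` or `"overlap_frac"`.
#' @param threshold Rule threshold (see above).
#' @param secondary_threshold Binarization threshold for `"overlap_frac"`.
#' @return A list with `calls` (logical per cluster), `scores`, and
#'   `fraction_positive`.
#' @export
score_secondary_channel <- function(clusters, secondary,
                                    rule = c("mean_gt", "overlap_frac"),
                                    threshold, secondary_threshold = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(clusters, "label_mask"), is.finite(threshold))
  check_same_shape(clusters$labels, secondary, "clusters and secondary channel")
  n <- n_objects(clusters)
  sec <- as_pixels(secondary)
  if (rule == "mean_gt") {
    f <- region_features(clusters, sec)$features
    scores <- f$mean_intensity
    calls <- scores > threshold
  } else {
    if (is.null(secondary_threshold)) secondary_threshold <- otsu_threshold(sec)
    bin <- sec > secondary_threshold
    lab <- clusters$labels
    idx <- which(lab > 0L)
    g <- lab[idx]
    area <- as.numeric(tabulate(g, nbins = n))
    on_mask <- rowsum_by(as.numeric(bin[idx]), g, n)
    scores <- ifelse(area > 0, on_mask / area, 0)
    calls <- scores >= threshold
  }
  list(calls = calls, scores = scores,
       fraction_positive = if (n > 0) sum(calls) / n else NaN)
}
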