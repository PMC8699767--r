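#' Parameters of the elongation-index pipeline
#'
#' Defaults follow the published procedure: Gaussian smoothing with sigma
#' 8 px, a user-defined segmentation threshold, 8 iterations of binary
#' erosion followed by 8 iterations of binary dilation with the 3x3
#' diamond structuring element, and removal of residual objects with area
#' below 960 square pixels, eccentricity below 0.75, or major axis length
#' below 120 px (all strict "smaller than", so boundary values survive).
#'
#' @param smooth_sigma_px Gaussian sigma in pixels (0 disables smoothing).
#' @param seg_threshold Segmentation threshold (strict `>`); user-defined,
#'   no default.
#' @param n_erosions,n_dilations Morphology iteration counts (equal by
#'   default, i.e. an opening).
#' @param min_area_px2 Minimum surviving object area in square pixels.
#' @param min_eccentricity Minimum surviving eccentricity, in `[0, 1)`.
#' @param min_major_axis_px Minimum surviving major axis length in pixels.
#' @return A list of class `elongation_params`.
#' @export
elongation_params <- function(smooth_sigma_px = 8, seg_threshold,
                              n_erosions = 8L, n_dilations = n_erosions,
                              min_area_px2 = 960, min_eccentricity = 0.75,
                              min_major_axis_px = 120) {
  stopifnot(smooth_sigma_px >= 0, is.finite(seg_threshold),
            n_erosions >= 0L, n_dilations >= 0L,
            min_area_px2 >= 0, min_major_axis_px >= 0,
            min_eccentricity >= 0, min_eccentricity < 1)
  structure(list(smooth_sigma_px = smooth_sigma_px,
                 seg_threshold = seg_threshold,
                 n_erosions = as.integer(n_erosions),
                 n_dilations = as.integer(n_dilations),
                 min_area_px2 = min_area_px2,
                 min_eccentricity = min_eccentricity,
                 min_major_axis_px = min_major_axis_px),
            class = "elongation_params")
}

#' Segment cell bodies for the elongation analysis
#'
#' Gaussian smoothing followed by a strict threshold, exactly the
#' segmentation step of the elongation pipeline.
#'
#' @param stain A [calibrated_image()] (e.g. the S100b channel).
#' @param params An [elongation_params()].
#' @return A logical foreground matrix.
#' @export
segment_cells <- function(stain, params) {
  stopifnot(inherits(params, "elongation_params"))
  gauss_smooth(as_pixels(stain), params$smooth_sigma_px) > params$seg_threshold
}

#' Narrow-structure residual of a binary segmentation
#'
#' Removes narrow structures by `n_erosions` iterations of binary erosion
#' followed by `n_dilations` iterations of binary dilation with the 3x3
#' diamond element, then takes the element-wise XOR of the processed and
#' raw segmentations. Because the opening is anti-extensive (the processed
#' mask is a subset of the input, asserted here), the XOR equals the set
#' difference `foreground \ open(foreground)` and contains exactly the
#' structures the opening removed.
#'
#' @param foreground Logical (or 0/1) matrix.
#' @param params An [elongation_params()].
#' @return A logical residual matrix, always a subset of `foreground`.
#' @export
narrow_residual <- function(foreground, params) {
  stopifnot(inherits(params, "elongation_params"))
  fg <- as_binary(foreground)
  opened <- open_diamond(fg, params$n_erosions, params$n_dilations)
  if (any(opened & !fg)) stop("internal error: opening is not anti-extensive")
  fg & !opened
}

#' Deletion rule for residual objects
#'
#' An object is deleted when its area is smaller than `min_area_px2`, its
#' eccentricity smaller than `min_eccentricity`, or its major axis length
#' smaller than `min_major_axis_px` (strict inequalities: objects exactly
#' at a boundary survive).
#'
#' @param area_px2,eccentricity,major_axis_px Object feature vectors.
#' @param params An [elongation_params()].
#' @return Logical vector: `TRUE` for objects that are kept.
#' @export
residual_object_kept <- function(area_px2, eccentricity, major_axis_px, params) {
  stopifnot(inherits(params, "elongation_params"))
  !(area_px2 < params$min_area_px2 |
      eccentricity < params$min_eccentricity |
      major_axis_px < params$min_major_axis_px)
}

#' Filter residual objects by area, eccentricity and major axis length
#'
#' Labels the 4-connected components of the residual and deletes artifacts
#' per [residual_object_kept()]; survivors are relabeled 1..k with features
#' populated.
#'
#' @param residual Logical residual matrix from [narrow_residual()].
#' @param params An [elongation_params()].
#' @return A [label_mask()] of the surviving narrow structures.
#' @export
filter_residuals <- function(residual, params) {
  stopifnot(inherits(params, "elongation_params"))
  lab <- label_components(residual)
  lm <- region_features(label_mask(lab))
  keep <- lm$features$label[residual_object_kept(
    lm$features$area_px2, lm$features$eccentricity,
    lm$features$major_axis_px, params)]
  relabel_keep(lm$labels, keep)
}

#' Compute the elongation index of a stained field
#'
#' The elongation index quantifies how many elongated bipolar cells are
#' present and how pronounced their thin processes are: the stain is
#' smoothed and thresholded, narrow structures are isolated as the
#' XOR residual of a radius-8 diamond opening, artifacts are removed by
#' the area/eccentricity/major-axis filters, and the index is the sum of
#' the surviving objects' major axis lengths divided by the number of
#' marker-positive cells in the same field.
#'
#' @param stain A [calibrated_image()] (e.g. S100b).
#' @param n_positive_cells Positive-cell denominator (> 0), typically
#'   `n_positive` from the same field's marker classification; it is a
#'   required input, not recomputed here.
#' @param params An [elongation_params()].
#' @return An object of class `elongation_result` with fields `index`,
#'   `n_positive_cells`, `sum_major_axis_px` and `residual_objects` (a
#'   [label_mask()]).
#' @export
elongation_index <- function(stain, n_positive_cells, params) {
  stopifnot(inherits(params, "elongation_params"))
  if (!is.numeric(n_positive_cells) || length(n_positive_cells) != 1L ||
      !is.finite(n_positive_cells) || n_positive_cells <= 0) {
    stop("`n_positive_cells` must be a single value > 0: the index is undefined for an empty field")
  }
  fg <- segment_cells(stain, params)
  res <- narrow_residual(fg, params)
  objs <- filter_residuals(res, params)
  s <- sum(objs$features$major_axis_px)
  structure(list(index = s / n_positive_cells,
                 n_positive_cells = n_positive_cells,
                 sum_major_axis_px = s,
                 residual_objects = objs),
            class = "elongation_result")
}

#' @export
print.elongation_result <- function(x, ...) {
  cat(sprintf("<elongation_result> index %.3f (%d surviving objects, sum major axis %.1f px, %g positive cells)\n",
              x$index, n_objects(x$residual_objects), x$sum_major_axis_px,
              x$n_positive_cells))
  invisible(x)
}
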