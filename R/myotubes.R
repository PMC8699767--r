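#' Area threshold separating large from small myotubes
#'
#' Myotube populations are split at 200,000 square micrometers of
#' cytoplasmic area: strictly larger objects are "large", everything else
#' (including exactly the boundary value) is "small".
#' @export
LARGE_MYOTUBE_UM2 <- 200000

#' Measure myotube areas, size classes and coverage
#'
#' Works on any labeled myotube mask: automated segmentation
#' ([segment_myotubes_for_normalization()]) or imported manual outlines
#' ([polygons_to_label_mask()]). In automated mode connected components are
#' treated as individual myotubes (no declumping), which the output
#' metadata records.
#'
#' @param mask A [label_mask()] or integer label matrix.
#' @param pixel_size_um Micrometers per pixel edge.
#' @param image_area_px2 Area of the analyzed image in square pixels
#'   (denominator of percent coverage); defaults to the mask's own area.
#' @return A tibble of class `myotube_records` with one row per myotube:
#'   `id`, `area_px2`, `area_um2`, `size_class` (`"large"` iff
#'   `area_um2 > 200000`, strict), `coverage_percent`.
#' @export
measure_myotubes <- function(mask, pixel_size_um,
                             image_area_px2 = NULL) {
  lab <- if (inherits(mask, "label_mask")) mask$labels else mask
  stopifnot(pixel_size_um > 0)
  if (is.null(image_area_px2)) image_area_px2 <- prod(dim(lab))
  if (!is.finite(image_area_px2) || image_area_px2 <= 0) {
    stop("`image_area_px2` must be > 0: coverage is undefined without an image area")
  }
  n <- max(lab, 0L)
  area_px2 <- as.numeric(tabulate(lab[lab > 0L], nbins = n))
  if (sum(area_px2) > image_area_px2) {
    stop("`image_area_px2` must be at least the total object area")
  }
  area_um2 <- area_px2 * pixel_size_um^2
  out <- tibble::tibble(
    id = seq_len(n),
    area_px2 = area_px2,
    area_um2 = area_um2,
    size_class = ifelse(area_um2 > LARGE_MYOTUBE_UM2, "large", "small"),
    coverage_percent = 100 * area_px2 / image_area_px2)
  attr(out, "image_area_px2") <- image_area_px2
  attr(out, "pixel_size_um") <- pixel_size_um
  class(out) <- c("myotube_records", class(out))
  out
}

#' Percent coverage per myotube size class
#'
#' Sums per-myotube percent coverage within each size class for one image;
#' both classes are always reported (0 when a class is empty), and the two
#' class coverages sum exactly to the total myotube coverage.
#'
#' @param records A `myotube_records` tibble from [measure_myotubes()].
#' @return A tibble with columns `size_class` (`"large"`, `"small"`) and
#'   `coverage_percent`.
#' @export
coverage_by_class <- function(records) {
  stopifnot(inherits(records, "myotube_records"))
  tibble::tibble(
    size_class = c("large", "small"),
    coverage_percent = c(
      sum(records$coverage_percent[records$size_class == "large"]),
      sum(records$coverage_percent[records$size_class == "small"])))
}

#' Per-myotube distribution data for density curves
#'
#' Emits the raw per-myotube values plus log10-transformed coverage and
#' area, ready for kernel-density plotting on logarithmic axes; the KDE
#' bandwidth is an explicit parameter, never chosen silently. Degenerate
#' inputs (all values equal) are flagged instead of producing a density.
#'
#' @param records One or more `myotube_records` tibbles (a list is pooled).
#' @param bandwidth KDE bandwidth on the log10 area scale, or `NULL` to
#'   return data only.
#' @return A list with `data` (tibble: `area_um2`, `coverage_percent`,
#'   `log10_area_um2`, `log10_coverage_percent`, `size_class`),
#'   `degenerate` (logical), and `density` (a `stats::density` object on
#'   log10 area, or `NULL`).
#' @export
density_curve_data <- function(records, bandwidth = NULL) {
  if (inherits(records, "myotube_records")) records <- list(records)
  stopifnot(length(records) >= 1L)
  pooled <- dplyr::bind_rows(lapply(records, function(r) {
    tibble::tibble(area_um2 = r$area_um2,
                   coverage_percent = r$coverage_percent,
                   size_class = r$size_class)
  }))
  if (nrow(pooled) < 1L) stop("no myotube records supplied")
  pooled$log10_area_um2 <- log10(pooled$area_um2)
  pooled$log10_coverage_percent <- ifelse(pooled$coverage_percent > 0,
                                          log10(pooled$coverage_percent), NA_real_)
  degenerate <- length(unique(pooled$area_um2)) == 1L
  dens <- NULL
  if (!is.null(bandwidth) && !degenerate) {
    dens <- stats::density(pooled$log10_area_um2, bw = bandwidth)
  }
  list(data = pooled, degenerate = degenerate, density = dens)
}

#' Rasterize manually outlined myotube polygons to a label mask
#'
#' Supports the manual-outline workflow: each polygon (one per myotube) is
#' filled by even-odd ray casting over pixel centers. Polygons are supplied
#' as a data frame with columns `id`, `row`, `col` (vertices in order).
#'
#' @param polygons Data frame with columns `id`, `row`, `col`.
#' @param shape `(rows, cols)` of the target mask.
#' @return A [label_mask()] with polygons labeled in order of first
#'   appearance of their `id`.
#' @export
polygons_to_label_mask <- function(polygons, shape) {
  stopifnot(all(c("id", "row", "col") %in% names(polygons)))
  ids <- unique(polygons$id)
  lab <- matrix(0L, shape[1], shape[2])
  for (k in seq_along(ids)) {
    poly <- polygons[polygons$id == ids[k], ]
    pr <- poly$row; pc <- poly$col
    rs <- max(1L, floor(min(pr))):min(shape[1], ceiling(max(pr)))
    cs <- max(1L, floor(min(pc))):min(shape[2], ceiling(max(pc)))
    grid <- expand.grid(r = rs, c = cs)
    inside <- rep(FALSE, nrow(grid))
    nv <- length(pr)
    j <- nv
    for (i in seq_len(nv)) {
      crosses <- ((pr[i] > grid$r) != (pr[j] > grid$r)) &
        (grid$c < (pc[j] - pc[i]) * (grid$r - pr[i]) / (pr[j] - pr[i]) + pc[i])
      inside <- xor(inside, crosses)
      j <- i
    }
    lab[cbind(grid$r[inside], grid$c[inside])] <- k
  }
  region_features(label_mask(lab))
}

#' Read polygon outlines from CSV
#' @param path CSV with columns `id`, `row`, `col`.
#' @return A tibble of polygon vertices.
#' @export
read_polygons <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), row = readr::col_double(),
    col = readr::col_double()), progress = FALSE)
}
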