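#' Calibrated fluorescence image
#'
#' The unit every pipeline stage consumes: a 2D grid of non-negative
#' intensities (arbitrary fluorescence units) together with its physical
#' pixel size in micrometers per pixel edge and a free-text channel label
#' (e.g. "DAPI", "S100b", "aBTX").
#'
#' Geometry convention, used throughout the package: matrices are indexed
#' `[row, col]` with 1-based indices and origin at the top-left; the physical
#' length of a k-pixel run is `k * pixel_size_um` and the area of one pixel
#' is `pixel_size_um^2` square micrometers.
#'
#' @param pixels Numeric matrix of finite, non-negative intensities.
#' @param pixel_size_um Micrometers per pixel edge; a single value > 0.
#' @param channel Channel label (free text).
#' @return An object of class `calibrated_image` with fields `pixels`,
#'   `pixel_size_um` and `channel`.
#' @examples
#' img <- calibrated_image(matrix(0, 16, 16), pixel_size_um = 0.5, channel = "DAPI")
#' pixel_area_um2(img)
#' @export
calibrated_image <- function(pixels, pixel_size_um, channel = "unknown") {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("`pixels` must be a matrix with at least one row and one column")
  }
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels))) stop("`pixels` must be finite")
  if (any(pixels < 0)) stop("`pixels` must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single finite value > 0")
  }
  structure(
    list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
         channel = as.character(channel)[1L]),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %.4g um/px, channel '%s', range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$channel,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)

#' Physical area of one pixel in square micrometers
#' @param img A `calibrated_image`.
#' @return `pixel_size_um^2`, in square micrometers.
#' @export
pixel_area_um2 <- function(img) {
  stopifnot(inherits(img, "calibrated_image"))
  img$pixel_size_um^2
}

as_pixels <- function(x) {
  if (inherits(x, "calibrated_image")) x$pixels else x
}

check_same_shape <- function(a, b, what = "images") {
  da <- dim(as_pixels(a)); db <- dim(as_pixels(b))
  if (!identical(da, db)) {
    stop(sprintf("dimension mismatch between %s: %dx%d vs %dx%d",
                 what, da[1], da[2], db[1], db[2]))
  }
  invisible(TRUE)
}

#' Read a calibrated image from a grayscale TIFF or PNG file
#'
#' Intensities are read in their native integer range and are never rescaled
#' or normalized; integer inputs are preserved bit-exactly. The pixel size is
#' always supplied by the caller (acquisition calibration is not reliably
#' recorded in file metadata).
#'
#' @param path Path to a single-plane grayscale TIFF or PNG file.
#' @param pixel_size_um Micrometers per pixel edge (> 0).
#' @param channel Channel label to attach.
#' @param page For multi-page TIFFs, which page to read (1-based). Reading a
#'   multi-page file without `page` is an error naming the page count.
#' @return A [calibrated_image()].
#' @export
read_image <- function(path, pixel_size_um, channel = "unknown", page = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read image: '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    planes <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
    if (length(planes) > 1L && is.null(page)) {
      stop(sprintf("multi-plane TIFF with %d pages: supply `page` to select one",
                   length(planes)))
    }
    m <- planes[[if (is.null(page)) 1L else as.integer(page)]]
  } else if (ext == "png") {
    m <- png::readPNG(path)
    # readPNG rescales to [0,1]; recover native integers from the bit depth
    # recorded in the IHDR chunk (byte 25 of the file).
    hdr <- readBin(path, "raw", n = 25L)
    bits <- as.integer(hdr[25L])
    m <- round(m * (2^bits - 1))
  } else {
    stop(sprintf("unsupported image format '%s' (use TIFF or PNG)", ext))
  }
  if (length(dim(m)) == 3L) {
    if (dim(m)[3L] == 1L) m <- m[, , 1L]
    else stop("color images are not supported; supply one grayscale file per channel")
  }
  calibrated_image(m, pixel_size_um = pixel_size_um, channel = channel)
}

#' Write a calibrated image to a 16-bit grayscale TIFF
#'
#' Fluorescence intensities are stored on the native 16-bit integer scale:
#' integer-valued images round-trip bit-exactly through [read_image()];
#' fractional intensities are rounded to the nearest integer on export.
#' Values above 65535 are an error (rescale before writing).
#'
#' @param img A [calibrated_image()].
#' @param path Output path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "calibrated_image"))
  m <- round(img$pixels)
  if (max(m) > 65535) stop("intensities exceed the 16-bit range; rescale before writing")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
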