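# Shared numeric helpers: Gaussian smoothing, Otsu thresholding, and the
# zero-fill shift primitive used by the binary morphology and the Laplacian.

#' Gaussian smoothing of an intensity grid
#'
#' Separable Gaussian filtering in floating point with replicate (nearest
#' edge) boundary padding. `sigma = 0` disables smoothing and returns the
#' input unchanged, which the analytic elongation fixtures rely on.
#'
#' @param x Numeric matrix or [calibrated_image()].
#' @param sigma Gaussian standard deviation in pixels (>= 0).
#' @return A numeric matrix of the same shape.
#' @export
gauss_smooth <- function(x, sigma) {
  m <- as_pixels(x)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (sigma == 0) return(m)
  radius <- ceiling(3 * sigma)
  # filter2 requires the kernel to fit inside the image
  radius <- min(radius, floor((min(dim(m)) - 1) / 2))
  size <- 2L * radius + 1L
  kern <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  out <- EBImage::filter2(m, kern, boundary = "replicate")
  matrix(as.numeric(out), nrow(m), ncol(m))
}

#' Otsu threshold of an intensity grid
#'
#' @param x Numeric matrix or [calibrated_image()].
#' @param levels Number of histogram levels.
#' @return The threshold on the intensity scale of `x`; for a constant image
#'   the maximum value is returned (so that strict `>` yields an empty
#'   foreground).
#' @export
otsu_threshold <- function(x, levels = 256L) {
  m <- as_pixels(x)
  lo <- min(m); hi <- max(m)
  if (hi <= lo) return(hi)
  EBImage::otsu(m, range = c(lo, hi), levels = levels)
}

# Shift a matrix by (dr, dc) filling vacated cells with `fill`;
# result[i, j] = x[i + dr, j + dc] (or `fill` outside the image).
shift_mat <- function(x, dr, dc, fill) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(fill, nr, nc)
  r0 <- max(1L, 1L + dr); r1 <- min(nr, nr + dr)
  c0 <- max(1L, 1L + dc); c1 <- min(nc, nc + dc)
  if (r0 <= r1 && c0 <= c1) {
    rs <- r0:r1; cs <- c0:c1
    out[rs - dr, cs - dc] <- x[rs, cs, drop = FALSE]
  }
  out
}

as_binary <- function(x) {
  m <- as_pixels(x)
  if (is.logical(m)) return(m)
  m != 0
}
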