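# Independent oracles and geometric fixtures used across the suite.
# These deliberately avoid the package's own vectorized code paths.

# Exhaustive per-pixel neighborhood sweep morphology with the 3x3 diamond
# (center + 4 edge neighbors); pixels outside the image are background.
DIAMOND_DR <- c(0L, 1L, -1L, 0L, 0L)
DIAMOND_DC <- c(0L, 0L, 0L, 1L, -1L)

sweep_erode <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ok <- TRUE
    for (k in 1:5) {
      ii <- i + DIAMOND_DR[k]; jj <- j + DIAMOND_DC[k]
      v <- if (ii < 1L || ii > nr || jj < 1L || jj > nc) FALSE else x[ii, jj]
      if (!v) { ok <- FALSE; break }
    }
    out[i, j] <- ok
  }
  out
}

sweep_dilate <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    hit <- FALSE
    for (k in 1:5) {
      ii <- i + DIAMOND_DR[k]; jj <- j + DIAMOND_DC[k]
      if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc && x[ii, jj]) {
        hit <- TRUE; break
      }
    }
    out[i, j] <- hit
  }
  out
}

sweep_iterate <- function(x, n, f) {
  for (i in seq_len(n)) x <- f(x)
  x
}

# Brute-force moment oracle: explicit coordinate list, population covariance,
# eigen decomposition. Same pixel-center convention the package documents.
moment_oracle <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  mu <- unname(colMeans(idx))
  centered <- sweep(idx, 2, mu)
  C <- crossprod(centered) / n
  ev <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  ev <- pmax(ev, 0)
  major <- 4 * sqrt(ev[1])
  minor <- 4 * sqrt(ev[2])
  ecc <- if (ev[1] > 0) sqrt(max(1 - ev[2] / ev[1], 0)) else 0
  list(area = n, centroid = mu, major = major, minor = minor, ecc = ecc)
}

# Geometric fixtures -------------------------------------------------------

rect_mask <- function(shape, r0, c0, h, w) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- TRUE
  m
}

disc_mask_at <- function(shape, center, radius) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) {
    if ((i - center[1])^2 + (j - center[2])^2 <= radius^2) m[i, j] <- TRUE
  }
  m
}

# L1 ball (diamond) of the given radius centered in the image.
diamond_ball <- function(shape, center, radius) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) {
    if (abs(i - center[1]) + abs(j - center[2]) <= radius) m[i, j] <- TRUE
  }
  m
}

# Capsule rendered independently of the package's generator: all pixels
# within width/2 of the central segment (total length includes the caps).
capsule_mask_at <- function(shape, center, length, width, theta) {
  half_seg <- (length - width) / 2
  u <- c(cos(theta), sin(theta))
  m <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) {
    dr <- i - center[1]; dc <- j - center[2]
    t <- min(max(dr * u[1] + dc * u[2], -half_seg), half_seg)
    if ((dr - t * u[1])^2 + (dc - t * u[2])^2 <= (width / 2)^2) m[i, j] <- TRUE
  }
  m
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Greedy matching of detections to ground-truth points within a radius.
match_points <- function(truth, detected, radius) {
  if (nrow(truth) == 0L || nrow(detected) == 0L) {
    return(list(recall = 0, precision = 0, n_matched = 0L))
  }
  D <- sqrt(outer(truth[, 1], detected[, 1], "-")^2 +
            outer(truth[, 2], detected[, 2], "-")^2)
  matched_t <- rep(FALSE, nrow(truth)); matched_d <- rep(FALSE, nrow(detected))
  repeat {
    D2 <- D
    D2[matched_t, ] <- Inf; D2[, matched_d] <- Inf
    if (all(!is.finite(D2)) || min(D2) > radius) break
    k <- arrayInd(which.min(D2), dim(D2))
    matched_t[k[1]] <- TRUE; matched_d[k[2]] <- TRUE
  }
  list(recall = mean(matched_t), precision = mean(matched_d),
       n_matched = sum(matched_t))
}

# Random binary grid with tunable density.
random_grid <- function(shape, p = 0.5) {
  matrix(stats::runif(prod(shape)) < p, shape[1], shape[2])
}
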