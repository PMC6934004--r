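# Shared numeric helpers.

#' Proton gyromagnetic ratio
#'
#' The gyromagnetic ratio of the proton, in rad s^-1 T^-1. Fixed constant used
#' throughout the background-gradient and sinc-dephasing computations.
#' @export
GAMMA_PROTON <- 2.675222e8

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap phase to (-pi, pi]
#'
#' @param phi numeric vector/array of phase values in radians.
#' @return values wrapped into the half-open interval (-pi, pi].
#' @export
wrap_phase <- function(phi) {
  w <- phi - 2 * pi * round(phi / (2 * pi))
  # round() maps pi -> wrapped -pi on some inputs; enforce (-pi, pi]
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' Unnormalized sinc
#'
#' sin(x)/x with radian argument and sinc(0) = 1. This is the convention under
#' which the through-slice dephasing factor sinc(gamma/2 * gz * dz * TE) has
#' its first null at full dephasing gamma*gz*dz*TE = 2*pi.
#' @param x numeric, radians.
#' @export
sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- abs(x) > .Machine$double.eps
  out[nz] <- sin(x[nz]) / x[nz]
  dim(out) <- dim(x)
  out
}

#' Interpolated histogram mode
#'
#' Mode estimator shared by the CSF calibration and the retest summary:
#' a histogram over the central `trim` quantile range with `bins` bins, and
#' parabolic interpolation through the maximal bin and its two neighbours.
#'
#' @param x numeric vector of samples (non-finite values dropped).
#' @param bins number of histogram bins (default 128).
#' @param trim central probability mass covered by the histogram range
#'   (default 0.99, i.e. quantiles 0.005 to 0.995).
#' @return the estimated mode (scalar).
#' @export
hist_mode <- function(x, bins = 128L, trim = 0.99) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop("hist_mode: need at least 3 finite samples")
  p <- (1 - trim) / 2
  rng <- stats::quantile(x, c(p, 1 - p), names = FALSE, type = 7)
  if (diff(rng) <= 0) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  xs <- x[x >= rng[1] & x <= rng[2]]
  counts <- tabulate(pmin(pmax(findInterval(xs, edges, rightmost.closed = TRUE), 1L), bins),
                     nbins = bins)
  i <- which.max(counts)
  centers <- (edges[-1] + edges[-(bins + 1L)]) / 2
  if (i == 1L || i == bins) return(centers[i])
  # parabola through (i-1, i, i+1)
  y1 <- counts[i - 1L]; y2 <- counts[i]; y3 <- counts[i + 1L]
  denom <- (y1 - 2 * y2 + y3)
  delta <- if (denom == 0) 0 else 0.5 * (y1 - y3) / denom
  delta <- max(min(delta, 0.5), -0.5)
  centers[i] + delta * (centers[2] - centers[1])
}

# 1D DCT-II basis matrix: n samples x k components (k includes the DC term).
# Columns are orthonormal on the sample grid.
dct_basis <- function(n, k) {
  x <- seq_len(n) - 1L
  B <- sapply(seq_len(k) - 1L, function(j) cos(pi * (2 * x + 1) * j / (2 * n)))
  B <- matrix(B, nrow = n)
  B[, 1] <- B[, 1] / sqrt(n)
  if (k > 1) B[, -1] <- B[, -1] * sqrt(2 / n)
  B
}

# Evaluate a separable 3D DCT expansion at given voxel indices.
# coords: matrix nvox x 3 of 1-based voxel indices; dims: c(nx,ny,nz);
# order: components per axis. Returns design matrix nvox x (order^3).
dct_design <- function(coords, dims, order) {
  Bx <- dct_basis(dims[1], order)[coords[, 1], , drop = FALSE]
  By <- dct_basis(dims[2], order)[coords[, 2], , drop = FALSE]
  Bz <- dct_basis(dims[3], order)[coords[, 3], , drop = FALSE]
  nvox <- nrow(coords)
  A <- matrix(0, nvox, order^3)
  col <- 1L
  for (kz in seq_len(order)) for (ky in seq_len(order)) for (kx in seq_len(order)) {
    A[, col] <- Bx[, kx] * By[, ky] * Bz[, kz]
    col <- col + 1L
  }
  A
}

# voxel index grid for a 3D array: nvox x 3 integer matrix
voxel_grid <- function(dims) {
  as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                        z = seq_len(dims[3]), KEEP.OUT.ATTRS = FALSE))
}
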