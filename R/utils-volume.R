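## Low-level 3-D volume utilities shared by the phantom, warp and inference
## code. All fields live on the voxel lattice; coordinates are 1-based voxel
## indices, displacements are in voxel units (voxel size carries the mm scale).

#' Trilinear interpolation of a 3-D volume at arbitrary voxel coordinates
#'
#' Samples `vol` at continuous 1-based voxel coordinates. Coordinates outside
#' the grid are either clamped to the boundary (`mode = "clamp"`) or returned
#' as `fill` (`mode = "fill"`).
#'
#' @param vol 3-D numeric array.
#' @param x,y,z numeric vectors of equal length, 1-based voxel coordinates.
#' @param mode boundary handling, `"clamp"` or `"fill"`.
#' @param fill value used outside the grid when `mode = "fill"`.
#' @return numeric vector of sampled values.
#' @keywords internal
interpTrilinear <- function(vol, x, y, z, mode = c("clamp", "fill"), fill = NA_real_) {
  mode <- match.arg(mode)
  d <- dim(vol)
  outside <- x < 1 | x > d[1] | y < 1 | y > d[2] | z < 1 | z > d[3]
  if (mode == "clamp" || any(outside)) {
    x <- pmin(pmax(x, 1), d[1])
    y <- pmin(pmax(y, 1), d[2])
    z <- pmin(pmax(z, 1), d[3])
  }
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L); z0 <- pmin(floor(z), d[3] - 1L)
  if (d[1] == 1L) x0 <- rep(1, length(x))
  if (d[2] == 1L) y0 <- rep(1, length(y))
  if (d[3] == 1L) z0 <- rep(1, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  ix <- function(a, b, c) ((c - 1) * d[2] + (b - 1)) * d[1] + a
  v <- vol
  dim(v) <- NULL
  out <-
    v[ix(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    v[ix(x1, y0, z0)] * fx       * (1 - fy) * (1 - fz) +
    v[ix(x0, y1, z0)] * (1 - fx) * fy       * (1 - fz) +
    v[ix(x1, y1, z0)] * fx       * fy       * (1 - fz) +
    v[ix(x0, y0, z1)] * (1 - fx) * (1 - fy) * fz +
    v[ix(x1, y0, z1)] * fx       * (1 - fy) * fz +
    v[ix(x0, y1, z1)] * (1 - fx) * fy       * fz +
    v[ix(x1, y1, z1)] * fx       * fy       * fz
  if (mode == "fill" && any(outside)) out[outside] <- fill
  out
}

#' Voxel-coordinate grids for a 3-D volume
#' @param d integer length-3 grid shape.
#' @return list of three arrays `x`, `y`, `z` of dim `d`.
#' @keywords internal
coordinateGrids <- function(d) {
  list(
    x = array(rep(seq_len(d[1]), times = d[2] * d[3]), dim = d),
    y = array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), dim = d),
    z = array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  )
}

#' Gaussian smoothing of a 3-D volume by FFT convolution
#'
#' Circular (periodic) convolution with a separable Gaussian kernel. Periodic
#' wrap-around is acceptable for the fields used here (noise fields, demons
#' regularization) because the objects of interest sit away from the faces.
#'
#' @param vol 3-D numeric array.
#' @param sigma kernel standard deviation in voxels (scalar or per-axis).
#' @return smoothed array, same dim.
#' @keywords internal
smoothGaussianFFT <- function(vol, sigma) {
  d <- dim(vol)
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  if (all(sigma <= 0)) return(vol)
  k1 <- function(n, s) {
    if (s <= 0) return(c(1, rep(0, n - 1L)))
    half <- seq(0, n - 1L)
    half <- pmin(half, n - half)          # circular distance
    k <- exp(-0.5 * (half / s)^2)
    k / sum(k)
  }
  kern <- outer(outer(k1(d[1], sigma[1]), k1(d[2], sigma[2])), k1(d[3], sigma[3]))
  dim(kern) <- d
  Re(stats::fft(stats::fft(vol) * stats::fft(kern), inverse = TRUE)) / prod(d)
}

#' Stationary Gaussian random field with a target smoothness
#'
#' White Gaussian noise convolved (circularly) with a Gaussian kernel of the
#' given FWHM and rescaled to unit marginal variance. Used for null-field
#' simulation in the cluster-inference calibration.
#'
#' @param d length-3 grid shape.
#' @param fwhm kernel full width at half maximum in voxels (scalar or per axis).
#' @return 3-D array with (near-)unit variance and Gaussian autocorrelation.
#' @export
gaussianRandomField <- function(d, fwhm) {
  sigma <- fwhm / sqrt(8 * log(2))
  noise <- array(stats::rnorm(prod(d)), dim = d)
  if (all(sigma <= 0)) return(noise)
  sm <- smoothGaussianFFT(noise, sigma)
  ## circular convolution of unit white noise has variance sum(kernel^2)
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  k2 <- 1
  for (i in 1:3) {
    half <- seq(0, d[i] - 1L); half <- pmin(half, d[i] - half)
    k <- exp(-0.5 * (half / max(sigma[i], 1e-12))^2); k <- k / sum(k)
    k2 <- k2 * sum(k^2)
  }
  sm / sqrt(k2)
}

#' Central-difference spatial gradient of a 3-D volume
#'
#' One-sided differences at the grid faces, central differences inside.
#'
#' @param vol 3-D numeric array.
#' @return list of three arrays `gx`, `gy`, `gz` (per-voxel units).
#' @keywords internal
volumeGradient <- function(vol, spacing = c(1, 1, 1)) {
  d <- dim(vol)
  gAxis <- function(v, axis) {
    n <- d[axis]
    idxPlus <- pmin(seq_len(n) + 1L, n)
    idxMinus <- pmax(seq_len(n) - 1L, 1L)
    denom <- (idxPlus - idxMinus) * spacing[axis]
    sel <- function(idx) {
      args <- list(v, 1:d[1], 1:d[2], 1:d[3])
      args[[axis + 1L]] <- idx
      do.call(`[`, args)
    }
    g <- (sel(idxPlus) - sel(idxMinus))
    shape <- c(1, 1, 1); shape[axis] <- n
    sweep(g, axis, denom, "/")
  }
  list(gx = gAxis(vol, 1L), gy = gAxis(vol, 2L), gz = gAxis(vol, 3L))
}

#' Block-mean downsampling of a 3-D volume by a factor of two
#' @keywords internal
downsampleVolume <- function(vol) {
  d <- dim(vol)
  nd <- pmax(d %/% 2L, 1L)
  x <- pmin(2L * seq_len(nd[1]), d[1]); x0 <- x - 1L
  y <- pmin(2L * seq_len(nd[2]), d[2]); y0 <- y - 1L
  z <- pmin(2L * seq_len(nd[3]), d[3]); z0 <- z - 1L
  (vol[x0, y0, z0, drop = FALSE] + vol[x, y0, z0, drop = FALSE] +
   vol[x0, y, z0, drop = FALSE] + vol[x, y, z0, drop = FALSE] +
   vol[x0, y0, z, drop = FALSE] + vol[x, y0, z, drop = FALSE] +
   vol[x0, y, z, drop = FALSE] + vol[x, y, z, drop = FALSE]) / 8
}

#' Monomial basis for low-order 3-D polynomial fields
#'
#' Coordinates are scaled to [-1, 1] per axis before taking powers, which keeps
#' the regression well conditioned up to order 4.
#'
#' @param d grid shape.
#' @param order maximum total degree.
#' @param subset optional logical/integer index of voxels to evaluate.
#' @return design matrix, one column per monomial (including the constant).
#' @keywords internal
polyBasis3D <- function(d, order, subset = NULL) {
  g <- coordinateGrids(d)
  sc <- function(v, n) if (n > 1) 2 * (v - 1) / (n - 1) - 1 else v * 0
  x <- sc(as.numeric(g$x), d[1]); y <- sc(as.numeric(g$y), d[2]); z <- sc(as.numeric(g$z), d[3])
  if (!is.null(subset)) { x <- x[subset]; y <- y[subset]; z <- z[subset] }
  cols <- list(); nm <- character(0)
  for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j)) {
    cols[[length(cols) + 1L]] <- x^i * y^j * z^k
    nm <- c(nm, paste0("x", i, "y", j, "z", k))
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nm
  m
}

#' @keywords internal
logSumExpRows <- function(m) {
  mx <- do.call(pmax, as.data.frame(m))
  mx + log(rowSums(exp(m - mx)))
}

#' Erode a logical mask (6-connectivity)
#'
#' Removes `iterations` shells of voxels adjacent to the mask complement.
#' Used to exclude partial-volume boundary voxels from analysis masks.
#'
#' @param mask logical 3-D array.
#' @param iterations number of one-voxel erosion passes.
#' @return eroded logical array.
#' @export
erodeMask <- function(mask, iterations = 1) {
  d <- dim(mask)
  for (i in seq_len(iterations)) {
    m <- array(FALSE, d + 2L)
    m[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
    keep <- m[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
      m[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] & m[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
      m[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] & m[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
      m[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] & m[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
    mask <- keep
  }
  mask
}


## sum of a 4-D stack over its 4th (class) dimension, returned as 3-D array
## (fast replacement for apply(x, 1:3, sum))
sumOverClasses <- function(stack) {
  d <- dim(stack)
  array(rowSums(matrix(stack, ncol = d[4])), d[1:3])
}

## row-wise maximum of the class dimension (fast argmax companion)
maxOverClasses <- function(stack) {
  d <- dim(stack)
  m <- matrix(stack, ncol = d[4])
  array(do.call(pmax, as.data.frame(m)), d[1:3])
}
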