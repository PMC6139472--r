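# Shared internal helpers: seeding, affines, causal convolution.

#' @importFrom stats rnorm dgamma cor sd var predict
#' @importFrom utils read.csv write.csv read.delim
NULL

# Evaluate expr under a fixed RNG seed (restoring the caller's RNG state),
# or as-is when seed is NULL.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Derive a set of sub-seeds from one master seed; values stay below 2^31.
derive_seeds <- function(seed, n) {
  with_seed_or_not(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Build a diagonal RAS+ affine for a centered grid
#'
#' Voxel-to-world map for an isotropic grid whose center sits at the world
#' origin. Voxel indices are 0-based in the affine convention (NIfTI style);
#' R array indices are these plus one.
#'
#' @param grid_shape integer vector of 3 grid dimensions.
#' @param voxel_size voxel edge length in mm (default 3).
#' @return a 4x4 matrix mapping homogeneous 0-based voxel indices to mm.
#' @export
make_affine <- function(grid_shape, voxel_size = 3) {
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0), voxel_size > 0)
  aff <- diag(c(rep(voxel_size, 3), 1))
  aff[1:3, 4] <- -(grid_shape - 1) / 2 * voxel_size
  aff
}

# World mm -> fractional 0-based voxel coordinates.
mm_to_voxel <- function(affine, mm) {
  mm <- rbind(matrix(mm, ncol = 3))
  xyz1 <- cbind(mm, 1)
  v <- t(solve(affine) %*% t(xyz1))
  v[, 1:3, drop = FALSE]
}

# 0-based voxel coordinates -> world mm.
voxel_to_mm <- function(affine, voxel) {
  voxel <- rbind(matrix(voxel, ncol = 3))
  v <- t(affine %*% t(cbind(voxel, 1)))
  v[, 1:3, drop = FALSE]
}

# Round half away from zero (deterministic tie-break for voxel centers;
# base R round() rounds half to even).
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

#' Causal convolution truncated to the input length
#'
#' Convolves a series with a kernel and keeps the first `length(x)` samples,
#' so output sample t depends only on inputs at times <= t.
#'
#' @param x numeric vector, or a matrix with time in rows (each column one
#'   series).
#' @param kernel numeric kernel sampled at the same interval as `x`.
#' @return object of the same shape as `x`.
#' @export
conv_causal <- function(x, kernel) {
  kernel <- as.numeric(kernel)
  if (is.matrix(x)) {
    H <- conv_matrix(nrow(x), kernel)
    return(H %*% x)
  }
  n <- length(x)
  full <- stats::convolve(x, rev(kernel), type = "open")
  full[seq_len(n)]
}

# n x n lower-banded Toeplitz convolution operator for a causal kernel.
conv_matrix <- function(n, kernel) {
  kernel <- as.numeric(kernel)
  k <- length(kernel)
  H <- matrix(0, n, n)
  for (d in seq_len(min(k, n))) {
    idx <- seq_len(n - d + 1)
    H[cbind(idx + d - 1, idx)] <- kernel[d]
  }
  H
}

# Remove intercept + linear trend by least squares. Accepts a vector or a
# matrix with time in rows; returns the same shape.
.detrend_mat <- function(X) {
  n <- nrow(X)
  tt <- seq_len(n) - (n + 1) / 2
  Q <- qr.Q(qr(cbind(rep(1, n), tt)))
  X - Q %*% crossprod(Q, X)
}

#' Remove intercept and linear trend from a time-series
#'
#' Least-squares projection removing the constant and linear components, so
#' the output has zero mean and zero fitted slope.
#'
#' @param series numeric vector, or matrix with time in rows.
#' @return detrended object of the same shape.
#' @export
detrend_series <- function(series) {
  if (is.matrix(series)) {
    stopifnot(nrow(series) >= 3)
    return(.detrend_mat(series))
  }
  stopifnot(length(series) >= 3)
  drop(.detrend_mat(matrix(series, ncol = 1)))
}
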