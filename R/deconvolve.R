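# Regularized hemodynamic deconvolution: ridge inversion of the causal
# Toeplitz convolution operator, with generalized cross-validation (GCV) for
# the penalty when none is given.

# Precompute the SVD of the n x n causal convolution operator for a kernel.
# Reused across the many voxel series of one run (the operator depends only
# on run length and kernel).
deconv_operator <- function(n, kernel) {
  H <- conv_matrix(n, kernel)
  sv <- svd(H)
  structure(list(n = n, kernel = kernel, u = sv$u, d = sv$d, v = sv$v),
            class = "fc_deconv_op")
}

# Default lambda grid for GCV (absolute scale; the kernel is unit-sum so
# singular values are O(1)).
.gcv_grid <- function() 10^seq(-6, 2, length.out = 33)

# Core solver: Y is n x m (time in rows). Returns list(coef, lambda) where
# lambda is per-column (GCV-chosen when lambda = NULL).
.deconv_solve <- function(op, Y, lambda = NULL, lambda_grid = .gcv_grid()) {
  n <- op$n
  d2 <- op$d^2
  UY <- crossprod(op$u, Y)                       # rotated data, n x m
  if (is.null(lambda)) {
    m <- ncol(Y)
    best_gcv <- rep(Inf, m)
    best_lam <- rep(lambda_grid[1], m)
    for (lam in lambda_grid) {
      f <- d2 / (d2 + lam)
      resid <- colSums(((1 - f) * UY)^2)
      df <- sum(f)
      g <- n * resid / (n - df)^2
      take <- g < best_gcv
      best_gcv[take] <- g[take]
      best_lam[take] <- lam
    }
    lambda <- best_lam
  } else {
    if (length(lambda) == 1 && lambda == 0) {
      if (min(op$d) / max(op$d) < 1e-12)
        stop("convolution operator is numerically singular at lambda = 0; ",
             "supply a positive regularization lambda")
    }
    lambda <- rep(lambda, length.out = ncol(Y))
  }
  coef <- matrix(0, n, ncol(Y))
  for (lam in unique(lambda)) {
    cols <- which(lambda == lam)
    w <- op$d / (d2 + lam)
    coef[, cols] <- op$v %*% (w * UY[, cols, drop = FALSE])
  }
  list(coef = coef, lambda = lambda)
}

#' Deconvolve BOLD series to neural-level series
#'
#' Inverts the causal HRF convolution by ridge-regularized least squares on
#' the Toeplitz operator. The penalty `lambda` is chosen per series by
#' generalized cross-validation when not supplied. The noiseless contract is
#' exact recovery up to the (tiny) ridge bias; with noise, the recoverable
#' content is the part of the source spectrum the HRF does not annihilate, so
#' quality is assessed on the reconvolved signal (see the methods vignette).
#'
#' @param series numeric vector, or matrix with time in rows (one column per
#'   voxel series).
#' @param hrf an [canonical_hrf()] object or bare numeric kernel sampled at
#'   the series' TR.
#' @param lambda ridge penalty; `NULL` (default) selects it per series by
#'   GCV. `lambda = 0` is refused when the operator is numerically singular.
#' @param lambda_grid grid searched by GCV.
#' @return deconvolved object of the same shape as `series`, with attribute
#'   `"lambda"` giving the penalty used per series.
#' @examples
#' h <- canonical_hrf(2)
#' n <- rnorm(100)
#' y <- conv_causal(c(n, numeric(length(h$values) - 1)), h$values)
#' nhat <- deconvolve_bold(y, h, lambda = 1e-6)
#' @export
deconvolve_bold <- function(series, hrf, lambda = NULL,
                            lambda_grid = .gcv_grid()) {
  kernel <- hrf_values(hrf)
  vec <- !is.matrix(series)
  Y <- if (vec) matrix(series, ncol = 1) else series
  if (nrow(Y) < length(kernel))
    stop("series length (", nrow(Y), ") must be at least the kernel length (",
         length(kernel), ")")
  op <- deconv_operator(nrow(Y), kernel)
  out <- .deconv_solve(op, Y, lambda = lambda, lambda_grid = lambda_grid)
  res <- if (vec) drop(out$coef) else out$coef
  attr(res, "lambda") <- out$lambda
  res
}
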