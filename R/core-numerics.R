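# Regularized Heaviside/Dirac pair and replicate-padded Gaussian smoothing.
# These primitives are shared by every region term in the model.

#' Regularized Heaviside function
#'
#' Smooth arctangent surrogate for the unit step,
#' \deqn{H_\epsilon(z) = \frac{1}{2}\left(1 + \frac{2}{\pi}
#'   \arctan\frac{z}{\epsilon}\right),}
#' used to turn region integrals over the sign of the level-set field into
#' differentiable quantities. Output lies strictly inside \eqn{(0, 1)} and is
#' strictly increasing in \code{z}; its derivative is [diracEps()].
#'
#' @param z Numeric scalar, vector or matrix (typically a level-set field).
#' @param eps Regularization width, positive. The model's reference value is
#'   0.3; the classical Chan-Vese setting uses 1.0.
#'
#' @return Same shape as \code{z}, values in \eqn{(0, 1)}.
#' @examples
#' heavisideEps(0, 1)            # 0.5
#' heavisideEps(1, 0.3) + heavisideEps(-1, 0.3)  # 1
#' @export
heavisideEps <- function(z, eps) {
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop("'eps' must be a single positive number")
  0.5 * (1 + (2 / pi) * atan(z / eps))
}

#' Regularized Dirac delta
#'
#' The derivative of [heavisideEps()]:
#' \deqn{\delta_\epsilon(z) = \frac{1}{\pi}\,
#'   \frac{\epsilon}{\epsilon^2 + z^2}.}
#' Even in \code{z}, with maximum \eqn{1/(\pi\epsilon)} at \eqn{z = 0} and unit
#' total integral. In the four-phase flow it localizes the update around the
#' zero crossing of each level-set field; small \code{eps} narrows the
#' effective band (risking local minima), large \code{eps} blurs the final
#' contour placement.
#'
#' @inheritParams heavisideEps
#' @return Same shape as \code{z}, non-negative.
#' @examples
#' diracEps(0, 0.3)  # 1 / (0.3 * pi)
#' @export
diracEps <- function(z, eps) {
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop("'eps' must be a single positive number")
  (1 / pi) * eps / (eps^2 + z^2)
}

# One-dimensional convolution operator with replicate (edge-value) padding,
# expressed as a dense n x n row-stochastic matrix. Out-of-range taps clamp to
# the nearest edge index, so each row still sums to exactly the kernel mass
# and constant fields are fixed points.
.convOperator <- function(n, weights) {
  r <- (length(weights) - 1L) %/% 2L
  M <- matrix(0, n, n)
  idx <- seq_len(n)
  for (k in seq_along(weights)) {
    j <- pmin(pmax(idx + (k - r - 1L), 1L), n)
    M[cbind(idx, j)] <- M[cbind(idx, j)] + weights[k]
  }
  M
}

#' Gaussian smoothing of a 2-D field
#'
#' Convolves a matrix with the separable 2-D Gaussian kernel (the outer
#' product of the kernel's normalized 1-D weights) under replicate boundary
#' padding. Because every output pixel is a convex combination of input
#' pixels, the result is bounded by the input's range, a constant field passes
#' through unchanged, and smoothing commutes with adding a constant.
#'
#' @param field Numeric matrix with finite values.
#' @param kernel A [SmoothingKernel-class], or a single positive number taken
#'   as \code{sigma} for [smoothingKernel()].
#'
#' @return Matrix of the same shape.
#' @examples
#' gaussianConvolve(matrix(1, 5, 5), 1)  # still all ones
#' @export
gaussianConvolve <- function(field, kernel) {
  if (is.numeric(kernel) && length(kernel) == 1L)
    kernel <- smoothingKernel(kernel)
  stopifnot(is(kernel, "SmoothingKernel"))
  if (!is.matrix(field) || length(field) == 0L)
    stop("'field' must be a non-empty numeric matrix")
  if (any(!is.finite(field))) stop("'field' must be finite-valued")
  w <- kernel@weights
  R <- .convOperator(nrow(field), w)
  C <- .convOperator(ncol(field), w)
  R %*% field %*% t(C)
}
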