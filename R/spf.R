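# Signed pressure force construction: global region means (Chan-Vese style),
# kernel-weighted local fits (LBF style), local-contrast adaptive weight, and
# their convex combination. Every SPF is normalized by its maximum absolute
# value, so it lies in [-1, 1] and attains |1| on any non-constant input.

.DENOM_FLOOR <- 1e-12

.checkImage <- function(image) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0L)
    stop("'image' must be a non-empty numeric matrix")
  if (any(!is.finite(image))) stop("'image' contains non-finite intensities")
  invisible(image)
}

.checkSameShape <- function(a, b, what = "fields") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must have the same shape", what))
}

#' Global region mean intensities
#'
#' The Chan-Vese region statistics: mean image intensity weighted by the
#' regularized Heaviside of the level-set field (inside, \code{c1}) and by its
#' complement (outside, \code{c2}),
#' \deqn{c_1 = \frac{\sum I\,H_\epsilon(\phi)}{\sum H_\epsilon(\phi)}, \qquad
#'       c_2 = \frac{\sum I\,(1 - H_\epsilon(\phi))}{\sum (1 -
#'       H_\epsilon(\phi))}.}
#' If one side has essentially no mass (weight sum below 1e-12, e.g. a
#' single-signed field with tiny \code{eps}), that side falls back to the
#' global image mean with a warning.
#'
#' @param image Numeric matrix of intensities.
#' @param phi Level-set field, same shape.
#' @param epsH Heaviside regularization width.
#'
#' @return Named numeric vector \code{c(c1 = ..., c2 = ...)}.
#' @export
globalRegionMeans <- function(image, phi, epsH = 0.3) {
  .checkImage(image)
  .checkSameShape(image, phi, "'image' and 'phi'")
  h <- heavisideEps(phi, epsH)
  sideMean <- function(w, side) {
    sw <- sum(w)
    if (sw < .DENOM_FLOOR) {
      warning(sprintf("degenerate %s region; using global image mean", side))
      return(mean(image))
    }
    sum(image * w) / sw
  }
  c(c1 = sideMean(h, "inside"), c2 = sideMean(1 - h, "outside"))
}

#' Local intensity fitting functions
#'
#' The LBF-style spatially varying fits: at each pixel, the kernel-weighted
#' mean intensity of the local interior and local exterior of the contour,
#' \deqn{f_1 = \frac{K_\sigma * (H_\epsilon(\phi)\, I)}
#'                  {K_\sigma * H_\epsilon(\phi)}, \qquad
#'       f_2 = \frac{K_\sigma * ((1 - H_\epsilon(\phi))\, I)}
#'                  {K_\sigma * (1 - H_\epsilon(\phi))}.}
#' Denominators are floored at 1e-12, which only engages where one side has
#' essentially no kernel mass. Both fits are convex averages of image values,
#' hence bounded by the image range.
#'
#' @inheritParams globalRegionMeans
#' @param kernel Fitting kernel: a [SmoothingKernel-class] or a numeric
#'   \code{sigma} (model default 5).
#'
#' @return List with matrices \code{f1} and \code{f2}.
#' @export
localFittingFunctions <- function(image, phi, kernel = 5, epsH = 0.3) {
  .checkImage(image)
  .checkSameShape(image, phi, "'image' and 'phi'")
  if (is.numeric(kernel) && length(kernel) == 1L)
    kernel <- smoothingKernel(kernel)
  h <- heavisideEps(phi, epsH)
  fit <- function(w) {
    den <- gaussianConvolve(w, kernel)
    num <- gaussianConvolve(w * image, kernel)
    num / pmax(den, .DENOM_FLOOR)
  }
  list(f1 = fit(h), f2 = fit(1 - h))
}

# Normalize a raw force field by its max absolute value; all-zero (constant
# image) input maps to an all-zero force, the only self-consistent choice.
.normalizeSPF <- function(raw) {
  m <- max(abs(raw))
  if (m < .DENOM_FLOOR) return(array(0, dim(raw)))
  raw / m
}

#' Global signed pressure force
#'
#' \deqn{s_g(x) = \frac{I(x) - (c_1 + c_2)/2}
#'                    {\max_x |I(x) - (c_1 + c_2)/2|}.}
#' Positive where the image exceeds the midpoint of the two region means,
#' negative below it; with a positive balloon force this expands the positive
#' phase into bright pixels. A constant image yields the all-zero force.
#'
#' @param image Numeric matrix.
#' @param means Output of [globalRegionMeans()] (any numeric vector with
#'   elements \code{c1}, \code{c2}).
#' @return Matrix in \eqn{[-1, 1]}.
#' @export
spfGlobal <- function(image, means) {
  .checkImage(image)
  if (any(!is.finite(means))) stop("'means' must be finite")
  .normalizeSPF(image - (means[["c1"]] + means[["c2"]]) / 2)
}

#' Local signed pressure force
#'
#' Same construction as [spfGlobal()] with the pointwise local fits replacing
#' the global means:
#' \deqn{s_l(x) = \frac{I(x) - (f_1(x) + f_2(x))/2}
#'                    {\max_x |I(x) - (f_1(x) + f_2(x))/2|}.}
#' Because \eqn{f_1, f_2} track the local intensity level, the sign of
#' \eqn{s_l} stays correct under smooth intensity inhomogeneity where a single
#' global midpoint fails.
#'
#' @param image Numeric matrix.
#' @param fits Output of [localFittingFunctions()] (list with \code{f1},
#'   \code{f2}).
#' @return Matrix in \eqn{[-1, 1]}.
#' @export
spfLocal <- function(image, fits) {
  .checkImage(image)
  if (any(!is.finite(fits$f1)) || any(!is.finite(fits$f2)))
    stop("'fits' must be finite")
  .checkSameShape(image, fits$f1, "'image' and 'fits'")
  .normalizeSPF(image - (fits$f1 + fits$f2) / 2)
}

#' Local Michelson contrast
#'
#' Contrast ratio over a sliding window (default 5x5, replicate padding):
#' \deqn{C_R(x) = \frac{\max_R I - \min_R I}{\max_R I + \min_R I + \eta},
#'   \qquad \eta = 10^{-8}.}
#' Zero on flat regions, large near region boundaries, invariant to positive
#' rescaling of the image (up to \eqn{\eta}), and bounded in \eqn{[0, 1)} for
#' non-negative images.
#'
#' @param image Numeric matrix (non-negative intensities expected).
#' @param window Odd window side length, at least 3.
#' @return Non-negative matrix.
#' @export
localContrast <- function(image, window = 5L) {
  .checkImage(image)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3")
  r <- window %/% 2L
  nr <- nrow(image); nc <- ncol(image)
  mx <- mn <- NULL
  for (dy in -r:r) {
    ri <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
    for (dx in -r:r) {
      ci <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
      s <- image[ri, ci, drop = FALSE]
      if (is.null(mx)) { mx <- s; mn <- s }
      else { mx <- pmax(mx, s); mn <- pmin(mn, s) }
    }
  }
  (mx - mn) / (mx + mn + 1e-8)
}

#' Adaptive local/global balance weight
#'
#' \deqn{\omega(x) = \exp\!\left(-\beta\,
#'   \frac{C_R(x)}{\overline{C_R}}\right),}
#' where \eqn{\overline{C_R}} is the image-wide mean contrast. \eqn{\omega}
#' lies in \eqn{(0, 1]} and decreases with contrast: in smooth regions the
#' (fast, large-capture-range) global force dominates; near boundaries the
#' weight shifts to the (accurate under inhomogeneity) local force. A
#' zero-contrast image gets \eqn{\omega \equiv 1}.
#'
#' @param contrast Non-negative matrix from [localContrast()].
#' @param beta Positive gain (model default 1).
#' @return Matrix in \eqn{(0, 1]}.
#' @export
adaptiveWeight <- function(contrast, beta = 1) {
  if (!is.matrix(contrast) || any(contrast < 0))
    stop("'contrast' must be a non-negative matrix")
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("'beta' must be a single positive number")
  m <- mean(contrast)
  if (m == 0) return(array(1, dim(contrast)))
  exp(-beta * contrast / m)
}

#' Combined signed pressure force
#'
#' The model's force: a pointwise convex combination
#' \deqn{S^{new}(x) = \omega(x)\, s_g(x) + (1 - \omega(x))\, s_l(x),}
#' which inherits the \eqn{[-1, 1]} bound from its ingredients. With
#' \eqn{\omega \equiv 1} it degenerates to the purely global force (GCV mode);
#' with \eqn{\omega \equiv 0}, to the purely local force.
#'
#' @param globalSPF,localSPF Matrices in \eqn{[-1,1]} from [spfGlobal()] /
#'   [spfLocal()].
#' @param omega Weight matrix in \eqn{[0,1]} from [adaptiveWeight()].
#' @return Matrix in \eqn{[-1, 1]}.
#' @export
combinedSPF <- function(globalSPF, localSPF, omega) {
  .checkSameShape(globalSPF, localSPF, "SPF fields")
  .checkSameShape(globalSPF, omega, "SPF and weight fields")
  omega * globalSPF + (1 - omega) * localSPF
}
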