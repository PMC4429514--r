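#' @import methods
NULL

#' Truncated Gaussian smoothing kernel
#'
#' A separable Gaussian kernel truncated at a finite radius and renormalized so
#' its discrete weights sum to one. The same kernel type serves two distinct
#' roles in the model: the fitting kernel \eqn{K_\sigma} that defines the local
#' intensity fits (default \eqn{\sigma = 5}), and the much narrower filter used
#' to regularize the binarized level-set field between iterations.
#'
#' @slot sigma Standard deviation in pixels (positive).
#' @slot radius Truncation radius in pixels (positive integer); weights outside
#'   \code{[-radius, radius]} are dropped before renormalization.
#' @slot weights Numeric vector of length \code{2 * radius + 1}; strictly
#'   positive, symmetric, summing to 1.
#'
#' @seealso [smoothingKernel()], [gaussianConvolve()]
#' @export
setClass("SmoothingKernel",
  representation(sigma = "numeric", radius = "integer", weights = "numeric"))

setValidity("SmoothingKernel", function(object) {
  msg <- character()
  if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
      object@sigma <= 0)
    msg <- c(msg, "'sigma' must be a single positive finite number")
  if (length(object@radius) != 1L || object@radius < 1L)
    msg <- c(msg, "'radius' must be a single positive integer")
  w <- object@weights
  if (length(w) != 2L * object@radius + 1L)
    msg <- c(msg, "'weights' must have length 2*radius + 1")
  else {
    if (any(w <= 0)) msg <- c(msg, "kernel weights must be strictly positive")
    if (abs(sum(w) - 1) > 1e-12) msg <- c(msg, "kernel weights must sum to 1")
    if (max(abs(w - rev(w))) > 1e-15)
      msg <- c(msg, "kernel must be symmetric about its center")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a truncated Gaussian smoothing kernel
#'
#' @param sigma Standard deviation in pixels; must be positive.
#' @param radius Truncation radius in pixels; defaults to \code{ceiling(3 *
#'   sigma)}, which retains essentially all of the kernel mass.
#'
#' @return A [SmoothingKernel-class] object.
#' @examples
#' k <- smoothingKernel(1)
#' sum(kernelWeights(k))  # exactly 1
#' @export
smoothingKernel <- function(sigma, radius = ceiling(3 * sigma)) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("'sigma' must be a single positive number")
  radius <- as.integer(radius)
  x <- seq(-radius, radius)
  w <- exp(-x^2 / (2 * sigma^2))
  new("SmoothingKernel", sigma = as.numeric(sigma), radius = radius,
      weights = w / sum(w))
}

#' @describeIn smoothingKernel Extract the normalized 1-D weight vector.
#' @param object,x A \code{SmoothingKernel}.
#' @export
kernelWeights <- function(x) {
  stopifnot(is(x, "SmoothingKernel"))
  x@weights
}

setMethod("show", "SmoothingKernel", function(object) {
  cat("SmoothingKernel: sigma =", object@sigma,
      ", radius =", object@radius,
      " (", length(object@weights), "taps )\n")
})

#' Parameters of the level-set evolution
#'
#' Collects every tunable of the two- and four-phase solvers. Defaults follow
#' the model's reference configuration: time step \eqn{\Delta t = 1}, fitting
#' kernel scale \eqn{\sigma = 5}, Heaviside/Dirac regularization width
#' \eqn{\epsilon = 0.3}, contrast-weight gain \eqn{\beta = 1}. The balloon
#' force \eqn{\alpha} is image-dependent; when \code{alpha} is \code{NA} the
#' solver uses magnitude 20 with the sign chosen from which side of the global
#' intensity midpoint the initial region's mean falls on.
#'
#' @slot alpha Balloon force; sign selects expansion (positive phase grows into
#'   bright pixels) vs shrinkage. \code{NA} means auto.
#' @slot dt Time step (positive).
#' @slot sigmaFit Scale of the local-fitting kernel, pixels.
#' @slot sigmaReg Scale of the Gaussian filter regularizing the binarized
#'   level-set field, pixels.
#' @slot rho Magnitude of the binary initialization.
#' @slot beta Gain of the adaptive contrast weight \eqn{\omega}.
#' @slot epsH Width of the regularized Heaviside.
#' @slot epsD Width of the regularized Dirac delta.
#' @slot maxIters Iteration cap.
#' @slot tol Convergence tolerance: maximum number of binarized-mask pixel
#'   changes still counted as "stable"; stability over 3 consecutive
#'   iterations stops the solver.
#' @slot mode One of \code{"proposed"} (adaptive local+global SPF),
#'   \code{"gcv"} (global SPF only, \eqn{\omega \equiv 1}) or \code{"local"}
#'   (local SPF only, \eqn{\omega \equiv 0}).
#'
#' @seealso [evolutionParams()], [segmentTwoPhase()], [segmentFourPhase()]
#' @export
setClass("EvolutionParams",
  representation(alpha = "numeric", dt = "numeric", sigmaFit = "numeric",
                 sigmaReg = "numeric", rho = "numeric", beta = "numeric",
                 epsH = "numeric", epsD = "numeric", maxIters = "integer",
                 tol = "numeric", mode = "character"))

setValidity("EvolutionParams", function(object) {
  msg <- character()
  chk1 <- function(v) length(v) == 1L && (is.na(v) || is.finite(v))
  if (!chk1(object@alpha)) msg <- c(msg, "'alpha' must be a single number or NA")
  for (nm in c("dt", "sigmaFit", "sigmaReg", "rho", "beta", "epsH", "epsD")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", nm))
  }
  if (length(object@maxIters) != 1L || object@maxIters < 1L)
    msg <- c(msg, "'maxIters' must be >= 1")
  if (length(object@tol) != 1L || !is.finite(object@tol) || object@tol < 0)
    msg <- c(msg, "'tol' must be a single non-negative number")
  if (length(object@mode) != 1L ||
      !object@mode %in% c("proposed", "gcv", "local"))
    msg <- c(msg, "'mode' must be one of 'proposed', 'gcv', 'local'")
  if (length(msg)) msg else TRUE
})

#' Construct evolution parameters
#'
#' @param alpha Balloon force (\code{NA} = magnitude 20, automatic sign).
#' @param dt Time step.
#' @param sigmaFit Local-fitting kernel scale (pixels).
#' @param sigmaReg Level-set regularization filter scale (pixels).
#' @param rho Initialization magnitude.
#' @param beta Adaptive-weight gain.
#' @param epsH,epsD Heaviside / Dirac regularization widths.
#' @param maxIters Iteration cap.
#' @param tol Changed-pixel tolerance of the convergence test.
#' @param mode \code{"proposed"}, \code{"gcv"} or \code{"local"}.
#'
#' @return An [EvolutionParams-class] object.
#' @examples
#' evolutionParams(alpha = 20, mode = "gcv")
#' @export
evolutionParams <- function(alpha = NA_real_, dt = 1, sigmaFit = 5,
                            sigmaReg = 1, rho = 2, beta = 1, epsH = 0.3,
                            epsD = 0.3, maxIters = 200L, tol = 0,
                            mode = c("proposed", "gcv", "local")) {
  mode <- match.arg(mode)
  new("EvolutionParams", alpha = as.numeric(alpha), dt = as.numeric(dt),
      sigmaFit = as.numeric(sigmaFit), sigmaReg = as.numeric(sigmaReg),
      rho = as.numeric(rho), beta = as.numeric(beta), epsH = as.numeric(epsH),
      epsD = as.numeric(epsD), maxIters = as.integer(maxIters),
      tol = as.numeric(tol), mode = mode)
}

setMethod("show", "EvolutionParams", function(object) {
  cat("EvolutionParams (mode =", object@mode, ")\n")
  cat("  alpha:", ifelse(is.na(object@alpha), "auto (|20|)", object@alpha),
      " dt:", object@dt, "\n")
  cat("  sigmaFit:", object@sigmaFit, " sigmaReg:", object@sigmaReg,
      " rho:", object@rho, "\n")
  cat("  beta:", object@beta, " epsH:", object@epsH, " epsD:", object@epsD,
      "\n")
  cat("  maxIters:", object@maxIters, " tol:", object@tol, "\n")
})

#' Result of a two-phase segmentation
#'
#' @slot mask Logical matrix; \code{TRUE} marks the positive phase (object).
#'   Equals \code{levelSet(x) > 0} exactly.
#' @slot phi Final level-set field (matrix in \eqn{[-1, 1]} after the last
#'   binarize-and-smooth step).
#' @slot iterations Number of iterations actually run.
#' @slot converged Whether the stability criterion was met before the cap.
#' @slot history Integer vector of per-iteration changed-pixel counts of the
#'   binarized mask.
#' @slot alpha Balloon force actually used (after automatic sign selection).
#' @slot mode SPF mode used.
#' @export
setClass("SegmentationResult",
  representation(mask = "matrix", phi = "matrix", iterations = "integer",
                 converged = "logical", history = "integer", alpha = "numeric",
                 mode = "character"))

setValidity("SegmentationResult", function(object) {
  msg <- character()
  if (!is.logical(object@mask)) msg <- c(msg, "'mask' must be logical")
  if (!identical(dim(object@mask), dim(object@phi)))
    msg <- c(msg, "'mask' and 'phi' must have the same shape")
  else if (!identical(object@mask, object@phi > 0))
    msg <- c(msg, "'mask' must equal phi > 0 exactly")
  if (object@iterations > length(object@history) && length(object@history))
    msg <- c(msg, "'history' shorter than 'iterations'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SegmentationResult", function(object) {
  d <- dim(object@mask)
  cat("SegmentationResult (", object@mode, " mode )\n", sep = "")
  cat("  image:", d[1], "x", d[2], " object pixels:", sum(object@mask), "\n")
  cat("  iterations:", object@iterations,
      if (object@converged) "(converged)" else "(iteration cap reached)", "\n")
  cat("  alpha:", object@alpha, "\n")
})

#' Result of a four-phase segmentation
#'
#' Two level-set fields jointly encode four regions through their sign
#' combinations. Labels are 1: \eqn{\phi_1>0,\phi_2>0}, 2:
#' \eqn{\phi_1>0,\phi_2\le 0}, 3: \eqn{\phi_1\le 0,\phi_2>0}, 4: both
#' non-positive; this equals the argmax of the regularized membership fields
#' computed from the final binarized fields.
#'
#' @slot labels Integer matrix with values in 1..4.
#' @slot phi1,phi2 Final level-set fields.
#' @slot iterations Iterations run.
#' @slot converged Stability criterion met.
#' @slot history Integer matrix, one row per iteration, columns = changed-pixel
#'   counts of the two binarized masks.
#' @slot means Named numeric vector of final region mean intensities
#'   \code{c1..c4} (ordered by label).
#' @slot legend Character vector naming the sign region of each label.
#' @export
setClass("FourPhaseResult",
  representation(labels = "matrix", phi1 = "matrix", phi2 = "matrix",
                 iterations = "integer", converged = "logical",
                 history = "matrix", means = "numeric", legend = "character"))

setValidity("FourPhaseResult", function(object) {
  msg <- character()
  if (!all(object@labels %in% 1:4))
    msg <- c(msg, "'labels' must take values in 1..4")
  if (!identical(dim(object@labels), dim(object@phi1)) ||
      !identical(dim(object@phi1), dim(object@phi2)))
    msg <- c(msg, "'labels', 'phi1', 'phi2' must share one shape")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FourPhaseResult", function(object) {
  d <- dim(object@labels)
  cat("FourPhaseResult\n")
  cat("  image:", d[1], "x", d[2], "\n")
  cnt <- tabulate(object@labels, 4L)
  for (i in 1:4)
    cat(sprintf("  label %d (%s): %d px, mean intensity %.4f\n", i,
                object@legend[i], cnt[i], object@means[i]))
  cat("  iterations:", object@iterations,
      if (object@converged) "(converged)" else "(iteration cap reached)", "\n")
})

#' Specification of a synthetic phantom
#'
#' Describes a piecewise-constant scene, a smooth multiplicative bias field and
#' additive Gaussian noise; [makePhantom()] renders it deterministically from
#' the stored seed. This is the package's stand-in for the inhomogeneous test
#' images the model targets: each region has a single true intensity, the bias
#' field emulates MR coil inhomogeneity, and the exact label field is kept as
#' ground truth.
#'
#' @slot shape Integer vector \code{c(rows, cols)}.
#' @slot geometry One of \code{"disk"}, \code{"rectangle"},
#'   \code{"hand_like_polygon"}, \code{"two_vessels"}, \code{"four_quadrant"},
#'   \code{"brain_rings"}.
#' @slot intensities Per-region true intensities in \eqn{[0,1]}, ordered by
#'   label; must be pairwise distinct.
#' @slot bias Bias field kind: \code{"none"}, \code{"linear_ramp"} or
#'   \code{"gaussian_blob"}.
#' @slot biasStrength Peak relative amplitude of the bias field, in
#'   \eqn{[0, 1)}.
#' @slot noiseSigma Standard deviation of the additive Gaussian noise.
#' @slot seed Integer RNG seed; identical specs render bit-identical phantoms.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", geometry = "character",
                 intensities = "numeric", bias = "character",
                 biasStrength = "numeric", noiseSigma = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 2L || any(object@shape < 8L))
    msg <- c(msg, "'shape' must be two integers >= 8")
  if (!object@geometry %in% c("disk", "rectangle", "hand_like_polygon",
                              "two_vessels", "four_quadrant", "brain_rings"))
    msg <- c(msg, paste("unknown geometry:", object@geometry))
  iv <- object@intensities
  if (any(!is.finite(iv)) || any(iv < 0) || any(iv > 1))
    msg <- c(msg, "'intensities' must lie in [0, 1]")
  if (anyDuplicated(iv)) msg <- c(msg, "'intensities' must be distinct")
  if (!object@bias %in% c("none", "linear_ramp", "gaussian_blob"))
    msg <- c(msg, paste("unknown bias kind:", object@bias))
  if (object@biasStrength < 0 || object@biasStrength >= 1)
    msg <- c(msg, "'biasStrength' must be in [0, 1)")
  if (object@noiseSigma < 0) msg <- c(msg, "'noiseSigma' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A rendered phantom: image plus exact ground truth
#'
#' @slot image Numeric matrix in \eqn{[0,1]}.
#' @slot truth Integer label matrix (1 = background region).
#' @slot spec The [PhantomSpec-class] it was rendered from.
#' @seealso [makePhantom()]
#' @export
setClass("Phantom",
  representation(image = "matrix", truth = "matrix", spec = "PhantomSpec"))

setMethod("show", "Phantom", function(object) {
  s <- object@spec
  cat("Phantom:", s@geometry, paste(s@shape, collapse = "x"), "\n")
  cat("  regions:", length(s@intensities),
      " bias:", s@bias,
      if (s@bias != "none") sprintf("(strength %.2f)", s@biasStrength) else "",
      " noise sd:", s@noiseSigma, " seed:", s@seed, "\n")
})
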