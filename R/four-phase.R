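# Four-phase extension: two level-set fields encode four regions through
# their sign combinations. Each field is driven by a conditional SPF built
# from the four region statistics, localized by the regularized Dirac delta.

#' Membership fields of the four phases
#'
#' Products of the regularized Heavisides of the two fields:
#' \deqn{M_1 = H(\phi_1)H(\phi_2),\; M_2 = H(\phi_1)(1 - H(\phi_2)),\;
#'       M_3 = (1 - H(\phi_1))H(\phi_2),\; M_4 = (1 - H(\phi_1))(1 -
#'       H(\phi_2)).}
#' They form a partition of unity at every pixel by construction.
#'
#' @param phi1,phi2 Level-set fields (same shape).
#' @param epsH Heaviside regularization width.
#' @return List of four matrices \code{m1..m4}, each in \eqn{(0, 1)}, summing
#'   to 1 pointwise.
#' @export
membershipFields <- function(phi1, phi2, epsH = 0.3) {
  .checkSameShape(phi1, phi2, "'phi1' and 'phi2'")
  h1 <- heavisideEps(phi1, epsH)
  h2 <- heavisideEps(phi2, epsH)
  list(m1 = h1 * h2, m2 = h1 * (1 - h2), m3 = (1 - h1) * h2,
       m4 = (1 - h1) * (1 - h2))
}

#' Global mean intensities of the four phases
#'
#' Membership-weighted image means \eqn{c_i = \sum I\,M_i / \sum M_i}, with
#' the weight sum floored at 1e-12 (an essentially empty phase falls back to
#' the global image mean with a warning).
#'
#' @param image Numeric matrix.
#' @param memberships List \code{m1..m4} from [membershipFields()].
#' @return Named numeric vector \code{c(c1, c2, c3, c4)}.
#' @export
fourPhaseMeans <- function(image, memberships) {
  .checkImage(image)
  vapply(setNames(memberships, paste0("c", 1:4)), function(m) {
    sm <- sum(m)
    if (sm < .DENOM_FLOOR) {
      warning("degenerate phase; using global image mean")
      return(mean(image))
    }
    sum(image * m) / sm
  }, numeric(1))
}

#' Local fitting functions of the four phases
#'
#' Kernel-weighted local means per phase,
#' \eqn{f_i = K_\sigma * (M_i I) / K_\sigma * M_i} (denominators floored at
#' 1e-12). Deep inside a pure phase, \eqn{f_i} tracks that phase's local
#' intensity including any smooth bias.
#'
#' @inheritParams fourPhaseMeans
#' @param kernel A [SmoothingKernel-class] or numeric sigma (default 5).
#' @return List of four matrices \code{f1..f4}.
#' @export
fourPhaseLocalFits <- function(image, memberships, kernel = 5) {
  .checkImage(image)
  if (is.numeric(kernel) && length(kernel) == 1L)
    kernel <- smoothingKernel(kernel)
  lapply(setNames(memberships, paste0("f", 1:4)), function(m) {
    den <- gaussianConvolve(m, kernel)
    num <- gaussianConvolve(m * image, kernel)
    num / pmax(den, .DENOM_FLOOR)
  })
}

#' Signed pressure forces of the two level-set fields
#'
#' The coupling is hierarchical. \eqn{\phi_1} carries the coarse split and is
#' driven by the marginal two-phase force of its own partition — global means
#' and local fits computed from \eqn{H(\phi_1)} alone, combined exactly as in
#' [segmentTwoPhase()] — so its flow does not depend on \eqn{\phi_2} and,
#' with \eqn{\phi_2} frozen, the four-phase model reduces to the two-phase
#' model by construction. \eqn{\phi_2} refines each side of \eqn{\phi_1}:
#' flipping its sign exchanges phases 1 and 2 where \eqn{\phi_1 > 0} and
#' phases 3 and 4 where \eqn{\phi_1 \le 0}, so its force blends the two
#' pairwise competition terms
#' \deqn{s_2 \propto H(\phi_1)\,\big[(I - c_2)^2 - (I - c_1)^2\big] +
#'   (1 - H(\phi_1))\,\big[(I - c_4)^2 - (I - c_3)^2\big],}
#' normalized by its maximum absolute value (each bracket equals
#' \eqn{2(c_a - c_b)(I - (c_a + c_b)/2)}; the pair-difference factor orients
#' the push toward the better-fitting phase whatever the pair's intensity
#' ordering). The local force replaces \eqn{c_i} by \eqn{f_i(x)}; global and
#' local parts are blended with the adaptive weight \eqn{\omega} as in the
#' two-phase model. A fully symmetric coupling (each field conditioned on the
#' other) admits exactly mirrored or identical field pairs as invariant
#' states onto which the binarization step projects, collapsing two phases;
#' the one-way coupling removes those states.
#'
#' @param image Numeric matrix.
#' @param phi1,phi2 Current level-set fields.
#' @param means Vector \code{c1..c4} from [fourPhaseMeans()].
#' @param fits List \code{f1..f4} from [fourPhaseLocalFits()], or \code{NULL}
#'   when only the global force is needed.
#' @param omega Weight matrix in \eqn{[0,1]}; scalars are recycled (1 = global
#'   only, 0 = local only).
#' @param epsH Heaviside width.
#' @param kernel Fitting kernel for the marginal fits of \eqn{\phi_1} (a
#'   [SmoothingKernel-class] or numeric sigma).
#' @return List with matrices \code{spf1}, \code{spf2}, each in
#'   \eqn{[-1, 1]}.
#' @export
fourPhaseSPF <- function(image, phi1, phi2, means, fits = NULL, omega = 1,
                         epsH = 0.3, kernel = 5) {
  .checkImage(image)
  if (length(omega) == 1L) omega <- array(omega, dim(image))
  globalOnly <- all(omega == 1)
  normSide <- function(raw, side) {
    m <- if (any(side)) max(abs(raw[side])) else max(abs(raw))
    if (m < .DENOM_FLOOR) array(0, dim(raw))
    else pmin(pmax(raw / m, -1), 1)
  }

  # phi1 global: marginal two-phase force of its own partition (autonomous
  # in phi2, which rules out locked mirrored/identical field pairs).
  # phi1 local: phase-aware pair competition conditioned on phi2's side —
  # marginal local fits would anchor phi1's front on whatever intensity edge
  # is nearest, including edges that belong to phi2's partition.
  sG1 <- spfGlobal(image, globalRegionMeans(image, phi1, epsH))
  spf1 <- if (globalOnly) sG1 else {
    side2 <- phi2 > 0
    pairL1 <- function(a, b, side)
      normSide(2 * (fits[[a]] - fits[[b]]) *
                 (image - (fits[[a]] + fits[[b]]) / 2), side)
    sL1 <- ifelse(side2, pairL1(1L, 3L, side2), pairL1(2L, 4L, !side2))
    combinedSPF(sG1, sL1, omega)
  }

  # phi2: pairwise phase competition conditioned on the side of phi1. Each
  # side's bracket is normalized over that side's own pixels (saturating at
  # +-1 elsewhere), so a weak-contrast side still receives forces of full
  # unit magnitude and the other side's intensities cannot set its scale.
  sidePos <- phi1 > 0
  # degenerate pair: if the two phase means are indistinguishable (below 2%
  # of the intensity range) there is no evidence for a second phase on this
  # side, and normalizing the bracket would amplify pure noise to unit
  # force; collapse the side deterministically onto the phi2 <= 0 member
  degenSep <- 0.02 * diff(range(image))
  branch2 <- function(a, b, side) {
    if (abs(means[a] - means[b]) < degenSep) return(array(-1, dim(image)))
    g <- normSide(2 * (means[a] - means[b]) *
                    (image - (means[a] + means[b]) / 2), side)
    if (globalOnly) return(g)
    l <- normSide(2 * (fits[[a]] - fits[[b]]) *
                    (image - (fits[[a]] + fits[[b]]) / 2), side)
    combinedSPF(g, l, omega)
  }
  # hard gating by the sign of phi1: each pixel belongs to exactly one
  # pairwise sub-problem; a soft Heaviside gate would leak the other side's
  # saturated bracket (weight H(-1) ~ 0.09 at eps 0.3) into every pixel,
  # enough to cancel the weak force that repopulates a collapsed phase
  spf2 <- ifelse(sidePos, branch2(1L, 2L, sidePos),
                 branch2(3L, 4L, !sidePos))
  list(spf1 = spf1, spf2 = spf2)
}

# Hard per-phase means from the sign regions, with k-means-style revival of
# collapsed phases: a phase holding less than 2% of its side of phi1 (a few
# interface stragglers at most) has its mean reset to the intensity of the
# side's worst-fitting pixel, so the pair competition can repopulate it. A
# membership-weighted mean of an empty phase would drift to the global image
# mean, which can pin the pair threshold exactly on a region's intensity and
# deadlock the flow.
.hardPhaseMeans <- function(image, phi1, phi2) {
  lab <- .labelsFromSigns(phi1, phi2)
  sides <- list(phi1 > 0, phi1 > 0, phi1 <= 0, phi1 <= 0)
  cnt <- tabulate(lab, 4L)
  sideN <- vapply(sides, sum, integer(1))
  alive <- cnt >= pmax(1, 0.02 * sideN)
  cs <- numeric(4)
  for (i in 1:4) cs[i] <- if (alive[i]) mean(image[lab == i]) else NA_real_
  sibling <- c(2L, 1L, 4L, 3L)
  for (i in 1:4) {
    if (!is.na(cs[i])) next
    side <- image[sides[[i]]]
    cs[i] <- if (!length(side)) mean(image)
    else if (is.na(cs[sibling[i]])) mean(side)
    else {
      # robust extreme of the side's intensity distribution, on whichever
      # tail lies farther from the sibling mean; plain which.max would grab
      # boundary stragglers misassigned by phi1 rather than by phi2
      qs <- stats::quantile(side, c(0.02, 0.98), names = FALSE)
      qs[which.max(abs(qs - cs[sibling[i]]))]
    }
  }
  setNames(cs, paste0("c", 1:4))
}

.labelsFromSigns <- function(phi1, phi2) {
  lab <- matrix(4L, nrow(phi1), ncol(phi1))
  lab[phi1 > 0 & phi2 > 0] <- 1L
  lab[phi1 > 0 & phi2 <= 0] <- 2L
  lab[phi1 <= 0 & phi2 > 0] <- 3L
  lab
}

.FOURPHASE_LEGEND <- c("phi1>0, phi2>0", "phi1>0, phi2<=0",
                       "phi1<=0, phi2>0", "phi1<=0, phi2<=0")

#' Four-phase level-set segmentation
#'
#' Joint evolution of two level-set fields encoding four regions (e.g. white
#' matter, gray matter, CSF, background in T1-weighted brain MR). Each
#' iteration computes memberships, the four global means and local fits, the
#' two conditional SPFs, then updates
#' \deqn{\phi_i \leftarrow \phi_i + \Delta t\,\alpha\, s_i\,
#'   \delta_\epsilon(\phi_i),}
#' binarizes and Gaussian-regularizes each field. The Dirac factor localizes
#' strong updates around each field's interface while still allowing
#' far-field sign corrections; its width \code{epsD} trades capture range
#' against final contour accuracy. Convergence: both binarized masks change
#' by at most \code{tol} pixels for 3 consecutive iterations.
#'
#' Default initializations are two overlapping offset rectangles, so all four
#' sign combinations are populated at start. Identical initializations
#' trigger a warning (two phases would start empty and may collapse).
#'
#' Labels are reported as sign regions (see [FourPhaseResult-class]); for
#' tissue naming, rank the reported phase means (brightest = WM in T1).
#'
#' @param image Numeric matrix of finite intensities.
#' @param init1,init2 Initialization regions for the two fields (rectangle
#'   \code{c(r0, r1, c0, c1)} or logical mask); \code{NULL} picks the default
#'   offset rectangles.
#' @param params An [EvolutionParams-class]. \code{NA} alpha defaults to +30
#'   (multi-phase reference value); \code{mode} selects the SPF blend as in
#'   [segmentTwoPhase()].
#' @param freeze2 Diagnostic switch: keep \eqn{\phi_2} fixed (used to verify
#'   the reduction to the two-phase flow).
#'
#' @return A [FourPhaseResult-class].
#' @export
segmentFourPhase <- function(image, init1 = NULL, init2 = NULL,
                             params = evolutionParams(), freeze2 = FALSE) {
  .checkImage(image)
  stopifnot(is(params, "EvolutionParams"))
  d <- dim(image)
  # default: two overlapping orthogonal band rectangles (a vertical band for
  # phi1, a horizontal one for phi2), so all four sign combinations start
  # with substantial area and each field's interface crosses most of the
  # image structure
  if (is.null(init1))
    init1 <- c(round(0.05 * d[1]), round(0.95 * d[1]),
               round(0.33 * d[2]), round(0.67 * d[2]))
  if (is.null(init2))
    init2 <- c(round(0.33 * d[1]), round(0.67 * d[1]),
               round(0.05 * d[2]), round(0.95 * d[2]))
  if (identical(init1, init2))
    warning("identical initialization regions; phases may collapse")
  asField <- function(init) {
    # a numeric (non-logical) matrix is taken as the initial field itself,
    # which lets callers freeze a phase at an arbitrary level
    if (is.matrix(init) && is.numeric(init) && !is.logical(init)) {
      .checkSameShape(image, init, "'image' and an initial field")
      init
    } else initializeLevelSet(d, init, params@rho)
  }
  phi1 <- asField(init1)
  phi2 <- asField(init2)
  alpha <- params@alpha
  if (is.na(alpha)) alpha <- 30
  kernel <- smoothingKernel(params@sigmaFit)
  omega <- switch(params@mode,
                  proposed = adaptiveWeight(localContrast(image),
                                            params@beta),
                  gcv = 1, local = 0)

  prev1 <- phi1 > 0; prev2 <- phi2 > 0
  history <- matrix(0L, 0L, 2L, dimnames = list(NULL, c("phi1", "phi2")))
  stable <- 0L; converged <- FALSE; iter <- 0L
  while (iter < params@maxIters) {
    iter <- iter + 1L
    cs <- .hardPhaseMeans(image, phi1, phi2)
    fs <- if (identical(omega, 1)) NULL else {
      m <- membershipFields(phi1, phi2, params@epsH)
      fourPhaseLocalFits(image, m, kernel)
    }
    s <- fourPhaseSPF(image, phi1, phi2, cs, fs, omega, params@epsH, kernel)
    phi1 <- phi1 + params@dt * alpha * s$spf1 * diracEps(phi1, params@epsD)
    phi1 <- regularizeGaussian(binarizeLevelSet(phi1), params@sigmaReg)
    if (!freeze2) {
      phi2 <- phi2 + params@dt * alpha * s$spf2 * diracEps(phi2, params@epsD)
      phi2 <- regularizeGaussian(binarizeLevelSet(phi2), params@sigmaReg)
    }
    mask1 <- phi1 > 0; mask2 <- phi2 > 0
    changed <- c(sum(mask1 != prev1), sum(mask2 != prev2))
    history <- rbind(history, changed)
    prev1 <- mask1; prev2 <- mask2
    stable <- if (max(changed) <= params@tol) stable + 1L else 0L
    if (stable >= 3L) { converged <- TRUE; break }
  }
  labels <- .labelsFromSigns(phi1, phi2)
  m <- membershipFields(binarizeLevelSet(phi1), binarizeLevelSet(phi2),
                        params@epsH)
  cs <- suppressWarnings(fourPhaseMeans(image, m))
  rownames(history) <- NULL
  new("FourPhaseResult", labels = labels, phi1 = phi1, phi2 = phi2,
      iterations = iter, converged = converged,
      history = matrix(as.integer(history), ncol = 2L,
                       dimnames = list(NULL, c("phi1", "phi2"))),
      means = cs, legend = .FOURPHASE_LEGEND)
}
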