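# Seeded synthetic phantoms with exact ground truth: piecewise-constant
# scenes under a smooth multiplicative bias field plus additive Gaussian
# noise, emulating the inhomogeneous images the model targets.

# Per-geometry default region intensities. Two-region scenes use a
# background/object ratio below 1.5 on purpose: under the multiplicative
# bias strengths used in the experiments the class intensity ranges then
# overlap, which is exactly the regime where a single global threshold fails
# and local fitting is required.
.DEFAULT_INTENSITIES <- list(
  disk = c(0.45, 0.65),
  rectangle = c(0.45, 0.65),
  hand_like_polygon = c(0.45, 0.65),
  two_vessels = c(0.40, 0.70),
  four_quadrant = c(0.10, 0.40, 0.70, 1.00),
  brain_rings = c(0.05, 0.30, 0.55, 0.85))

#' Construct a phantom specification
#'
#' @param shape Integer vector \code{c(rows, cols)}.
#' @param geometry Scene kind; see [PhantomSpec-class].
#' @param intensities True region intensities ordered by label; defaults are
#'   geometry-specific (two-region scenes: background 0.45, object 0.65;
#'   vessels 0.40/0.70; quadrants 0.1/0.4/0.7/1.0; brain rings
#'   background/CSF/GM/WM = 0.05/0.30/0.55/0.85, the T1-weighted ordering).
#' @param bias Bias kind: \code{"none"}, \code{"linear_ramp"} (zero-mean
#'   horizontal gradient) or \code{"gaussian_blob"} (centered bump).
#' @param biasStrength Peak relative bias amplitude in \eqn{[0, 1)}.
#' @param noiseSigma Additive Gaussian noise standard deviation.
#' @param seed RNG seed (rendering is bit-reproducible given the spec).
#'
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(shape, geometry, intensities = NULL,
                        bias = c("none", "linear_ramp", "gaussian_blob"),
                        biasStrength = 0, noiseSigma = 0, seed = 1L) {
  bias <- match.arg(bias)
  geometry <- as.character(geometry)
  if (is.null(intensities)) {
    if (!geometry %in% names(.DEFAULT_INTENSITIES))
      stop("unknown geometry: ", geometry)
    intensities <- .DEFAULT_INTENSITIES[[geometry]]
  }
  new("PhantomSpec", shape = as.integer(shape), geometry = geometry,
      intensities = as.numeric(intensities), bias = bias,
      biasStrength = as.numeric(biasStrength),
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
}

#' Smooth multiplicative bias field
#'
#' \code{"linear_ramp"}: zero-mean horizontal gradient running from
#' \code{-strength} at the left edge to \code{+strength} at the right.
#' \code{"gaussian_blob"}: centered bump of peak height \code{strength} and
#' standard deviation \code{0.18 * min(shape)} pixels, so the bias varies
#' appreciably across objects of typical size. \code{"none"} (or strength 0)
#' gives the zero field. The image model multiplies intensities by
#' \code{1 + field}.
#'
#' @param shape \code{c(rows, cols)}.
#' @param kind \code{"none"}, \code{"linear_ramp"} or \code{"gaussian_blob"}.
#' @param strength Peak amplitude in \eqn{[0, 1)}.
#' @return Matrix with values in \eqn{[-strength, strength]}.
#' @export
makeBiasField <- function(shape, kind = "none", strength = 0) {
  if (!is.numeric(strength) || strength < 0 || strength >= 1)
    stop("'strength' must be in [0, 1)")
  nr <- shape[1]; nc <- shape[2]
  if (kind == "none" || strength == 0) return(matrix(0, nr, nc))
  if (kind == "linear_ramp") {
    ramp <- if (nc == 1L) 0 else seq(-strength, strength, length.out = nc)
    return(matrix(ramp, nr, nc, byrow = TRUE))
  }
  if (kind == "gaussian_blob") {
    s <- 0.18 * min(nr, nc)
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
    d2 <- outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, `+`)
    return(strength * exp(-d2 / (2 * s^2)))
  }
  stop("unknown bias kind: ", kind)
}

# ---- scene geometry -------------------------------------------------------

.diskMask <- function(nr, nc, cy, cx, r) {
  outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, `+`) <= r^2
}

.sceneTruth <- function(spec) {
  nr <- spec@shape[1]; nc <- spec@shape[2]
  g <- spec@geometry
  truth <- matrix(1L, nr, nc)
  if (g == "disk") {
    # the disk edge passes through the image center, where the bias blob
    # peaks: the inhomogeneity straddles the object boundary
    truth[.diskMask(nr, nc, 0.32 * nr, 0.32 * nc, 0.30 * min(nr, nc))] <- 2L
  } else if (g == "rectangle") {
    r0 <- round(0.30 * nr); r1 <- round(0.70 * nr)
    c0 <- round(0.25 * nc); c1 <- round(0.65 * nc)
    truth[r0:r1, c0:c1] <- 2L
  } else if (g == "hand_like_polygon") {
    # palm disk plus finger-like lobes
    truth[.diskMask(nr, nc, 0.65 * nr, 0.50 * nc, 0.20 * min(nr, nc))] <- 2L
    fx <- c(0.28, 0.40, 0.52, 0.64, 0.76)
    for (i in seq_along(fx)) {
      len <- (0.22 + 0.06 * sin(i)) * nr
      cx <- fx[i] * nc
      r0 <- max(1L, round(0.50 * nr - len)); r1 <- round(0.55 * nr)
      c0 <- max(1L, round(cx - 0.025 * nc)); c1 <- min(nc, round(cx + 0.025 * nc))
      truth[r0:r1, c0:c1] <- 2L
    }
  } else if (g == "two_vessels") {
    # two near-vertical sinusoidal bars of different calibre
    rows <- seq_len(nr)
    for (v in list(c(0.30, 0.035, 3.0), c(0.68, 0.050, -4.0))) {
      ctr <- v[1] * nc + v[3] * sin(2 * pi * rows / nr)
      half <- v[2] * nc
      for (r in rows) {
        c0 <- max(1L, round(ctr[r] - half)); c1 <- min(nc, round(ctr[r] + half))
        truth[r, c0:c1] <- 2L
      }
    }
  } else if (g == "four_quadrant") {
    rh <- nr %/% 2L; ch <- nc %/% 2L
    truth[seq_len(rh), (ch + 1L):nc] <- 2L
    truth[(rh + 1L):nr, seq_len(ch)] <- 3L
    truth[(rh + 1L):nr, (ch + 1L):nc] <- 4L
  } else if (g == "brain_rings") {
    # nested ellipses: background, CSF ring, GM ring, WM core
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
    R <- 0.46 * min(nr, nc)
    e <- sqrt(outer(((seq_len(nr) - cy) / 1.05)^2,
                    ((seq_len(nc) - cx) / 0.90)^2, `+`))
    truth[e <= R] <- 2L            # CSF shell
    truth[e <= 0.80 * R] <- 3L     # GM ring
    truth[e <= 0.45 * R] <- 4L     # WM core
  } else stop("unknown geometry: ", g)
  truth
}

#' Render a phantom
#'
#' Builds the label field for the requested geometry, assigns the true region
#' intensities, applies the multiplicative bias (\code{intensity * (1 +
#' bias)}), adds Gaussian noise, and clips to \eqn{[0, 1]} (the clip slightly
#' truncates the noise distribution near the range ends). The stored seed
#' drives a local RNG, so identical specs render bit-identical phantoms; the
#' segmentation solvers themselves are RNG-free.
#'
#' @param spec A [PhantomSpec-class].
#' @return A [Phantom-class] carrying the image, the exact label field and
#'   the spec.
#' @examples
#' ph <- makePhantom(phantomSpec(c(64, 64), "disk", bias = "gaussian_blob",
#'                               biasStrength = 0.5, noiseSigma = 0.02))
#' ph
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  truth <- .sceneTruth(spec)
  nlab <- max(truth)
  if (length(spec@intensities) < nlab)
    stop(sprintf("geometry '%s' needs %d intensities, got %d",
                 spec@geometry, nlab, length(spec@intensities)))
  img <- matrix(spec@intensities[truth], nrow(truth), ncol(truth))
  img <- img * (1 + makeBiasField(spec@shape, spec@bias, spec@biasStrength))
  if (spec@noiseSigma > 0) {
    rng <- .localRNG(spec@seed)
    img <- img + rng(length(img)) * spec@noiseSigma
  }
  img <- pmin(pmax(img, 0), 1)
  new("Phantom", image = img, truth = truth, spec = spec)
}

# Seeded normal deviates drawn without disturbing the caller's RNG state.
.localRNG <- function(seed) {
  function(n) {
    hasSeed <- exists(".Random.seed", envir = globalenv())
    if (hasSeed) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (hasSeed) assign(".Random.seed", old, envir = globalenv())
            else rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    stats::rnorm(n)
  }
}
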