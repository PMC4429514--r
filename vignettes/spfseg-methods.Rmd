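---
title: "Local and global signed pressure forces: the model behind SPFSeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local and global signed pressure forces: the model behind SPFSeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SPFSeg)
```

## The segmentation problem

MR images combine three properties that defeat simple thresholding: smooth
multiplicative intensity drift within each tissue (the bias field), noise,
and weak boundaries between adjacent tissues. Purely global region models
(Chan–Vese and its signed-pressure-force descendants) assume each class has
one representative intensity and fail under bias; purely local fitting
models handle bias but fall into local minima and depend strongly on the
initial contour. SPFSeg implements a geodesic active contour whose driving
force blends both information sources, with the blend chosen per pixel from
the local image contrast.

## Two-phase model

The contour is the zero crossing of a level-set field $\phi$. Region
integrals use the regularized Heaviside
$H_\epsilon(z) = \tfrac12(1 + \tfrac{2}{\pi}\arctan(z/\epsilon))$ and its
derivative, the regularized Dirac
$\delta_\epsilon(z) = \tfrac{1}{\pi}\,\epsilon/(\epsilon^2 + z^2)$.

Three force ingredients are computed from the current field:

* global means $c_1, c_2$ (inside/outside, $H_\epsilon$-weighted),
* local fits $f_1, f_2$ = ratios of Gaussian-smoothed masked intensities
  to smoothed masks (kernel scale $\sigma_{fit}$),
* the contrast weight $\omega$.

Both the global and the local force subtract the midpoint of the relevant
pair from the image and normalize by the maximum absolute deviation, so
each force lies in $[-1, 1]$ and attains magnitude 1 somewhere on any
non-constant image. The blended force
$S = \omega\, s_g + (1-\omega)\, s_l$ inherits the bound as a convex
combination.

One iteration is: build $S$; transport
$\phi \leftarrow \phi + \Delta t\,\alpha\, S\, |\nabla\phi|$ (central
differences, replicate boundary); binarize to $\pm 1$ (zero maps to $-1$,
matching the strict inequality of the update rule); smooth with a narrow
Gaussian ($\sigma_{reg}$). The binarize-and-smooth step is the model's
regularizer: it replaces both the curvature term and signed-distance
re-initialization, and it is why the $\nabla S \cdot \nabla\phi$ term of
the full geodesic flow can be dropped — the region statistics already give
the force a large capture range. A consequence worth knowing: the front
only moves where $|\nabla\phi| > 0$, i.e. within a band of roughly
$3\sigma_{reg}$ pixels around the current interface, so an initialization
must intersect (or surround) every structure it is meant to capture.

### The contrast weight

The model needs $\omega$ large in smooth regions (global force: fast,
initialization-robust) and small near boundaries (local force: correct
placement under bias). We use the Michelson contrast over a $5\times 5$
replicate-padded window,
$C_R = (\max_R I - \min_R I)/(\max_R I + \min_R I + 10^{-8})$, which is
bounded, zero on flat patches and invariant to positive intensity scaling,
and map it through $\omega = \exp(-\beta\, C_R/\overline{C_R})$ with the
image-mean normalization making $\beta = 1$ a usable default across
images. $\omega$ is computed once from the input image: the contrast map
does not depend on the contour, and freezing it keeps every iteration
strictly deterministic. `mode = "gcv"` forces $\omega \equiv 1$ (the
global-only ablation), `mode = "local"` forces $\omega \equiv 0$.

### Balloon force

$\alpha$ sets the sign convention: with a bright object, $\alpha > 0$
grows the positive phase into pixels above the running midpoint. Its
magnitude is image-dependent (20 for the disk-style phantoms, 10 for the
vessel images, 30 for the four-phase runs are the reference settings).
When `alpha = NA`, magnitude 20 is used and the sign is chosen by whether
the seed region's mean intensity lies above the initial global midpoint.

## Four-phase extension

Two fields encode four regions through their sign combinations, with
memberships $M_1 = H(\phi_1)H(\phi_2)$, $M_2 = H(\phi_1)(1-H(\phi_2))$,
$M_3 = (1-H(\phi_1))H(\phi_2)$, $M_4 = (1-H(\phi_1))(1-H(\phi_2))$ — an
exact partition of unity. Updates use
$\phi_i \leftarrow \phi_i + \Delta t\,\alpha\, s_i\,
\delta_\epsilon(\phi_i)$, then the same binarize-and-smooth step. The
Dirac factor concentrates strong updates near each interface while still
permitting far-field sign corrections where the force is strong — that is
what lets a phase claim a region its interface does not yet touch.

### Why the coupling is hierarchical

The textbook four-region competition drives each field by brackets such as
$(I - c_3)^2 - (I - c_1)^2$ conditioned on the other field's side. A fully
symmetric implementation of that coupling has a structural failure mode in
the binarized setting: exactly mirrored ($\phi_2 = -\phi_1$) and exactly
identical field pairs are invariant under the flow, and the binarization
step projects nearby states onto them. Once there, two of the four phases
are empty, their membership-weighted means equal the global image mean,
and the flow is stuck. We observed this reproducibly from a wide range of
initializations.

SPFSeg therefore couples the fields one way:

* $\phi_1$'s **global** force is the *marginal* two-phase force of its own
  partition. It is autonomous in $\phi_2$, which removes the
  mirror/identical invariant states, and it makes the reduction exact:
  freezing $\phi_2$ at a large positive constant turns the four-phase
  solver into the two-phase solver (`freeze2 = TRUE` exposes this, and the
  test suite asserts mask equality).
* $\phi_1$'s **local** force and *all* of $\phi_2$'s forces are pairwise
  competitions $2(c_a - c_b)(I - (c_a + c_b)/2)$ (equivalently
  $(I-c_b)^2 - (I-c_a)^2$), gated by the other field's side. The
  pair-difference factor matters: without it the push reverses whenever a
  pair's intensity ordering flips. A purely marginal local force for
  $\phi_1$ is not usable either — being blind to the four-phase structure
  it anchors the front on whatever intensity edge is nearest, including
  edges interior to $\phi_2$'s partition (we saw it drag the tissue/CSF
  boundary onto the stronger CSF/background edge).

### Numerical choices in the competition

* **Hard means with revival.** The solver's pair competitions use hard
  sign-region means. A phase holding less than 2% of its side of $\phi_1$
  is treated as collapsed and its mean is revived at the side's 2%/98%
  intensity quantile farthest from its sibling's mean. The quantile (not
  the worst-fitting pixel) makes revival robust to the handful of
  stragglers that sit on the wrong side of $\phi_1$'s interface; an
  unreviveable membership-weighted mean would drift to the global image
  mean, which can pin the pair threshold exactly on a region's intensity
  and deadlock the flow.
* **Per-side normalization, hard gating.** Each side's bracket is
  normalized over that side's own pixels (saturating at $\pm 1$
  elsewhere): normalizing over the whole image lets a high-contrast side
  set the scale and starves the other side of force. Gating by the sign of
  $\phi_1$ (rather than $H_\epsilon(\phi_1)$) matters for the same reason:
  at $\epsilon = 0.3$ a soft gate leaks $\approx 9\%$ of the other side's
  saturated bracket into every pixel, enough to cancel weak revival
  forces.
* **Degenerate pairs.** If a pair's means are closer than 2% of the image
  intensity range there is no evidence for a second phase on that side;
  normalizing the bracket would amplify pure noise to unit force. The side
  then collapses deterministically onto the $\phi_2 \le 0$ member. This is
  what makes a genuinely two-valued image end with two populated phases.

Default initializations are two overlapping orthogonal band rectangles, so
all four sign combinations start with substantial area and each interface
crosses most of the image. Labels are reported as sign regions; tissue
names are assigned afterwards by ranking the phase means (brightest = WM
in T1-weighted images).

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| $\Delta t$ | 1 | – | time step of the explicit update |
| $\alpha$ | auto (±20); 30 in four-phase | – | balloon force, sign = expand/shrink |
| $\sigma_{fit}$ | 5 | px | scale of the local fitting kernel |
| $\sigma_{reg}$ | 1 | px | level-set regularization filter |
| $\epsilon$ (`epsH`, `epsD`) | 0.3 | – | Heaviside/Dirac width |
| $\beta$ | 1 | – | contrast-weight gain |
| $\rho$ | 2 | – | initialization magnitude (any positive value gives the same binarized trajectory after one iteration) |
| `maxIters` | 200 | – | iteration cap |
| `tol` | 0 | px | changed-pixel tolerance of the stability test |

Kernels are truncated at $\lceil 3\sigma\rceil$ and renormalized; all
convolutions use replicate padding, so constant fields are fixed points
and no spurious forces arise at image borders. Intensities are rescaled to
$[0,1]$ on load and all defaults are interpreted on that scale. Both
regularization widths carry the reference value 0.3; the classical
Chan–Vese setting $\epsilon = 1.0$ remains available per argument.
Convergence is declared when the binarized mask changes by at most `tol`
pixels for three consecutive iterations — the three-in-a-row requirement
guards against the single quiet iteration that can occur while the front
crosses a flat region. Degenerate inputs are handled explicitly: constant
images produce zero force everywhere (the only self-consistent choice
under max-normalization), empty region sides fall back to the global mean
with a warning, and all ratio denominators are floored at $10^{-12}$.

The $\epsilon$-sensitivity experiment varies the *shared* width of $H$ and
$\delta$ ($\epsilon \in \{0.1, 0.3, 0.8\}$): small $\epsilon$ localizes
$\delta_\epsilon$ so strongly that capture slows and local minima appear,
while large $\epsilon$ softens the memberships until the region statistics
mix across phases. With only the Dirac width varied, the large-$\epsilon$
penalty mostly disappears under the binarized update, which is why the
sweep moves both.

## The phantom generator

`makePhantom()` renders piecewise-constant scenes — disk, rectangle,
hand-like polygon, two vessels, four quadrants, brain-like nested rings —
then applies a smooth multiplicative bias ($I \cdot (1 + b)$, with $b$ a
zero-mean horizontal ramp or a centered Gaussian blob of width
$0.18\,\min(\text{shape})$), adds Gaussian noise, and clips to $[0,1]$
(the clip slightly truncates the noise distribution near the range ends).
The multiplicative form matches MR coil inhomogeneity; the exact label
field is kept, so evaluation has zero annotation ambiguity. Rendering is
bit-reproducible from the stored seed and leaves the caller's RNG state
untouched; the solvers themselves use no randomness.

Two design choices deserve emphasis:

* Two-region phantoms default to background 0.45 / object 0.65. The ratio
  1.44 is deliberate: under bias strengths up to 0.5 the class intensity
  ranges then overlap, which is the regime where a global mid-point rule
  must fail. The disk is placed so its edge runs through the bias blob —
  inhomogeneity straddling the boundary is precisely the configuration
  the blended force is built for, and it keeps the globally-misleading
  band adjacent to the boundary where the local fits can veto it. (A
  misleading patch deep inside a smooth region would defeat the model's
  own premise that global information is reliable away from boundaries.)
* The brain-ring phantom uses bg/CSF/GM/WM = 0.05/0.30/0.55/0.85, the
  T1-weighted brightness ordering, with a mild blob (strength 0.2) and
  noise 0.01.

What passing these phantom tests does *not* show: performance on real MR
data with Rician noise, partial-volume mixing, anatomical texture, or 3-D
context (volumes are processed slice-wise). The phantoms probe the force
design — bias robustness, initialization robustness, multi-region
competition — not MR physics.

## Problem sizes and scope

The shipped experiments use 128×128 two-phase phantoms and 96×96
four-phase phantoms with 50–200 iterations; a full experiment suite runs
in well under a minute on one core, and the scaling is linear in pixels ×
iterations (each iteration is a fixed small number of separable
convolutions). Out of scope by design: curvature-driven edge-stopping
evolution as a baseline, bias-field estimation/correction, more than two
level-set fields, narrow-band acceleration, and surface-distance metrics.

## Known limitations

* The hierarchical coupling privileges $\phi_1$: the coarse bimodal split
  must be meaningful for the refinement to succeed. Scenes whose four
  classes are not separable as two pairs by intensity will frustrate it.
* $\omega$ is computed from raw contrast, so heavy noise raises $C_R$
  everywhere and flattens the weight's discrimination between smooth
  regions and boundaries.
* Far-field capture in the four-phase flow requires
  $\alpha\,\Delta t\,\delta_\epsilon(1)\,|s| > 1$; very small $\alpha$
  confines each field to interface motion and inherits the
  initialization sensitivity that entails.
* Dice of thin structures (the CSF shell) is boundary-dominated and
  saturates well below the values of compact regions even for visually
  good segmentations.
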