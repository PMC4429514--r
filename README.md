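# SPFSeg

Region-based geodesic level-set segmentation for grayscale images whose
intensities drift smoothly within tissue classes — the *intensity
inhomogeneity* (bias field) typical of MR acquisitions. SPFSeg is aimed at
people who need a dependency-light, fully deterministic R implementation of
local+global signed-pressure-force active contours: a two-phase solver for
object/background problems, and a four-phase (two level-set) extension for
WM/GM/CSF-style tissue labeling, together with a seeded phantom generator
carrying exact ground truth and Dice-based evaluation.

## The model

A level-set field φ partitions the image by its sign; the contour is its
zero crossing. Instead of an edge-stopping function, evolution is driven by
a **signed pressure force (SPF)** bounded in [−1, 1], positive where the
contour should expand and negative where it should shrink:

- **Global force** (Chan–Vese statistics): with region means
  c₁ = ∫I·H\_ε(φ)/∫H\_ε(φ) and c₂ its complement,

  s\_g(x) = (I(x) − (c₁+c₂)/2) / max|I − (c₁+c₂)/2|.

- **Local force** (local-binary-fitting statistics): with kernel-weighted
  local fits f₁ = K\_σ∗(H\_ε(φ)I)/K\_σ∗H\_ε(φ) and f₂ its complement,

  s\_l(x) = (I(x) − (f₁(x)+f₂(x))/2) / max|I − (f₁+f₂)/2|.

- **Adaptive blend**: a per-pixel weight ω(x) = exp(−β·C\_R(x)/mean(C\_R)),
  computed once from the 5×5-window Michelson contrast C\_R, gives

  S(x) = ω(x)·s\_g(x) + (1 − ω(x))·s\_l(x),

  so smooth regions are swept quickly by the global force while boundaries
  are placed by the inhomogeneity-robust local fits.

Each iteration applies the transport step φ ← φ + Δt·α·S·|∇φ| (balloon
force α sets expand/shrink), then **binarizes** φ to ±1 and smooths it with
a narrow Gaussian — the selective-binary regularization that replaces both
curvature terms and signed-distance re-initialization.

The four-phase extension evolves two fields jointly; their sign
combinations encode four regions (memberships M₁..M₄ = products of
H\_ε(φ₁), H\_ε(φ₂) and complements, a partition of unity). φ₁ carries the
coarse split under its marginal two-phase force; φ₂ refines each side of φ₁
through pairwise phase competition ((I−c\_b)² − (I−c\_a)² brackets), with
updates localized by the regularized Dirac δ\_ε(φᵢ). Accuracy is measured
by the Dice similarity coefficient DSC = 2N(S₁∩S₂)/(N(S₁)+N(S₂)).

## Worked example

```r
library(SPFSeg)

spec <- phantomSpec(c(128, 128), "disk", bias = "gaussian_blob",
                    biasStrength = 0.5, noiseSigma = 0.02, seed = 1)
ph <- makePhantom(spec)
res <- segmentTwoPhase(phantomImage(ph), init = c(26, 80, 26, 80),
                       evolutionParams(alpha = 20))
res
#> SegmentationResult (proposed mode )
#>   image: 128 x 128  object pixels: 4804
#>   iterations: 26 (converged)
#>   alpha: 20
dice(segMask(res), phantomTruth(ph) == 2)
#> [1] 0.9825
```

The phantom is a disk whose edge runs through a multiplicative bias blob of
strength 0.5, so the class intensity ranges overlap and a single global
threshold cannot separate them. The adaptive blend reaches Dice 0.9825; the
global-only mode (`mode = "gcv"`) on the same input and initialization
stops at 0.9464, misassigning the bias-brightened band along the boundary.

Four-phase tissue labeling of a brain-like ring phantom:

```r
phb <- makePhantom(phantomSpec(c(96, 96), "brain_rings",
                   bias = "gaussian_blob", biasStrength = 0.2,
                   noiseSigma = 0.01, seed = 3))
res4 <- segmentFourPhase(phantomImage(phb),
                         params = evolutionParams(alpha = 30, maxIters = 50))
multiLabelDice(phantomTruth(phb), labelMap(res4))$mean
#> [1] 0.9467
```

The per-label Dice values (best-permutation matching) are 1.000 / 0.879 /
0.909 / 0.998 for background, CSF ring, GM ring and WM core: the thin CSF
shell is the hardest class, as expected for boundary-dominated structures.

A command-line interface wraps the same functions
(`inst/cli/spfseg.R`; subcommands `segment2`, `segment4`, `phantom`,
`evaluate`), writing masks/labels as PNG or NIfTI plus a JSON-lines
iteration log and the fully resolved configuration.

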