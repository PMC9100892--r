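---
title: "Non-destructive root phenotyping of plug seedlings: methods and design"
author: "RootBallPheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-destructive root phenotyping of plug seedlings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RootBallPheno)
```

## The measurement problem

The root system of a plug seedling (here: pumpkin used as a grafting
rootstock) is conventionally phenotyped destructively: the root ball is
washed free of substrate and the roots are flat-bed scanned. That kills the
seedling and caps throughput. A consumer RGB-D camera offers an
alternative: the roots visible on the *surface* of the root ball can be
imaged in situ, measured, and used to predict whole-root-system phenotypes
through allometric relations, because surface-root quantities correlate
strongly with total-root quantities in plug-grown seedlings.

`RootBallPheno` implements that pipeline end to end:

1. **Stitching** — four colour+depth views, taken by rotating the plant
   90° between shots in front of a high-texture fiducial curtain, are
   registered through Harris corners, adaptive non-maximal suppression
   (ANMS), normalized patch descriptors, RANSAC homography estimation, and
   composited into one surface panorama.
2. **Preprocessing** — gain/gamma enhancement, edge-based background
   removal (Sobel edges, morphological closing, largest-component
   filtering), and homomorphic illumination correction.
3. **Segmentation** — a multi-scale Hessian vesselness filter marks
   tubular bright structures; thresholding inside the root-ball foreground
   yields the surface-root mask.
4. **Phenotyping** — the depth point cloud calibrates physical pixel
   scale; non-overlapping roots give the average diameter via the
   area-to-skeleton-length ratio; encapsulation (DSR) and surface-root
   area (SASR) are pixel ratios; linear models predict total-root surface
   area, length and volume.
5. **Synthesis** — a generator renders root-ball scenes with full analytic
   ground truth, so every stage above is testable without a camera.

## Core quantities and formulas

With `S_ROI` the actual surface area of the region of interest (from the
depth point cloud), `n` its pixel count:

* `S_pix = S_ROI / n` (cm² per pixel), `L_pix = sqrt(S_pix)` (cm).
* Skeleton length of the non-overlapping roots:
  `TLSR = N_skeleton × 1.2 × L_pix`. The 1.2 multiplier is the shipped
  average of the pixel edge length (1) and diagonal (√2), compensating the
  mix of straight and diagonal skeleton steps. It is applied exactly as
  published; for perfectly horizontal/vertical chains it overestimates
  length by 20%, for 45° chains it underestimates by 15%, and across the
  orientation mix of real (and our synthetic) roots the net bias on the
  diameter is about −7%. The Euclidean chain length is reported alongside
  (`skeletonLength()$euclideanCm`) for comparison but is never used in the
  published formulas.
* Average diameter of total root: `ADTR = (S_pix × N_mask) / TLSR`,
  reported in µm.
* Encapsulation: `DSR = 100 × N_root / N_matrix` (%).
* Predictions: `SATR = 2.16556 × SASR + 7.6522` (cm²),
  `LTR = SATRP / ADTR` (cm, diameter in cm), `LTRP = 2.9723 × LTR +
  16.83062` (cm), `VTR = π (ADTR/2)² × LTRP` (cm³). The slope/intercept
  pairs are the reference models shipped with the package, fitted on
  pumpkin rootstock plug seedlings; `fitPredictionModel()` refits them
  from paired data. Note that `LTR = SATRP / ADTR` omits the factor π that
  a cylinder's lateral surface would imply; the length model's fitted
  slope (2.9723 ≈ π) absorbs it. The formula is implemented as published,
  not "corrected".

### Vesselness

At scale σ the image is convolved with σ-scaled Gaussian derivative
kernels and the per-pixel 2×2 Hessian is eigendecomposed with
|λ₁| ≤ |λ₂|. Second derivatives are multiplied by σ² (scale-space
normalization) so responses are comparable across scales; the discrete
kernels are moment-corrected so a constant image has an exactly zero
response. The response is

> V = 0 if λ₂ > 0, else exp(−R_B²/2β²)·(1 − exp(−S²/2c²)),

with R_B = |λ₁|/|λ₂| (defined as 0 at flat pixels, avoiding 0/0),
S = √(λ₁²+λ₂²), and the multi-scale response is the pointwise max over a
geometric scale ladder. Bright tubes on dark substrate are assumed
(λ₂ > 0 suppressed); a polarity flag inverts the image for dark roots.

**Parameter c.** The admissible range printed for c in the source
formulation is dimensionally inconsistent with S being the Frobenius norm
of an intensity Hessian, so the package does not guess a fixed value:
`c = "auto"` (half the maximum S per scale, standard Frangi practice) is
the default and any explicit value is passed through verbatim.

**β.** Defaults to 0.5, the midpoint of the commonly recommended low
range [0.3, 2]; it controls how strongly blob-like (non-eccentric)
structures are suppressed.

### Mask refinement and thresholding

The vesselness support does not coincide with the photometric tube
boundary: thin tubes gain a halo, wide tubes lose their rim. Two optional
steps recover width fidelity, both on by default in the pipeline:

* **Hysteresis** (`hysteresisLow = 0.5`): pixels above half the Otsu
  threshold are kept when their component touches the threshold — tube
  cores recruit their full cross-section without admitting detached
  speckle.
* **Intensity refinement** (`refineRootMask()`): within a 2 px dilation of
  the detected mask, pixels brighter than the local Otsu threshold are
  kept, placing the boundary at the bright/dark transition of the roots
  themselves.

### Skeletonization

Topology-preserving two-pass (Zhang–Suen) thinning, followed by a
sequential simple-point reduction: any non-endpoint pixel whose neighbours
remain locally 8-connected after removal is deleted (row-major order, to a
fixed point). The parallel pass alone leaves staircase pixels at
intermediate orientations (up to ~30% length inflation on wide oblique
tubes); the reduction yields a minimal 8-connected path while provably
preserving topology and endpoints. `skeletonLength(smooth = TRUE)`
additionally median-filters (3×3) the mask before thinning — segmentation
boundaries are ragged at the pixel level and would otherwise spawn
skeleton loops; the smoothing is off by default because a 3×3 median
erases structures that are already one pixel wide.

### Non-overlapping root extraction

Erode (disc), median-filter, dilate (disc, same radius — restoration
symmetry), then subtract the restored image from the mask. Single roots
vanish under erosion and cannot be restored, so they survive the
subtraction; overlap regions (near-parallel root bundles) survive erosion,
are restored, and are excluded. The structuring element must be wider than
the thickest single root: the function defaults to radius 2 px (a generic
working-resolution value), while the pipeline configuration uses radius
5 px because the reference study conditions produce roots up to ~11 px
wide after refinement. Point crossings at steep angles are narrower than
the element and stay in the measurement; they are rare for the
near-parallel geometry of real plug-surface roots.

### Calibration

Each valid-depth ROI pixel is back-projected through the pinhole model;
per-pixel surface patch areas are the cross-product norms of the local
3-D tangent vectors (central differences). Invalid (zero) depth is
infilled from nearest valid neighbours first. `smoothSigma` (default 0)
optionally Gaussian-smooths the depth before differentiation: synthetic
float depth needs none (the closed-form plane checks are then exact), but
depth quantized to integer millimetres — the native unit of time-of-flight
sensors and of the 16-bit files the package writes — has 1 mm steps whose
finite differences would corrupt patch areas, so the pipeline uses
σ = 2 px when it loads depth from disk and `smooth_sigma` is left at its
default.

## The synthetic scene generator

The generator emulates the capture, not the optics of a real sensor:

* **Geometry.** The root ball is a vertical cylinder (radius 60 mm, axis
  245 mm from the camera, pinhole focal length 1800 px), seen as a
  240×640 px panorama whose central 140-row band is the plug surface. The
  front-surface pixel subtends ~103 µm. Depth per column follows the
  analytic ray–cylinder intersection; the fiducial curtain sits at 400 mm
  behind a 16 px dark occlusion gap with invalid (zero) depth, mimicking
  time-of-flight dropout at the silhouette.
* **Roots.** Smooth random-walk tubes of per-root constant width (default
  4–9 px ≈ 400–900 µm), drawn with sub-pixel anti-aliased coverage, butt
  caps and round joins. Headings are near-horizontal (±45°) with mild
  wander: surface roots of a plug run along the plug wall, and isotropic
  walks would cross far more often than real roots do. Substrate is dark
  with bright perlite-like speckle (density 0.15) — the main distractor
  class for the vesselness filter.
* **Views.** Four windows with 40% overlap (adjacent quarter-turn views of
  a cylinder share a wide arc), the first a pure crop (the reference
  plane), the others mildly projectively perturbed, plus Gaussian
  intensity noise (sd 2/255). True view→panorama homographies are stored
  in the ground truth.
* **Ground truth** uses analytic centreline geometry — never pixel counts
  — under the *mean-pixel-scale convention*: lengths and areas are
  image-plane quantities scaled by the mean per-pixel surface area of the
  depth model over the band, the same mean that the calibration equations
  themselves define. The ±20% within-scene variation of the true pixel
  scale across the curved surface is therefore not represented in the
  truth values; it is a known simplification.

What passing tests on these scenes show — and what they do not: the
pipeline recovers commanded diameters within ~5–15% across 400–900 µm,
registration is accurate to <10⁻³, calibration matches closed forms. They
do not show robustness to wet specular soil, root/substrate colour
overlap, depth noise beyond quantization, or parallax between the root
surface and the fiducial plane (views here are exact homographies of one
panorama; a real root ball has depth relief, which the source workflow
also ignores by stitching with a single homography per view).

## Registration accuracy

Descriptor matching alone pairs only corners that survive ANMS in both
frames (a few dozen here); two refinements follow, both standard:

1. **Guided re-matching**: project all detected corners through the
   RANSAC estimate, pair by proximity (1.2 px), refit by least-squares
   DLT.
2. **Photometric (direct) refinement**: Gauss–Newton on the eight
   homography parameters minimizing the intensity SSD over the overlap,
   on images pre-smoothed with σ = 1.5 px (damping the model mismatch
   that bilinear resampling induces at sharp fiducial edges).

On noise-free synthetic view sets the chained view→reference homographies
are recovered to ~10⁻⁴–10⁻³ normalized Frobenius error; the RANSAC stage
alone tolerates ≥20% outliers at 2 px reprojection tolerance.

## Numerical and design choices

* Pixel coordinates are 1-based (x = column, y = row); homographies act on
  homogeneous (x, y, 1) and are normalized to H₃₃ = 1.
* Colour is blended with centre-weighted feathering; depth is warped
  nearest-neighbour with first-valid-wins overlap resolution — feathering
  depth would invent geometry.
* "Remove components smaller than half the total" in background removal is
  interpreted as *half the largest component's area* (an
  absolute-image-fraction mode is available): on root-ball images this
  keeps exactly the root-ball blob.
* Otsu thresholds: Sobel-magnitude threshold and vesselness threshold
  default to Otsu (restricted to the foreground for vesselness); the
  source workflow prints no constants.
* Homomorphic filter: gain γL + (γH−γL)(1 − exp(−D²/2d₀²)) on the centred
  frequency radius, applied to log(1+x); defaults γL = 0.5, γH = 1.5,
  d₀ = 0.05·min(H, W). With γH = γL = 1 the filter is an exact all-pass.
  Output is min–max rescaled to [0, 1] with a constant-image guard.
* Degenerate inputs are first-class: flat images yield zero corners, an
  all-zero vesselness map yields an empty mask with a warning, a zero
  skeleton raises an `undefinedDiameter` condition, stage failures abort
  the pipeline naming the stage.
* Problem sizes in the test-suite: scenes are 240×640 px with 8–12 roots;
  the diameter-recovery study uses 20 seeded scenes spanning width centres
  4.2–8.6 px, measured on the panorama directly (registration is validated
  separately) — these sizes exercise every code path at full fidelity
  while keeping a full run in minutes on one core.

## Known limitations

* The headline agreement figures of the source workflow (93.3% diameter
  consistency with a scanner, 88.1%/87.2% prediction accuracies, 29 µm
  mean diameter error) require live plants and scanner references and are
  out of scope here; `validateAgainstTruth()`/`runBatch()` reproduce the
  *form* of those analyses (per-plant error tables, batch medians) against
  synthetic truth.
* DSR compares measured-foreground ratios against the generator's
  band-wide ratio; morphological margins and ROI insetting make the
  measured foreground noticeably smaller than the ideal band (more so
  after stitching, where warped view borders trim it further), so DSR
  validation errors of tens of percent on synthetic scenes reflect that
  definitional mismatch more than segmentation error — SASR, whose
  numerator and physical scale are shared with DSR, validates to a few
  percent.
* The 1.2 length factor's −7% diameter bias is inherited from the
  published method and deliberately not corrected.
* The generator's conservation property (analytic area = S_pix × mask
  count) holds per root to <1%; on dense multi-root scenes the union mask
  undercounts by the genuinely overlapped area, which is the very effect
  the non-overlap extraction exists to handle.
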