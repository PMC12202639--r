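---
title: "Methods: seat-comfort metrics, shape averaging and foam identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seat-comfort metrics, shape averaging and foam identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergoseat)
```

This vignette documents the models behind `ergoseat`, the conventions
and parameters that matter, what the synthetic-data generators emulate
(and deliberately do not), and the numerical choices made where the
design was genuinely open.

## Pressure-map statistics

A body-pressure recording is a rectangular grid of cell pressures in
kPa with a physical cell pitch, taken at the cushion or backrest
interface. A cell is *in contact* when its pressure strictly exceeds a
threshold (default 0 kPa — the "non-zero units" convention; a positive
value models a sensor noise floor and is exposed everywhere the
default matters). Over the $n$ contact cells of a region:

$$\mathrm{SPD} \;=\; \frac{\sum_{i=1}^{n} (p_i - p_{ave})^2}{4\,n\,p_{ave}^2},$$

with $p_{ave}$ the mean over *contact cells only*. Averaging over all
cells would make the statistic depend on how much empty mat surrounds
the sitter, which is an artefact of pad size, not of comfort. The
index runs over the $n$ contact cells ($n$ terms); SPD is
scale-invariant ($\mathrm{SPD}(c\,p) = \mathrm{SPD}(p)$), zero exactly
when all contact pressures are equal, and $1-\mathrm{SPD}$ is reported
alongside so that larger values mean more comfort. These identities
are tested, as is bit-level agreement with an independent brute-force
loop.

Conventions chosen once and kept fixed:

* **Histogram bins** are half-open $[kw, (k{+}1)w)$ starting at 0,
  width 4 kPa by default. A pressure exactly on an edge falls in the
  upper bin.
* **Grid orientation**: row 1 is the top of the mat as exported.
  Orientation is metadata; every metric is orientation-invariant, and
  the segmentation operations take explicit row indices (or a physical
  height in mm, converted through the row pitch).
* **Backrest segmentation**: the waist/back division is the row where
  the upper end of L1 projects onto the backrest — rows below it
  (toward the cushion) are waist, rows at or above are back. The
  hip/legs division of the cushion has no anatomically defined default;
  it is a required user parameter.
* **Ideal ranges** for the regional maximum pressure are closed
  intervals, default 7–11 kPa (buttocks/hip) and 4–8 kPa (lower
  back/waist), configurable per region.
* **Units**: kPa for interface pressure, MPa for tissue stress and foam
  stress, mm for geometry, cm² for contact area, degrees for angles.

## Spinal angles

Cervical lordosis (CC), thoracic kyphosis (TTK) and lumbar lordosis
(LL) are Cobb angles between vertebral endplate lines. The default
levels follow standard radiographic convention — CC: inferior C2 vs
inferior C7; TTK: superior T1 vs inferior T12; LL: superior L1 vs
superior S1 — and are configurable, since different studies measure
slightly different spans.

The sagittal plane defaults to the least-squares plane of all endplate
corner landmarks (override by passing a normal). Within the plane, the
2D frame is *intrinsic*: the cranial axis runs from the most caudal to
the most cranial vertebra centroid, and the anterior axis is the mean
posterior-to-anterior corner direction orthogonalized against it.
Because a Cobb angle is a difference of direction angles, any common
rotation of the frame cancels, so the angles are exactly invariant
under rigid motion and uniform scaling — a property the tests assert at
1e-9 degrees. Signs: lordotic curvature of the cervical and lumbar
regions and kyphotic curvature of the thoracic region are positive;
mirroring the curvature flips all three signs.

## Mean shape by generalized Procrustes analysis

Correspondence first: the base scan is warped by the thin-plate RBF
field taking its landmarks onto the target's landmarks (69 manually
placed landmarks in the classical protocol), then every warped base
point snaps to its nearest neighbour on the target, ties broken toward
the lowest target index. The result has the base's point count and
ordering, so clouds become homologous.

Alignment: for homologous clouds the optimal *proper* rotation
minimizing $\|X R - \bar X\|_F$ after centering is obtained from the
SVD of the cross-covariance, with the determinant sign corrected by
flipping the axis of the smallest singular value — the deterministic
tie-break for degenerate spectra, and the guard that a human body is
never mirrored. Centering is applied even though the underlying
formulation is written with a rotation only: scanner frames differ by
translations, and translation removal is the standard Procrustes
preprocessing. No scale is fitted — absolute anthropometric size (the
50th-percentile stature) is the quantity of interest.

The mean iterates: align all clouds to the running mean, re-average
point-wise, stop when the relative objective change drops below
`tol = 1e-6` or after `max_iter = 100` iterations (non-convergence
returns a flagged result with a warning). Both half-steps are descent
steps, so the objective trace is non-increasing — asserted on every
tested run. The mean is reported rigidly aligned back onto the first
cloud's frame.

## Landmark-driven morphing

The deformation field is an RBF interpolant with first-degree
polynomial drift — the interpolant of universal Kriging with a linear
trend. This matches the behaviour a Kriging-based scaling module
guarantees (exact landmark interpolation, affine reproduction,
smoothness) without asserting equivalence to any particular commercial
implementation, whose covariance and nugget settings are not public.
The default kernel is the 3D thin-plate (biharmonic) kernel
$\varphi(r) = r$; a Gaussian kernel with explicit width is available.
Regularization defaults to 0 (exact interpolation, residuals < 1e-8 mm
at 142-point scale); a positive ridge trades exactness for smoothness
on noisy landmark sets. The bordered linear system is solved densely;
a condition estimate above 1e12 triggers a warning rather than a
silent bad solve. Duplicate control points are rejected by name, and
coplanar control sets are rejected because the 3D drift is then
ill-posed.

## Foam hysteresis model

The quasi-static point model keeps the parameter set of a nonlinear
viscoelastic foam material card — density RO, tensile modulus E, the
compressive loading curve, hysteretic unloading coefficient HU,
unloading shape factor SHAPE, creep decay constant BETA — and gives the
unloading branch the phenomenological form

$$\sigma_u(\varepsilon) = \sigma_l(\varepsilon)\,
  \Big[\mathrm{HU} + (1-\mathrm{HU})\,
  \big(W(\varepsilon)/W(\varepsilon_{max})\big)^{\mathrm{SHAPE}}\Big],$$

with $W(\varepsilon)=\int_0^{\varepsilon}\sigma_l\,d\varepsilon'$
computed exactly (piecewise quadratic) for the piecewise-linear
loading curve. The form is continuous at the reversal point, collapses
to the loading curve at HU = 1, and never exceeds it for HU ≤ 1. For a
linear curve $\sigma = E\varepsilon$ with SHAPE = 1 it has the closed
form $E\varepsilon\,[\mathrm{HU} + (1-\mathrm{HU})
(\varepsilon/\varepsilon_{max})^2]$, which the tests use as an
analytic oracle. This is a desk-scale stand-in for a solver's internal
hysteresis model, suitable for parameter identification and loop-area
diagnostics; equivalence with any commercial material model is not
claimed. BETA is stored but excluded from the quasi-static fit — the
comfort analysis this package supports is static.

Identification minimizes the sum of squared unloading-branch stress
residuals over (HU, SHAPE) within bounds (HU ∈ [1e-3, 1],
SHAPE ∈ [0.05, 10]) using L-BFGS-B from 8 starts (one central, seven
drawn uniformly from a fixed seed). Tension and compression are
treated as separate curves. Noise-free recovery is exact to well
under 1%; at 2% relative noise the mean of 20 replicate estimates
stays within 5%.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *statistical structure* of the study's
inputs, not their mechanics:

* **Cushion maps** sum two exponential-decay bumps at the ischial
  tuberosities (heavier tails than Gaussian bumps, closer to mat data)
  inside an elongated contact ellipse covering buttocks and thighs;
  **backrest maps** use one mid-waist bump decaying to the periphery.
  Noise is zero-truncated Gaussian, added only inside the contact
  patch. Default amplitudes put the cushion maximum inside the 7–11
  kPa ideal band and the baseline backrest maximum inside 4–8 kPa,
  which is where a comfortable baseline configuration sits.
* **Condition series** migrate load from cushion to backrest as the
  angle grows (amplitudes and contact-patch axes move linearly with
  the recline fraction), and draw internal responses from smooth
  effect models — monotone vertebral stress and disc strain, U-shaped
  disc stress — plus relative Gaussian noise. The shipped studies use
  five whole-chair angles (0–40°) and four backrest angles (0–30°),
  2% internal noise and 0.3 kPa pressure noise.
* **Spines** realize requested (CC, TTK, LL) *exactly* when unjittered:
  endplate tilts vary linearly within each region so the bounding
  Cobb differences equal the targets, and vertebra bodies are stacked
  with positive disc gaps (overlap raises an error). Corner jitter of
  0.5 mm on ~30 mm endplates propagates to roughly 1.7° of angle noise
  — the recovery tests assert that statistically honest envelope, not
  wishful precision.
* **Body-scan families** warp a template by smooth Gaussian-RBF fields
  constrained to zero mean across subjects — so the template *is* the
  true mean and recovery is well-posed — then rotate rigidly (≤ 20° by
  default) and add 1 mm coordinate noise.

None of this simulates buttock soft-tissue contact, foam deformation
fields, or gravity settling; passing tests demonstrate that the
*computations* are correct on data with the right shape, not that any
seat is comfortable.

## Problem sizes and numerical tolerances

The test and acceptance runs use 100 random maps for oracle
equivalence (1e-12), 20 random 50-point cloud pairs against 10,000
random rotations each for Procrustes optimality, 4 subjects × 300
points for mean-shape recovery (RMSD ≤ 1 mm at 1 mm noise), 40
controls and 200 probe points for morphing (1e-8 mm interpolation,
1e-6 affine reproduction), a 27-point curvature grid for spinal
recovery (0.5°), and 60–80-sample foam tests. These sizes exercise
every code path at full fidelity; all the algorithms are polynomial in
the input size and have been run on clouds an order of magnitude
larger.

Degenerate inputs are errors, not silent answers: empty contact sets
(SPD undefined), strains beyond the loading-curve domain, zero plane
normals, coincident endplate corners, duplicate or coplanar morphing
controls, constant series in trend correlation, and incomplete
hysteresis cycles all raise descriptive errors naming the offending
record.

## Known limitations

* Nearest-neighbour correspondence assumes the target scan densely
  samples the surface; sparse or partial scans will snap several base
  points to one target vertex.
* The intrinsic sagittal frame requires the spine's anterior direction
  to be distinguishable from its long axis; a pathologically collapsed
  spine (all endplates parallel to the cranio-caudal axis) is rejected.
* The foam model is quasi-static and uncoupled between tension and
  compression; rate effects (BETA) are carried but never applied.
* Trend similarity with few conditions (4–5) takes coarse rank values;
  it orders hypotheses rather than testing them.
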