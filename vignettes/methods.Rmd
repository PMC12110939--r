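---
title: "Quantifying bilateral corneal elevation symmetry: model, registration and validation"
author: "corneaSym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bilateral corneal elevation symmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corneaSym)
```

## The problem

Fellow eyes are, to a good approximation, mirror images of each other
(enantiomorphs). Corneal ectasias such as keratoconus are typically
asymmetric between the eyes, so the *difference* between one cornea and the
mirrored fellow cornea is a sensitive, patient-specific probe of early
disease: each patient serves as their own reference surface. This package
implements that comparison for dense Scheimpflug elevation exports: square
(typically 140 × 140, 0.1 mm step) matrices of corneal surface height in
micrometers relative to a best-fit sphere, one matrix per eye and surface
layer.

The summary statistic is the **VBS index**: after registering the mirrored
left eye onto the right eye, the mean of the absolute point-wise elevation
differences over a central circular zone, in micrometers. The clinically
standard zones are 4.0 mm (where keratoconic asymmetry concentrates) and
6.0 mm. A derived "volume" reading (VBS × zone area) is reported for
interpretability but plays no role in thresholds.

## Coordinate conventions

Physical coordinates are `x = (col − c) · s`, `y = (row − c) · s`
millimeters with `s` the grid step and `c` the center index. The default
center is the *exact* geometric center `(n + 1) / 2` — index 70.5 for
n = 140. With a half-integer center the mirror flip is an exact column
reversal (`x → −x`, an involution that loses no data), and zone masks are
reflection-symmetric. An integer center on an even grid would make the flip
either lossy or off by one step; when a file supplies an apex index it is
honored as-is.

## Registration model

Four adjustments align the mirrored left eye with the right eye,
compensating acquisition differences (head tilt, rotation, decentration,
reference-plane offset):

* **Flip** — the mirror relation between fellow eyes (column reversal).
  Mirror symmetry is the anatomical default; direct (unflipped) comparison
  is available, and mode `auto` optimizes both and keeps the lower VBS
  (ties go to mirror).
* **Shift** — in-plane translation `(dx, dy)` in mm.
* **Rotate** — frontal-plane rotation about the grid center, degrees.
* **Tilt + offset** — a plane `dz + t_x x + t_y y` added to the elevation.
  Head tilt along the sagittal/transverse planes enters device elevation
  maps, to first order, as a planar term: for tilts of a few degrees on a
  ±60 µm elevation range the planar approximation dominates any true 3-D
  surface re-rendering, and it makes the subproblem exactly solvable
  (below).

The transformed moving surface is
`E(R_{−ρ}(x − dx, y − dy)) + dz + t_x x + t_y y`, evaluated by mask-aware
bilinear interpolation: a target sample is valid only if every lattice
neighbor with non-zero weight is valid, so the transform can only shrink
the validity mask, never extrapolate across the missing-data boundary.
Exact lattice hits are snapped (tolerance 10⁻⁹ steps), making identity and
integer-step shifts numerically exact.

## The optimizer

`autoRegister()` minimizes the VBS with a nested scheme:

* **Inner, exact:** for fixed flip/shift/rotation the offset and tilt are
  linear in the model, and the `(dz, t_x, t_y)` minimizing the mean
  *absolute* residual are an L1 (least-absolute-deviation) plane fit to
  the signed difference. `fitL1Plane()` solves it by iteratively
  reweighted least squares (weights `1/max(|r|, 10⁻⁶ µm)`, at most 50
  iterations); the suite verifies it against an exhaustive parameter
  lattice.
* **Outer, derivative-free:** Nelder–Mead over `(dx, dy, rot)` from the
  all-zero start (center matching), preceded by a small deterministic
  probe lattice (±0.4 mm, ±4°) that guards against a stalled start. Every
  accepted (improving) candidate is recorded in the trace, so the trace's
  VBS column is non-increasing by construction, and no randomness is used
  anywhere — identical inputs give bit-identical traces.

Three design choices deserve explanation, because each was forced by a
measurable failure of the naive alternative:

**Objective zone (default 6 mm, reporting still 4 mm).** Shift gradients
of *quadratic* surface components (defocus, astigmatism) are planes, which
the inner tilt fit absorbs exactly; rotation information inside 4 mm from
typical astigmatism is weak. Registering on the 4 mm zone alone under 1 µm
measurement noise leaves the optimum statistically displaced by
~0.1–0.2 mm and 1.5–2°. The 6 mm zone — still well-measured on clinical
devices, and one of the two standard reporting zones — carries several
times more alignment information (its astigmatic and higher-order
structure grows steeply with radius); with it the recovery error drops to
~0.01–0.03 mm and ~0.1°. Set `objectiveZone = zone` to optimize on the
reported zone itself.

**Search-scale smoothing (`searchSmoothPx = 1`).** Bilinear resampling of
white measurement noise attenuates its variance by the squared-weight sum
`s = Σw² ≤ 1`, so a mean-absolute objective on raw noisy grids is *biased
toward half-pixel offsets* (on pure-noise pairs the raw search drifts by
several degrees). The parameter search therefore runs on mask-aware
Gaussian-smoothed copies (σ = 1 step), where the noise is spatially
correlated and resampling is variance-neutral; the reported parameters,
plane and VBS are always re-evaluated on the raw grids, so the VBS
definition itself is untouched.

**Local search box (±0.8 mm, ±8°).** Auto mode refines the initial
center matching; it does not search the full manual-mode validity range
(±2 mm, ±15°). An unconstrained global minimization of a mean-absolute
difference between smooth surfaces will happily slide one eye a
millimeter off the anatomical correspondence to overlay unrelated
structure — we measured a keratoconus pair's VBS deflating from 12.0 to
4.7 µm that way. Decentrations beyond a millimeter are not plausible
acquisition artifacts; the box is generous for real head misalignment
while preventing anatomical nonsense.

### The noise floor of a registered comparison

If the only interocular difference is independent per-eye Gaussian noise
of sd σ, the aligned difference is N(0, σ√2) and the expected VBS is the
folded-normal mean **2σ/√π**. After a sub-lattice registration the moving
eye's noise is attenuated by its per-point squared-weight sum `s_i`, so
the exact expectation becomes `σ·sqrt(2/π)·mean_i sqrt(1 + s_i)` — up to
~15% below the lattice-aligned value. `noiseFloorVBS()` computes this
closed form for any transform; the test suite checks measured
post-registration VBS against it (and against the 1.1 × naive-floor upper
bound), rather than pretending resampling does not exist.

## Pattern classification

The registered signed difference map is decomposed into orthonormal
Zernike terms up to radial order 4 on the zone (least squares over valid
points, radius normalized to the zone radius). Piston is excluded
everywhere, making the classification invariant to constant offsets.
With energy fractions of the non-piston spectrum, the rule set is:

| label | rule (defaults) |
|---|---|
| `flat` | fitted non-piston RMS < 3 µm |
| `tilt` | tilt terms Z1⁻¹/Z1¹ carry ≥ 0.5 of the energy |
| `four_leaf` | astigmatism terms Z2⁻²/Z2² carry ≥ 0.5 |
| `cone` | defocus/spherical Z2⁰/Z4⁰ carry ≥ 0.5 *and* the central deviation agrees in sign with the fitted radial profile |
| `irregular` | no group dominates, or the cone sign check fails |

This transparent energy rule replaces a machine-learned classifier that
cannot be reproduced without its training data; the four canonical
patterns map naturally onto low-order Zernike structure (a residual plane
is tilt; aniso-astigmatism is the quadrant pattern; a unilateral cone is a
signed central bulge). Scores are the energy fractions normalized to sum
to one with the winning label as the argmax. Thresholds live in
`patternControl()`.

## The synthetic cornea simulator

`renderSurface()` builds device-style elevation maps from a parametric
surface: conicoid sagitta `z(r) = r² / (R(1 + sqrt(1 − (1+Q) r²/R²)))`
(apical radius R ≈ 7.8 mm anterior, asphericity Q ≈ −0.25) minus a
reference-sphere sagitta (best-fit by default, keeping elevations in the
±tens-of-µm device range), plus a toric term
`cyl · cos²(θ − axis) · (r/r_max)²` and an optional Gaussian cone bump.
Points outside the circular 12 mm footprint are missing, as on the
instrument (which is also why a 140 × 140 matrix holds roughly 20 000
usable measurements rather than 19 600 complete cells).

`makePair()` assembles a fellow-eye acquisition: OD is the base surface
with per-field deltas applied; OS is the mirrored base observed through an
injected misalignment transform; both eyes then receive independent
Gaussian measurement noise. The ground truth carries the injected
parameters, the *exact* re-aligning parameters (the mirror-conjugated
inverse of the injected transform — verified to cancel it to
interpolation accuracy), and the noise-free mirror-registered VBS.

Height detail beyond the quadric matters, and its anatomy is split
deliberately:

* a **mirror-shared** mid-scale component (Gaussian bumps, σ 0.4–1.1 mm)
  models the shape detail fellow eyes have in common. It is what makes
  rigid registration well-posed: a pure quadric plus noise leaves shift
  degenerate with tilt.
* a **per-eye independent** fine-scale component (σ 0.15–0.45 mm) models
  true interocular asymmetry. Broad independent undulations cannot play
  this role: any VBS-minimizing registration absorbs 30–45% of them by
  legitimate re-alignment, so the observable residual asymmetry is
  modeled directly at scales the search cannot exploit.

Cohort priors (`makeCohort()`, scenario `"separated"`): toric amplitudes
30–90 µm at the footprint edge (≈0.5–2 D of corneal cylinder), interocular
deltas in radius/asphericity/cylinder/axis, misalignments up to 0.4 mm /
4° / 8 µm·mm⁻¹, per-eye noise 1 µm, independent irregularity 5.5–7.5 µm
RMS, and for cases a unilateral cone of 25–60 µm amplitude (σ 0.6–1.0 mm)
within 0.8 mm of the corneal vertex. These ranges were fixed once so that
registered group means land on the clinically reported scale (normals in
the mid-single digits, keratoconus roughly double) — a calibration aid for
realism, not a validation claim. Scenario `"null"` omits the cones, so
screening performance should sit at chance.

What the simulator does *not* emulate: biomechanically coupled shape
change, Scheimpflug ray-geometry artifacts, pupil/iris segmentation
errors, spatially correlated device noise, or longitudinal progression.
Passing tests on these synthetics therefore demonstrates the correctness
and statistical behavior of the pipeline, not clinical performance on
patients.

## Screening statistics

`compareGroups()` is an unequal-variance (Welch) comparison with the
Welch–Satterthwaite 95% CI — the safer reading of an "independent samples
t-test", reducing to the pooled test under equal variances. Zero-variance
degenerate inputs are refused rather than silently producing infinite
statistics. `screenThresholds()` sweeps VBS cutoffs with the strict rule
*positive ⇔ VBS > threshold* (so "no control exceeded τ" maps to all
controls negative at τ); rates with empty denominators are `NA`, never 0
or 1. One VBS per eye *pair* is the unit of analysis.

## Numerical choices and degenerate inputs

* Elevations are micrometers everywhere internally; readers convert mm
  exports on input. Blank cells, `NA`, `NaN` and the −1000 sentinel are
  missing; any other non-numeric cell is an error with its row/column.
* Zone reports require ≥ 90% coverage of the zone's lattice by default
  and refuse otherwise, reporting the observed coverage. Ring summaries
  use 0.5 mm annuli partitioning the zone, so the point-weighted ring
  means reassemble the VBS exactly.
* Lattice-point averaging is the VBS definition; `areaWeighted = TRUE`
  down-weights rim cells by their approximate in-circle area fraction and
  changes the 4 mm VBS by well under 0.01 µm on smooth fields.
* Outer convergence: Nelder–Mead relative tolerance 10⁻⁸, 200 iterations;
  non-convergence returns the best parameters flagged
  `converged = FALSE`. Whether the plane is applied before or after the
  shift is immaterial — with the planar tilt model the two commute, and
  the inverse-parameter helper encodes the exact composition algebra.

## Problem sizes used in validation

The shipped suite exercises full-size 140 × 140 grids throughout:
misalignment recovery and the exhaustive-search comparison on 20 simulated
pairs each, the pattern suite on 25 maps per class (noiseless and at 2 µm
noise), and one simulated 30 + 30 screening study for the group-level
statistics; smaller grids (n = 60–100) appear only in unit tests of exact
algebraic properties where grid size is immaterial.

## Known limitations

* Rigid + planar-tilt registration cannot represent torsional
  misalignment combined with true 3-D tilt exactly; for clinically
  plausible angles the residual is far below measurement noise.
* VBS minimization absorbs any asymmetry component expressible as a small
  rigid motion plus a plane — including genuine axis aniso-astigmatism,
  part of which a rotation can cancel. This is a property of the method,
  not of the implementation.
* The pattern rules are intentionally coarse: mixed or off-axis
  pathologies land in `irregular` rather than being force-fitted into a
  canonical class.
* Published cohort figures from patient data (group means, screening
  thresholds and their sensitivities/PPVs) depend on an unavailable
  clinical dataset; this package reproduces the *procedure* and validates
  it on simulated corneas with known ground truth.
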