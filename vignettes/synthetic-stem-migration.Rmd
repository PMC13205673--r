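---
title: "Synthetic stem migration in hip CT: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic stem migration in hip CT: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctmigsim)
```

## The problem

CT-based implant migration measurement (CT-RSA) promises sub-millimeter
tracking of a femoral stem between a post-operative baseline scan and later
follow-ups. Validating such a tool is hard: marker-based radiostereometry
needs special equipment and implanted tantalum beads, double examinations
irradiate patients twice without producing a true migration signal, and
physical phantoms lack soft tissue and patient anatomy. `ctmigsim`
implements the alternative: manufacture follow-up CTs *digitally* from a
single baseline by moving only the implant voxels by known integer-voxel
steps, so that every synthetic follow-up carries an exact, controlled
ground-truth migration while all surrounding anatomy, HU statistics and
artifacts stay untouched.

## The simulation pipeline

For one baseline CT with a congruent label volume (bones, stem, head) and
three stem landmarks (stem center, stem tip, a neck point):

1. **Stem frame** (`build_stem_frame`). The stem coordinate system has its
   y axis along the stem centerline (unit vector tip→center, positive
   superior), its x axis along the component of the neckline orthogonal to
   y (positive medial), and z completing a right-handed frame (positive
   anterior for right hips). For left hips the x axis is negated so results
   read "as if all hips were right-sided"; the simulator and the
   measurement share the same frame, so the convention is consistent
   end-to-end.
2. **Rotation into the frame** (`resample_to_frame`). The CT is resampled
   onto a grid whose axes are parallel to the stem frame. The grid spacing
   inherits the CT spacing permuted to the closest-aligned axes, so "one
   voxel" in the stem-aligned grid remains commensurate with the scanner
   spacing; this is also what makes the ground truth
   `shift × spacing` meaningful in millimeters.
3. **Integer-voxel shift** (`apply_shift`). All stem+head voxels are
   translated by `(dx, dy, dz)` voxels as a pure integer array move — no
   interpolation, so the simulated displacement is exact by construction.
   Tissue at the destination is overwritten (a physical implant displaces
   tissue); the overlap fraction is reported.
4. **Hole filling** (`fill_vacated`). Voxels the implant vacated receive
   the HU of their nearest (Euclidean, mm-scaled) soft-tissue voxel,
   followed by a mean filter over the vacated set only. The smoothing
   window draws on already-filled voxels and surrounding soft tissue; bone
   and implant HU never bleed into the fill. Bone is excluded as a donor
   because the vacated space in a real revision fills with soft tissue, not
   cortical bone.
5. **Inverse rotation** (`resample_from_frame`). The modified volume is
   resampled back onto the original scanner grid using the exact inverse of
   the recorded rigid relation. Filling precedes the inverse resampling so
   interpolation smooths the filled region like everything else.

The ground truth of a follow-up is `(dx·sx, dy·sy, dz·sz)` with `s` the
stem-aligned grid spacing; the identity is enforced exactly in the manifest.

## The shift protocol

Per baseline, the default protocol (`full_protocol`) enumerates:

* one-axis families: x and z from −4 to +4 voxels, y from −5 to +5 (the
  stem axis maps to the axial scanner direction, whose spacing is
  smallest), including the zero shift per family — 9 + 11 + 9 = 29;
* two-axis families: for each pair of axes, diagonal steps `(a, ±a)` with
  `a ∈ ±1..4` (16 per pair), plus one all-zero shift — 49.

That is 78 follow-ups per baseline; ten baselines give 780, splitting
90/110/90/490 across the families. Zero-migration precision on axis *q*
pools every one-axis record generated along the other two axes, giving pool
sizes 200 (x), 180 (y), 200 (z) drawn from 290 distinct zero-migration
follow-ups. The zero shift is emitted once per one-axis family and once in
the two-axis family because both the family counts (9 + 11 + 9, 48 + 1)
and the pool sizes require per-family zeros.

One enumeration detail was genuinely ambiguous: for a reduced two-axis
bound `m`, the pair rule `a ∈ ±1..m, b ∈ {a, −a}` yields `4m` shifts per
pair (16 at the default m = 4), so `two_axis_max = 1` gives 13 shifts, not
a smaller ad-hoc count; the package follows the rule.

## The digital phantom

`generate_phantom` builds a baseline that has exactly the structure the
simulator relies on, with no patient data: a tapered metal stem (frustum,
tip radius one third of the shoulder radius) along an oblique centerline, a
metal neck (radius half the stem radius) joining the shoulder to a
spherical prosthetic head — one connected metal component, as for a
monoblock prosthesis — inside a coaxial bone cylinder, wrapped in a
soft-tissue ellipsoid, surrounded by air. Default HU levels are typical
clinical values (air −1000, soft tissue 40, bone 1200, metal 3000 HU);
default spacing (0.7812, 0.7812, 0.45) mm mirrors a common clinical hip
protocol, and `scanner_spacing_table()` provides the ten per-scanner
spacings (in-plane 0.72–0.86 mm, axial 0.45–0.6 mm) used by
`study_phantom_configs()`. Gaussian image noise (default SD 20 HU, a
typical soft-tissue noise level) is seeded and applied to the image only;
optional radial streaks emulate metal artifacts cosmetically.

The geometry is validated against the protocol: the implant must keep at
least 6 voxels of margin on every axis so that every shift of the protocol
(up to 5 voxels) stays inside the grid. Left-side phantoms are exact
mirror images of right-side ones, which exercises the right-sided reporting
convention.

What the phantom does *not* emulate: real pelvic anatomy, bone texture and
trabecular structure, beam-hardening physics, scanner reconstruction
kernels, or patient repositioning between scans. Tests passing on phantoms
therefore demonstrate the correctness of the simulation and evaluation
machinery, not clinical performance of any measurement tool.

## The measurement stand-in

The AI-based tools this simulator is meant to validate are proprietary.
So that the evaluation layer can be exercised end-to-end, the package ships
a transparent stand-in (`measure_translation`): threshold segmentation at
2500 HU reduced to the largest 26-connected component, then either

* **centroid** — difference of the HU-weighted mask centroids, rotated into
  the stem frame; exact on noise-free, axis-aligned data, but subject to
  threshold-boundary flutter (~0.1 mm scale) once genuine interpolation is
  involved; or
* **xcorr** — normalized cross-correlation of the HU in a 2-voxel-dilated
  implant neighborhood (the metal interior is nearly constant, so the
  registration signal lives on the boundary), searched over integer offsets
  in a window centred on the centroid estimate, with parabolic sub-voxel
  refinement. This is the more accurate method on noisy, tilted-frame data
  and is what `scripts/acceptance.R` uses.

The stand-in measures translations only. Rotation differences measured by
an external tool can be supplied to `report_tables` as pre-computed values,
so the zero-rotation precision table remains computable; a
threshold-centroid method cannot credibly estimate rotations of a
near-symmetric solid, and rotational migration simulation is out of scope
(the voxel-shift design is inherently translational). Femur-to-femur
registration is omitted: the simulator never moves the femur, so that
alignment is the identity by construction.

## Evaluation statistics

All statistics operate on signed differences, defined as ground truth minus
measurement:

* per-axis summaries (mean, sample SD with the n−1 denominator, min, max),
  per family and combined;
* zero-migration **precision** = 1.96 × SD over the per-axis zero pools
  (the half-width of the 95% interval);
* **Bland–Altman** limits of agreement = mean ± 1.96 × SD, with the 95% CI
  of the mean (SD/√n) and of each limit (the standard approximation
  SD·√(3/n)); the plot-ready output puts the amount of migration on the
  abscissa so systematic bias is visible directly;
* **Q-Q data** against normal quantiles at probability points (i − 0.5)/n,
  scaled by the sample mean and SD.

Display rounding is three decimals; all internal computation is unrounded.
A single-record selection reports SD 0 with an explicit flag rather than
NA, so degenerate subsets are visible instead of silently dropped.

## Numerical choices

* Interpolation: linear for HU, always nearest for labels (preserves label
  identity). Out-of-volume padding is −1024 HU (air), neutral for
  thresholding.
* The stem-aligned grid is sized from the voxel-center bounding box of the
  source volume, so for an axis-aligned frame the grid points coincide with
  source voxel centers and the round trip is bit-exact — this is what makes
  the zero-shift follow-up literally identical to its baseline.
* Nearest-donor filling uses an expanding-shell search that is exact under
  the mm-scaled Euclidean metric (the shell lower bound must exceed the
  best distance found before the search stops); ties between equidistant
  donors are broken by scan order.
* NCC peaks with a perfect score are accepted as exact integer matches;
  parabolic refinement is skipped there since it could only perturb them.
* Seeds: every stochastic step (phantom noise, streak directions) is an
  explicit function argument; `study_phantom_configs` derives per-baseline
  seeds from one master seed, keeping all seeds within 32-bit range.

## Problem sizes

The test suite exercises the full 78-shift protocol on a 96×96×128
noise-free phantom and the complete ten-baseline, 780-follow-up study on
64×64×112 phantoms with the ten scanner spacings — sizes chosen so the
whole simulation and evaluation cycle runs comfortably on a single CPU
while every protocol count (78, 780, 90/110/90/490, pools 200/180/200 of
290) is exercised at full scale. Larger grids change runtime, not logic:
all operations are linear in voxel count.

## Known limitations

* Migration resolution is bounded below by the voxel spacing: sub-voxel
  shifts cannot be simulated directly — a limitation inherited from the
  voxel-shift design itself.
* Only translations are simulated; rotational migration, subsidence with
  tilting, and bone remodeling are out of scope.
* The destination-overwrite policy is a modeling choice; real implant
  micro-motion compresses rather than replaces tissue.
* The stand-in is a validation device for this package's evaluation layer.
  Its accuracy and precision say nothing about any clinical CT-RSA product,
  and the package makes no claim of reproducing any specific tool's
  clinical values.
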