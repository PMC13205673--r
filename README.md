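# ctmigsim

Synthetic implant-migration simulation for validating CT-based migration
measurement (CT-RSA) of femoral stems.

## The problem

Measuring how a hip stem migrates between a post-operative baseline CT and a
follow-up CT is a key predictor of implant loosening, and modern CT-RSA
tools claim sub-millimeter accuracy. Validating those claims is the hard
part: radiostereometry needs tantalum markers and dedicated equipment,
double-examination studies irradiate patients twice and contain no true
migration signal, and physical phantoms lack soft tissue and real anatomy.

`ctmigsim` takes the remaining route: it manufactures follow-up CTs
*digitally* from a single baseline scan. Only the implant voxels move —
by known integer-voxel steps in a stem-aligned coordinate frame — while
every other voxel keeps its original HU. Each synthetic follow-up therefore
carries an exact, controlled ground-truth migration, and any measurement
tool can be scored against it.

## Method in brief

With a stem coordinate system (y along the stem centerline, positive
superior; x along the neckline, positive medial; z anterior-positive,
reported as if all hips were right-sided), one follow-up is produced by

1. resampling the baseline CT onto a stem-aligned grid whose spacing
   inherits the scanner spacing,
2. translating the stem+head voxels by an integer shift (dx, dy, dz) —
   a pure array move, no interpolation,
3. filling vacated voxels with nearest-neighbor soft-tissue HU plus mean
   smoothing,
4. resampling back to the scanner grid with the exact inverse transform.

The ground truth is `(dx·sx, dy·sy, dz·sz)` in mm, with `s` the
stem-aligned grid spacing. The default protocol runs, per baseline, 29
one-axis shifts (x, z: −4..+4; y: −5..+5 voxels) and 49 two-axis diagonal
shifts ((a, ±a), a ∈ ±1..4, per axis pair, plus one zero) — 78 follow-ups
per baseline, 780 over the ten bundled scanner configurations.

The evaluation layer computes the standard agreement statistics on
differences (ground truth − measurement): per-family summaries,
zero-migration precision (1.96 × SD over the per-axis zero pools of size
200/180/200), Bland–Altman limits of agreement (mean ± 1.96 × SD), and Q-Q
normality data.

A digital hip phantom generator (`generate_phantom`) and a transparent
threshold/centroid/NCC measurement stand-in (`measure_translation`) close
the loop so everything is testable without patient data.

## Worked example

```r
library(ctmigsim)

cfg   <- phantom_config(noise_sd_hu = 0, stem_tilt_deg = 0)
ph    <- generate_phantom(cfg)            # ct, labels, landmarks
frame <- build_stem_frame(ph$landmarks)

# shift the implant 2 voxels superior along the stem axis
g <- generate_followup(ph$ct, ph$labels, frame, shift_spec(0, 2, 0, "y"),
                       spec = resample_spec("nearest"))
g$record[, c("followup_id", "generating_axes", "dy", "truth_y_mm")]
#>   followup_id generating_axes dy truth_y_mm
#> 1    followup               y  2        0.9

m <- measure_translation(ph$ct, g$followup, frame)
round(m$translation_mm, 4)
#> [1] 0.0 0.9 0.0
```

The stem axis maps to the scanner's axial direction (0.45 mm spacing), so a
2-voxel shift is a 0.9 mm superior migration; the stand-in recovers it
exactly on this noise-free, axis-aligned phantom. A zero shift reproduces
the baseline bit-for-bit.

The full study loop — ten phantoms with the bundled scanner spacings, 780
follow-ups, measurement and report tables — is one call:

```r
run <- run_simulation(study_phantom_configs(seed = 1),
                      measurement = measurement_config(method = "xcorr"))
run$tables$zero_precision   # per-axis n = 200 / 180 / 200, precision = 1.96 SD
```

A command-line front end is installed as `exec/ctmigsim` with subcommands
`generate-phantom`, `simulate`, `measure` and `evaluate` (NIfTI volumes in,
CSV manifests and tables out).

## Scope

Translations only: rotational migration is not simulated (a voxel-shift
design is inherently translational), sub-voxel shifts are below the
method's resolution, and the bundled measurement is a stand-in for
exercising the evaluation layer — it is not a clinical tool, and no claim
is made about any proprietary CT-RSA product. See the methods vignette
(`vignettes/synthetic-stem-migration.Rmd`) for design details and
limitations.
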