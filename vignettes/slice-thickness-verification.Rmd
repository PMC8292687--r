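---
title: "Automated slice-thickness verification: methods and design notes"
author: "ctsliceQC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated slice-thickness verification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsliceQC)
```

## The measurement

CT slice thickness is verified on the AAPM performance phantom by imaging
its stair insert: thin aluminum plates inclined through the slice so that
the reconstructed in-plane width of each bar encodes the slice sensitivity
profile. The operational definition used throughout this package is the
full width at half maximum (FWHM) of the averaged intensity profile across
the middle bar, converted from pixels to millimetres with the DICOM
`PixelSpacing`.

`measureSliceThickness()` composes the stages, each exposed as its own
function so they can be tested and inspected individually:
`segmentStairs()` → `selectMiddleObject()` → `cropAbout()` →
`houghAngle()` → `rotateToUpright()` → `recropWindow()` → `meanProfile()`
→ `fwhm()`.

```{r example}
img <- generatePhantom(synthParams(nominalMm = 3, seed = 1L))
measureSliceThickness(img)
groundTruth(img)$trueFwhmMm
```

## Model assumptions

- **One frame, one measurement.** Each axial frame is analyzed
  independently; a series of repeated frames is aggregated as mean ±
  sample SD (`aggregateFrames()`; n − 1 denominator, recorded in the CLI
  output metadata since either convention is defensible).
- **Three parallel bars.** The phantom is assumed to carry three stair
  bars; the middle one is measured, assuming its thickness does not differ
  from its neighbors'.
- **FWHM equals slice thickness.** No ramp-angle factor is applied to the
  measured width: the plates are treated as a 45°-equivalent geometry in
  which the in-plane width equals the slab thickness. The generator
  mirrors this (`rampFactor = 1`) and exposes the factor for other
  geometries, because the true plate inclination of a given phantom copy
  is a property of the hardware, not of the algorithm.
- **Water baseline.** The half level is `baseline + (peak − baseline)/2`
  with the baseline estimated as the mean of the lowest quartile of the
  profile. With water ≈ 0 HU this nearly coincides with literal peak/2,
  but it makes the measurement invariant to HU offsets;
  `halfMode = "raw"` reproduces the literal convention.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `threshold` | `"auto"` (Otsu on HU in (−200, 1200)) | aluminum/water contrast ≈ 900 HU makes any reasonable split work; a fixed level (e.g. +200 HU) is available for reproducibility audits. Out-of-window pixels (air) are excluded from the histogram, otherwise the air/water split dominates. |
| area filter | 20–2000 px at 0.508 mm/px, scaled by (0.508/spacing)² | a 25.4 mm bar of 1–10 mm width spans ≈ 100–1000 px; the foundation strip is larger, speckle smaller |
| elongation filter | ≥ 3 | plates are thin and long (25.4 mm length vs ≤ 10 mm width) |
| crop half-size | 32 px (≈ 33 mm window) | holds a 25.4 mm bar at any rotation |
| θ grid | 0.5° over [−90°, 90°) | FWHM error from a residual angle ε scales as 1 − cos ε < 0.004% at 0.5° |
| re-crop | 30 × 30 px | excludes the foundation and neighbor bars while keeping enough water rows for the baseline |
| `noiseFloorHu` | 50 HU | declares a window empty well above averaged noise (σ/√30 ≈ 1.8 HU at σ = 10) and well below any real bar peak |

## The Hough angle and its conventions

The orientation is estimated from the standard (ρ, θ) line Hough transform
of the binarized crop. Two design points deserve explanation:

- **Integrated response.** Every foreground pixel votes exactly once per
  θ, so the plain ρ-sum of the accumulator is constant in θ and carries no
  orientation information. The 1-D response reported per θ is therefore
  the ρ-sum of the *squared* normalized accumulator — a vote-concentration
  measure that is flat for isotropic point clouds and peaks sharply where
  the votes collapse onto single lines, i.e. at the bar orientation.
  Votes are split linearly between the two nearest 1-px ρ bins;
  experiments during development showed hard rounding biases the argmax by
  up to one grid step, while sub-pixel ρ bins collapse onto the
  axis-aligned artifact created by integer pixel coordinates.
- **Angle convention.** `angleDeg` is the smallest-magnitude rotation that
  makes the bar axis-aligned, in (−45°, 45°], with ties broken toward 0.
  Both a perfectly vertical and a perfectly horizontal bar report 0°. The
  across-bar profile axis is then auto-detected from the upright window
  (the across-bar marginal has much higher dispersion than the along-bar
  one), so the convention cannot silently flip the profile direction.

Rotation uses bilinear interpolation with the border-median (water) fill.
Bilinear resampling of a near-Nyquist edge (the default PSF leaves the
900 HU bar edge spanning ≈ 1.5 px) carries a local error of up to ~10% of
the contrast; this does not propagate into the measurement — the measured
FWHM varies by < 3% over true angles within ±15° — but exact
rotate/un-rotate identity should only be expected for adequately sampled
content, and the test suite checks it on a band-limited bar.

## The synthetic phantom

`generatePhantom()` renders the phantom analytically rather than through a
projection/reconstruction simulation: a water disc (0 HU, radius 92 mm) in
air (−1000 HU), three bars (25.4 mm long, width = nominal thickness) at
12 mm vertical pitch with a 6 mm lateral staircase step, and a 16 × 40 mm
foundation strip just left of the bar ends. Partial-volume coverage is
computed exactly on a 4 × 4 sub-pixel grid, the image is convolved with a
Gaussian PSF (σ 0.6 px default) and i.i.d. Gaussian noise is added
(σ 10 HU default). Defaults correspond to a 512² reconstruction of a
260 mm field of view.

Geometry choices that matter downstream:

- the 6 mm stagger separates the bar centroids along both axes, so both
  the column-sort of `segmentStairs()` and the principal-axis ranking of
  `selectMiddleObject()` are exercised non-trivially;
- the foundation's area (≈ 2500 px) exceeds the bar area filter, so
  segmentation rejects it, and it sits > 20 mm left of the middle-bar
  center, so both the 65 × 65 Hough crop and the 30 × 30 re-crop exclude
  it at all rotations up to ±15° and offsets up to ±40 mm;
- `groundTruthFwhm()` is the FWHM of rect(width) ⊛ Gaussian(σ), computed
  by dense numeric convolution (step ≤ width/1000) with the same
  half-maximum definition the measurement uses, and cross-checked in the
  tests against the closed-form erf profile.

What the generator does *not* emulate: reconstruction artifacts (streaks,
beam hardening), correlated reconstruction noise (noise here is white),
partial phantom tilt out of plane, and the exact plate inclination of a
physical insert. Passing the closed-loop tests therefore demonstrates the
correctness of the measurement chain on images with known truth, not the
absolute accuracy of any particular scanner's slice profile; the
reconstruction-filter presets (`filterPreset()`) vary PSF and noise only,
which is the first-order effect of kernel choice.

## Numerical choices and degenerate inputs

- FWHM crossings by linear interpolation between adjacent samples,
  scanning outward from the peak; with multiple crossings (residual
  foundation pixels, noise bumps) the pair nearest the peak wins. Verified
  against a 1000× upsampled counting oracle to within 0.02 px.
- A peak at the window edge (no crossing on one side) is an error advising
  a larger window, not a truncated width.
- Pixel spacing for the mm conversion is the row spacing along the profile
  axis; a warning is emitted if row/col spacings differ by more than 0.1%.
- Zero-contrast images produce explicit "no stair objects found" / "no bar
  in window" errors rather than arbitrary thresholds.
- DICOM writing stores 16-bit values with intercept −2048, leaving
  headroom so noisy air (< −1024 HU) survives the round-trip within the
  0.5 HU quantization.

## Problem sizes

The test suite validates the closed loop at the defaults (512² matrix)
with five seeds per nominal thickness 1–5 mm, three seeds per offset
{0, ±20, ±40} mm and per filter preset, and angles {−10…+10}°; unit tests
use a 256² phantom with identical spacing and stair geometry. The
acceptance script measures 25 frames (5 thicknesses × 5 replicates) at the
defaults. These sizes were chosen to estimate means to well under the
0.1–0.3 mm tolerances being checked.

## Known limitations

- Single-frame DICOMs with uncompressed little-endian transfer syntaxes
  only; multi-frame objects and compressed syntaxes are out of scope.
- Phantoms with a number of stair bars other than three are not handled.
- Angles beyond ±45° alias to the complementary axis under the
  nearest-axis convention; physical phantom placements are within a few
  degrees of upright.
- The measured FWHM is reported as-is; deconvolving the in-plane PSF's
  small broadening contribution (≈ 0.1% at 5 mm, ≈ 8% at 1 mm) is
  deliberately not attempted, matching standard practice for this insert.
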