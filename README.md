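# ctsliceQC

Automated verification of CT slice thickness from axial images of the AAPM
CT performance phantom.

Slice thickness is a core CT image-quality parameter: it sets the
cross-plane resolution and trades off against image noise, so routine
quality control has to confirm that the reconstructed thickness matches the
nominal setting. On the AAPM phantom this is done with the stair-bar insert
— thin inclined aluminum plates in water whose in-plane image width encodes
the slice sensitivity profile. The conventional measurement (placing
electronic calipers on the middle bar by eye) is slow and subjective;
`ctsliceQC` automates it for medical physicists and QC engineers.

## Method

For one axial frame the pipeline is:

1. **Segmentation** — threshold the image (Otsu on HU clipped to
   [−200, 1200], or a fixed level), label 8-connected components, and keep
   bar-shaped ones (area and elongation filters reject the foundation strip
   and speckle).
2. **Middle bar** — rank the bar centroids by projection onto their
   principal axis and take the second; crop a 65 × 65 px window about its
   centroid.
3. **Deskew** — estimate the bar orientation θ with a (ρ, θ) line Hough
   transform on the binarized crop (θ grid 0.5°, anti-aliased ρ voting,
   response = ρ-integrated squared normalized accumulator) and rotate the
   crop by the smallest angle that makes the bar axis-aligned (bilinear
   interpolation, water-median fill).
4. **Profile and FWHM** — re-crop 30 × 30 px to exclude the foundation,
   average along the bar's long axis into a 1-D profile, and measure the
   full width at half maximum,

   FWHM = x₊ − x₋ with profile(x±) = baseline + (peak − baseline)/2,

   where the crossings are located by linear interpolation between samples
   (sub-pixel) and the baseline is the lowest quartile of the profile
   (surrounding water). The width in pixels is converted to mm with the
   DICOM `PixelSpacing`; the FWHM is the measured slice thickness.

Per series, repeated frames are aggregated as mean ± sample SD, and
automated results can be compared with manual caliper values via the
percent difference `100 · |manual − automated| / automated`.

A synthetic phantom generator (`generatePhantom()`) renders the stair
geometry analytically — water cylinder in air, three bars on a foundation,
arbitrary rotation and iso-center offset, Gaussian PSF and noise — with an
analytic ground-truth FWHM (`groundTruthFwhm()`), so the whole pipeline is
validated end-to-end without scanner data.

## Worked example

```r
library(ctsliceQC)

# five synthetic 5 mm frames, written and re-read as DICOM
paths <- file.path(tempdir(), sprintf("frame%d.dcm", 1:5))
for (s in 1:5)
  writeDicom(generatePhantom(synthParams(nominalMm = 5, seed = s)), paths[s])

results <- lapply(readSeries(paths), measureSliceThickness)
results[[1]]
#> SliceThicknessResult: 9.89 px = 5.02 mm (angle 0.0 deg) [...frame1.dcm]

aggregateFrames(results)
#> SeriesResult over 5 frame(s): 5.0 ± 0.0 mm

percentDifference(5.1, 5.7)
#> [1] 11.8
```

The first frame's profile is 9.89 px wide at half maximum, i.e. 5.02 mm at
0.5078 mm/px — within 0.03 mm of the 5 mm nominal setting; the series mean
rounds to 5.0 ± 0.0 mm. The last line is the automated-vs-manual percent
difference for a 5.1 mm automated and 5.7 mm manual reading.

The same operations are available from a shell via the thin CLI wrapper
(`inst/scripts/ctsliceqc`): `measure`, `synth`, `compare` and `validate`
subcommands; see `runCli()`.

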