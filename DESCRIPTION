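Package: ctsliceQC
Title: Automated CT Slice-Thickness Verification on the AAPM Performance Phantom
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated measurement of CT slice thickness from axial images of
    the AAPM CT performance phantom. The stair-bar insert is segmented, the
    middle bar is located, its in-plane orientation is estimated with a Hough
    transform and corrected, and the full width at half maximum (FWHM) of the
    averaged intensity profile across the bar is measured with sub-pixel
    interpolation and converted to millimetres using the DICOM pixel spacing.
    Includes a minimal single-frame CT DICOM reader/writer, a synthetic phantom
    generator with analytic ground truth for end-to-end validation, per-series
    aggregation (mean and standard deviation over frames), automated-vs-manual
    percent-difference reporting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: Software, QualityControl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
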