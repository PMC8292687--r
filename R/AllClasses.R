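#' @import methods
NULL

#' PhantomImage: a calibrated axial CT image
#'
#' Container for one axial CT frame of the AAPM performance phantom (or a
#' synthetic emulation of it): a matrix of Hounsfield units together with the
#' physical pixel spacing and free-text provenance. Synthetic frames carry a
#' ground-truth list used by closed-loop validation.
#'
#' @slot pixels numeric matrix of HU values, indexed `[row, col]`.
#' @slot spacing numeric(2), pixel spacing in mm/px as `(row, col)` — the order
#'   used by the DICOM `PixelSpacing` attribute.
#' @slot sourceId character(1) provenance, e.g. a file path or
#'   `"synthetic:<seed>"`.
#' @slot truth list; empty for scanner data. For synthetic frames it holds
#'   `trueFwhmMm`, `trueAngleDeg`, `barCentersPx` (n x 2 matrix of (row, col))
#'   and `nominalMm`.
#'
#' @seealso [readCTImage()], [generatePhantom()], [pixelData()],
#'   [pixelSpacing()]
#' @export
setClass("PhantomImage",
  representation(
    pixels   = "matrix",
    spacing  = "numeric",
    sourceId = "character",
    truth    = "list"
  ),
  prototype(truth = list())
)

setValidity("PhantomImage", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels) || length(object@pixels) == 0L)
    msg <- c(msg, "pixels must be a non-empty numeric matrix")
  else if (!all(is.finite(object@pixels)))
    msg <- c(msg, "pixels must contain only finite HU values")
  if (length(object@spacing) != 2L || !all(is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be two positive finite values (row, col) in mm/px")
  if (length(object@sourceId) != 1L)
    msg <- c(msg, "sourceId must be a single string")
  if (length(msg)) msg else TRUE
})

#' ObjectRegion: one labeled connected component
#'
#' A single 8-connected foreground component found by [segmentStairs()], with
#' the shape descriptors used to keep stair bars and reject the foundation
#' strip and speckle.
#'
#' @slot label positive integer component label.
#' @slot mask logical matrix in full-image coordinates.
#' @slot bbox integer(4) `(rowMin, colMin, rowMax, colMax)`, 1-based inclusive.
#' @slot centroid numeric(2) `(row, col)` in fractional pixels.
#' @slot areaPx integer(1) number of mask pixels.
#' @slot elongation numeric(1) major/minor principal-axis length ratio, >= 1.
#' @export
setClass("ObjectRegion",
  representation(
    label      = "integer",
    mask       = "matrix",
    bbox       = "integer",
    centroid   = "numeric",
    areaPx     = "integer",
    elongation = "numeric"
  )
)

setValidity("ObjectRegion", function(object) {
  msg <- character()
  if (object@areaPx <= 0L || object@areaPx != sum(object@mask))
    msg <- c(msg, "areaPx must equal the number of TRUE mask pixels and be > 0")
  if (length(object@bbox) != 4L)
    msg <- c(msg, "bbox must be (rowMin, colMin, rowMax, colMax)")
  else {
    b <- object@bbox
    cen <- object@centroid
    if (cen[1] < b[1] - 0.5 || cen[1] > b[3] + 0.5 ||
        cen[2] < b[2] - 0.5 || cen[2] > b[4] + 0.5)
      msg <- c(msg, "centroid must lie inside bbox")
  }
  if (object@elongation < 1)
    msg <- c(msg, "elongation must be >= 1")
  if (length(msg)) msg else TRUE
})

#' AngleEstimate: bar orientation from the Hough transform
#'
#' Orientation of the stair bar estimated from the integrated line-Hough
#' response of the binarized crop (see [houghAngle()]). `angleDeg` is the
#' smallest-magnitude rotation (degrees) that aligns the bar's long axis with
#' an image axis; applying `-angleDeg` with [rotateToUpright()] makes the bar
#' axis-aligned.
#'
#' @slot angleDeg numeric(1) in (-45, 45], a multiple of the theta grid step.
#' @slot response numeric vector in [0, 1]: integrated normalized Hough
#'   magnitude per theta sample.
#' @slot thetaDeg numeric vector of theta samples (degrees), same length as
#'   `response`.
#' @export
setClass("AngleEstimate",
  representation(
    angleDeg = "numeric",
    response = "numeric",
    thetaDeg = "numeric"
  )
)

setValidity("AngleEstimate", function(object) {
  msg <- character()
  if (length(object@response) != length(object@thetaDeg))
    msg <- c(msg, "response and thetaDeg must have equal length")
  if (any(object@response < 0 | object@response > 1 + 1e-12))
    msg <- c(msg, "response values must lie in [0, 1]")
  if (length(object@angleDeg) != 1L || !is.finite(object@angleDeg))
    msg <- c(msg, "angleDeg must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' IntensityProfile: averaged profile across the stair bar
#'
#' The 1-D profile obtained by averaging the re-cropped window along the bar's
#' long axis, with the baseline (surrounding water), peak, and the level at
#' which the width is measured.
#'
#' @slot values numeric vector, mean HU per across-bar pixel index.
#' @slot baseline numeric(1) HU of the surrounding water.
#' @slot peak numeric(1) maximum of `values`.
#' @slot halfLevel numeric(1) HU level at which FWHM is measured.
#' @export
setClass("IntensityProfile",
  representation(
    values    = "numeric",
    baseline  = "numeric",
    peak      = "numeric",
    halfLevel = "numeric"
  )
)

setValidity("IntensityProfile", function(object) {
  msg <- character()
  if (!all(is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (object@peak < object@baseline)
    msg <- c(msg, "peak must be >= baseline")
  if (object@peak > object@baseline &&
      (object@halfLevel <= object@baseline || object@halfLevel >= object@peak))
    msg <- c(msg, "halfLevel must lie strictly between baseline and peak")
  if (length(msg)) msg else TRUE
})

#' SliceThicknessResult: FWHM of one frame
#'
#' Result of the full automated measurement on a single frame: the profile
#' FWHM in (fractional) pixels and in millimetres, the applied rotation
#' correction, and provenance.
#'
#' @slot fwhmPx numeric(1) full width at half maximum in pixels.
#' @slot fwhmMm numeric(1) `fwhmPx * spacingMm`.
#' @slot spacingMm numeric(1) pixel spacing along the profile axis (mm/px).
#' @slot angleDeg numeric(1) rotation correction that was applied (degrees).
#' @slot frameId character(1) provenance of the frame.
#' @export
setClass("SliceThicknessResult",
  representation(
    fwhmPx    = "numeric",
    fwhmMm    = "numeric",
    spacingMm = "numeric",
    angleDeg  = "numeric",
    frameId   = "character"
  )
)

setValidity("SliceThicknessResult", function(object) {
  msg <- character()
  if (object@fwhmPx <= 0) msg <- c(msg, "fwhmPx must be > 0")
  if (abs(object@fwhmMm - object@fwhmPx * object@spacingMm) >
      1e-9 * max(1, abs(object@fwhmMm)))
    msg <- c(msg, "fwhmMm must equal fwhmPx * spacingMm")
  if (length(msg)) msg else TRUE
})

#' SeriesResult: aggregated slice thickness over frames
#'
#' Mean and sample standard deviation (n - 1) of the per-frame FWHM in mm, as
#' reported for a measurement series of repeated frames.
#'
#' @slot meanMm numeric(1) mean FWHM (mm).
#' @slot sdMm numeric(1) sample SD (mm); 0 when only one frame.
#' @slot nFrames integer(1) number of frames.
#' @slot perFrame list of [SliceThicknessResult-class] objects.
#' @export
setClass("SeriesResult",
  representation(
    meanMm   = "numeric",
    sdMm     = "numeric",
    nFrames  = "integer",
    perFrame = "list"
  )
)

setValidity("SeriesResult", function(object) {
  msg <- character()
  if (object@nFrames < 1L || object@nFrames != length(object@perFrame))
    msg <- c(msg, "nFrames must equal length(perFrame) and be >= 1")
  if (object@sdMm < 0) msg <- c(msg, "sdMm must be >= 0")
  if (object@nFrames == 1L && object@sdMm != 0)
    msg <- c(msg, "sdMm must be 0 for a single frame")
  if (length(msg)) msg else TRUE
})

#' SynthParams: synthetic phantom generator parameters
#'
#' Parameters of the synthetic AAPM-like phantom image: a water cylinder in
#' air containing three aluminum stair bars on a foundation strip, with
#' in-plane rotation, offset from iso-center, Gaussian in-plane blur and
#' additive Gaussian noise. Defaults emulate the reference acquisition: a
#' 512 x 512 reconstruction of a 260 mm field of view (0.5078 mm/px).
#'
#' @slot matrixSize integer(1) image side in px.
#' @slot spacingMm numeric(1) pixel size, mm/px.
#' @slot nominalMm numeric(1) nominal slice thickness (mm); the in-plane bar
#'   width is `nominalMm * rampFactor`.
#' @slot barLengthMm numeric(1) bar length (mm).
#' @slot barContrastHu numeric(1) bar HU above water.
#' @slot nBars integer(1) number of stair bars.
#' @slot barPitchMm numeric(1) center-to-center bar spacing (mm).
#' @slot barStaggerMm numeric(1) per-step lateral offset of the staircase (mm).
#' @slot foundation logical(1) include the foundation strip.
#' @slot rotationDeg numeric(1) in-plane rotation of the stair assembly.
#' @slot offsetMm numeric(2) `(dy, dx)` phantom offset from iso-center (mm);
#'   positive dy is downward in image coordinates.
#' @slot psfSigmaPx numeric(1) Gaussian in-plane PSF sigma (px).
#' @slot noiseSigmaHu numeric(1) additive Gaussian noise sigma (HU).
#' @slot rampFactor numeric(1) in-plane width per mm of nominal thickness
#'   (1 = the 45-degree ramp equivalence).
#' @slot waterRadiusMm numeric(1) radius of the water cylinder (mm).
#' @slot seed integer(1) RNG seed; identical parameters and seed give an
#'   identical image.
#'
#' @seealso [synthParams()], [generatePhantom()], [groundTruthFwhm()]
#' @export
setClass("SynthParams",
  representation(
    matrixSize    = "integer",
    spacingMm     = "numeric",
    nominalMm     = "numeric",
    barLengthMm   = "numeric",
    barContrastHu = "numeric",
    nBars         = "integer",
    barPitchMm    = "numeric",
    barStaggerMm  = "numeric",
    foundation    = "logical",
    rotationDeg   = "numeric",
    offsetMm      = "numeric",
    psfSigmaPx    = "numeric",
    noiseSigmaHu  = "numeric",
    rampFactor    = "numeric",
    waterRadiusMm = "numeric",
    seed          = "integer"
  )
)

setValidity("SynthParams", function(object) {
  msg <- character()
  if (object@matrixSize < 64L) msg <- c(msg, "matrixSize must be >= 64")
  if (object@spacingMm <= 0) msg <- c(msg, "spacingMm must be > 0")
  if (object@nominalMm <= 0) msg <- c(msg, "nominalMm must be > 0")
  if (object@psfSigmaPx < 0) msg <- c(msg, "psfSigmaPx must be >= 0")
  if (object@noiseSigmaHu < 0) msg <- c(msg, "noiseSigmaHu must be >= 0")
  if (object@nBars < 1L) msg <- c(msg, "nBars must be >= 1")
  if (length(object@offsetMm) != 2L)
    msg <- c(msg, "offsetMm must be (dy, dx)")
  if (object@rampFactor <= 0) msg <- c(msg, "rampFactor must be > 0")
  if (length(msg)) msg else TRUE
})
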