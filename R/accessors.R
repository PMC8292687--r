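#' @rdname accessors
#' @export
setMethod("pixelData", "PhantomImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("pixelSpacing", "PhantomImage", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("sourceId", "PhantomImage", function(x) x@sourceId)

#' @rdname accessors
#' @export
setMethod("groundTruth", "PhantomImage", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("angleDeg", "AngleEstimate", function(x) x@angleDeg)

#' @rdname accessors
#' @export
setMethod("angleDeg", "SliceThicknessResult", function(x) x@angleDeg)

#' @rdname accessors
#' @export
setMethod("fwhmPx", "SliceThicknessResult", function(x) x@fwhmPx)

#' @rdname accessors
#' @export
setMethod("fwhmMm", "SliceThicknessResult", function(x) x@fwhmMm)

#' @rdname accessors
#' @export
setMethod("profileValues", "IntensityProfile", function(x) x@values)

#' Construct a PhantomImage
#'
#' @param pixels numeric HU matrix `[row, col]`.
#' @param spacing numeric(2) or numeric(1) pixel spacing in mm/px (row, col).
#' @param sourceId character(1) provenance string.
#' @param truth optional ground-truth list (synthetic images).
#' @return a [PhantomImage-class] object.
#' @examples
#' img <- PhantomImage(matrix(0, 64, 64), spacing = 0.5, sourceId = "example")
#' dim(pixelData(img))
#' @export
PhantomImage <- function(pixels, spacing, sourceId = "unknown", truth = list()) {
  if (length(spacing) == 1L) spacing <- c(spacing, spacing)
  new("PhantomImage", pixels = pixels, spacing = as.numeric(spacing),
      sourceId = sourceId, truth = truth)
}

setMethod("show", "PhantomImage", function(object) {
  cat(sprintf("PhantomImage: %d x %d px, %.4f x %.4f mm/px\n",
              nrow(object@pixels), ncol(object@pixels),
              object@spacing[1], object@spacing[2]))
  cat(sprintf("  HU range [%.1f, %.1f]  source: %s%s\n",
              min(object@pixels), max(object@pixels), object@sourceId,
              if (length(object@truth)) "  (ground truth attached)" else ""))
})

setMethod("show", "ObjectRegion", function(object) {
  cat(sprintf(
    "ObjectRegion #%d: area %d px, centroid (%.1f, %.1f), elongation %.1f\n",
    object@label, object@areaPx, object@centroid[1], object@centroid[2],
    object@elongation))
})

setMethod("show", "AngleEstimate", function(object) {
  cat(sprintf("AngleEstimate: %.1f deg (theta grid %.1f deg step, %d samples)\n",
              object@angleDeg,
              if (length(object@thetaDeg) > 1)
                diff(object@thetaDeg[1:2]) else NA_real_,
              length(object@thetaDeg)))
})

setMethod("show", "IntensityProfile", function(object) {
  cat(sprintf(
    "IntensityProfile: %d samples, baseline %.1f HU, peak %.1f HU, half %.1f HU\n",
    length(object@values), object@baseline, object@peak, object@halfLevel))
})

setMethod("show", "SliceThicknessResult", function(object) {
  cat(sprintf("SliceThicknessResult: %.2f px = %.2f mm (angle %.1f deg) [%s]\n",
              object@fwhmPx, object@fwhmMm, object@angleDeg, object@frameId))
})

setMethod("show", "SeriesResult", function(object) {
  cat(sprintf("SeriesResult over %d frame(s): %s mm\n",
              object@nFrames, formatSeries(object)))
})

setMethod("show", "SynthParams", function(object) {
  cat(sprintf(
    "SynthParams: %d px @ %.4f mm/px, nominal %.2f mm, rot %.1f deg, offset (%g, %g) mm\n",
    object@matrixSize, object@spacingMm, object@nominalMm, object@rotationDeg,
    object@offsetMm[1], object@offsetMm[2]))
  cat(sprintf("  PSF sigma %.2f px, noise sigma %.1f HU, seed %d\n",
              object@psfSigmaPx, object@noiseSigmaHu, object@seed))
})
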