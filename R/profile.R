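# Averaged-profile FWHM measurement on the upright bar window, and the
# end-to-end single-frame pipeline.

#' Re-crop a square window on the upright bar
#'
#' Cuts a `sizePx` x `sizePx` window centered on the bar centroid recomputed
#' after rotation. The default 30 px window is small enough to exclude the
#' stair foundation and the neighboring bars while keeping enough water rows
#' on both sides of the bar for the baseline.
#'
#' @param upright a [PhantomImage-class] after rotation correction.
#' @param center numeric(2) `(row, col)` bar centroid in the upright image.
#' @param sizePx window side in px (default 30).
#' @return a [PhantomImage-class] window.
#' @export
recropWindow <- function(upright, center, sizePx = 30L) {
  stopifnot(is(upright, "PhantomImage"), length(center) == 2L)
  if (sizePx < 1L)
    stop("degenerate re-crop window (sizePx < 1)", call. = FALSE)
  px <- pixelData(upright)
  r0 <- round(center[1]) - floor((sizePx - 1) / 2)
  c0 <- round(center[2]) - floor((sizePx - 1) / 2)
  rows <- max(1, r0):min(nrow(px), r0 + sizePx - 1L)
  cols <- max(1, c0):min(ncol(px), c0 + sizePx - 1L)
  if (length(rows) < 1L || length(cols) < 1L)
    stop("degenerate re-crop window (outside image)", call. = FALSE)
  PhantomImage(px[rows, cols, drop = FALSE], pixelSpacing(upright),
               sourceId = paste0(sourceId(upright), ":recrop"),
               truth = groundTruth(upright))
}

#' Average the window into a 1-D across-bar profile
#'
#' Averages pixel values along the bar's long axis, yielding mean HU per
#' across-bar index. The across-bar axis is auto-detected from the window's
#' intensity structure (the long axis is the one whose marginal profile is
#' flatter), so the x-direction convention cannot silently flip; it can also
#' be forced. The baseline is the mean of the lowest quartile of profile
#' values (surrounding water), and the half level is
#' `baseline + (peak - baseline) / 2` (or `peak / 2` with
#' `halfMode = "raw"`).
#'
#' @param window a [PhantomImage-class] from [recropWindow()].
#' @param axis `"auto"`, `"rows"` (profile over rows, averaging columns) or
#'   `"cols"`.
#' @param noiseFloorHu minimum peak-to-baseline contrast (HU) below which the
#'   window is declared empty.
#' @param halfMode `"baseline"` measures at baseline-corrected half maximum;
#'   `"raw"` at literal `peak / 2`.
#' @return an [IntensityProfile-class].
#' @export
meanProfile <- function(window, axis = c("auto", "rows", "cols"),
                        noiseFloorHu = 50, halfMode = c("baseline", "raw")) {
  stopifnot(is(window, "PhantomImage"))
  axis <- match.arg(axis)
  halfMode <- match.arg(halfMode)
  px <- pixelData(window)
  if (axis == "auto") {
    # across-bar marginal has high dispersion (water rows vs bar rows); the
    # along-bar marginal is nearly flat since every column contains the bar
    axis <- if (stats::sd(rowMeans(px)) >= stats::sd(colMeans(px)))
      "rows" else "cols"
  }
  if (axis == "cols") px <- t(px)
  if (nrow(px) < 3L || ncol(px) < 1L)
    stop("window too small for a profile (need >= 3 across-bar samples)",
         call. = FALSE)
  values <- rowMeans(px)
  sv <- sort(values)
  baseline <- mean(sv[seq_len(max(1L, floor(length(sv) / 4)))])
  peak <- max(values)
  if (peak - baseline < noiseFloorHu)
    stop(sprintf("no bar in window (contrast %.1f HU below noise floor %.1f HU)",
                 peak - baseline, noiseFloorHu), call. = FALSE)
  half <- if (halfMode == "baseline") baseline + (peak - baseline) / 2
          else peak / 2
  new("IntensityProfile", values = values, baseline = baseline,
      peak = peak, halfLevel = half)
}

#' Full width at half maximum of a profile
#'
#' Scans outward from the peak for the first samples below the half level on
#' each side and locates the crossings by linear interpolation between
#' adjacent samples, giving sub-pixel precision. When noise produces several
#' crossings, the pair nearest the peak wins.
#'
#' @param profile an [IntensityProfile-class].
#' @return FWHM in fractional pixels.
#' @examples
#' p <- new("IntensityProfile", values = c(0, 0, 10, 10, 10, 0, 0),
#'          baseline = 0, peak = 10, halfLevel = 5)
#' fwhm(p)  # 3
#' @export
fwhm <- function(profile) {
  stopifnot(is(profile, "IntensityProfile"))
  v <- profile@values
  half <- profile@halfLevel
  ip <- which.max(v)
  left <- NA_real_
  if (ip > 1L) {
    for (i in seq(ip - 1L, 1L, by = -1L)) {
      if (v[i] < half) {
        left <- i + (half - v[i]) / (v[i + 1L] - v[i])
        break
      }
    }
  }
  right <- NA_real_
  if (ip < length(v)) {
    for (i in seq(ip + 1L, length(v), by = 1L)) {
      if (v[i] < half) {
        right <- i - (half - v[i]) / (v[i - 1L] - v[i])
        break
      }
    }
  }
  if (!is.finite(left) || !is.finite(right))
    stop("half-maximum level is never crossed on both sides of the peak; use a larger window",
         call. = FALSE)
  right - left
}

#' Measure slice thickness on one frame
#'
#' Runs the full automated pipeline on an axial AAPM-phantom image:
#' segmentation of the stair bars, selection of the middle bar, cropping,
#' Hough orientation estimation, rotation to upright, re-cropping to a
#' 30 x 30 window that excludes the foundation, averaging into an across-bar
#' profile, sub-pixel FWHM, and conversion to mm with the pixel spacing along
#' the profile axis. Deterministic given the image and configuration; stage
#' errors are propagated with the stage name.
#'
#' @param img a [PhantomImage-class].
#' @param config named list overriding any of: `threshold` (`"auto"` or HU),
#'   `cropHalfSizePx` (32), `recropSizePx` (30), `thetaStepDeg` (0.5),
#'   `halfMode` (`"baseline"` or `"raw"`), `noiseFloorHu` (50).
#' @param verbose log stage decisions (threshold, angle, crop center) to
#'   stderr.
#' @return a [SliceThicknessResult-class].
#' @examples
#' img <- generatePhantom(synthParams(nominalMm = 5, seed = 1L))
#' res <- measureSliceThickness(img)
#' fwhmMm(res)
#' @export
measureSliceThickness <- function(img, config = list(), verbose = FALSE) {
  stopifnot(is(img, "PhantomImage"))
  cfg <- utils::modifyList(list(
    threshold = "auto", cropHalfSizePx = 32L, recropSizePx = 30L,
    thetaStepDeg = 0.5, halfMode = "baseline", noiseFloorHu = 50), config)
  say <- function(...) if (verbose) message(sprintf(...))

  regions <- withStage("segmentation",
    segmentStairs(img, huThreshold = cfg$threshold))
  say("segmentation: %d bar(s) found", length(regions))
  mid <- withStage("middle-object", selectMiddleObject(regions))
  say("middle bar centroid: (%.1f, %.1f)", mid@centroid[1], mid@centroid[2])
  crop <- withStage("crop",
    cropAbout(img, mid@centroid, cfg$cropHalfSizePx))
  est <- withStage("hough",
    houghAngle(crop, binarizeThreshold = cfg$threshold,
               thetaStepDeg = cfg$thetaStepDeg))
  say("hough angle: %.1f deg", est@angleDeg)
  upright <- withStage("rotation", rotateToUpright(crop, est))

  # bar centroid recomputed in the upright crop: the filtered component
  # nearest the crop center (the crop was centered on the middle bar)
  cen <- withStage("recrop", {
    px <- pixelData(upright)
    thr <- resolveThresholdHu(px, cfg$threshold)
    lab <- label8(px > thr)
    if (max(lab) == 0L)
      stop("no foreground left after rotation", call. = FALSE)
    ctr <- (dim(px) + 1) / 2
    best <- NULL; bestD <- Inf
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k, arr.ind = TRUE)
      if (nrow(idx) < 10L) next
      cenK <- colMeans(idx)
      d <- sum((cenK - ctr)^2)
      if (d < bestD) { bestD <- d; best <- cenK }
    }
    if (is.null(best))
      stop("no bar-sized component near the crop center", call. = FALSE)
    best
  })
  win <- withStage("recrop", recropWindow(upright, cen, cfg$recropSizePx))
  prof <- withStage("profile",
    meanProfile(win, noiseFloorHu = cfg$noiseFloorHu,
                halfMode = cfg$halfMode))
  wpx <- withStage("fwhm", fwhm(prof))
  spacing <- pixelSpacing(img)
  if (abs(spacing[1] - spacing[2]) > 1e-3 * spacing[1])
    warning(sprintf("row/col pixel spacing differ by > 0.1%% (%.6f vs %.6f mm); using row spacing for the mm conversion",
                    spacing[1], spacing[2]))
  say("fwhm: %.2f px = %.3f mm", wpx, wpx * spacing[1])
  new("SliceThicknessResult", fwhmPx = wpx, fwhmMm = wpx * spacing[1],
      spacingMm = spacing[1], angleDeg = est@angleDeg,
      frameId = sourceId(img))
}
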