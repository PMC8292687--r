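# Stair-bar segmentation: threshold, 8-connected labeling, bar-shape
# filtering, middle-bar selection, and cropping for orientation analysis.

# shape descriptors of one labeled component
regionFromMask <- function(mask, label) {
  idx <- which(mask, arr.ind = TRUE)
  area <- nrow(idx)
  cen <- colMeans(idx)
  # principal-axis elongation from the second central moments of pixel coords;
  # 1/12 per-pixel variance keeps one-pixel-wide components finite
  cv <- stats::cov(idx) * (area - 1) / area + diag(1 / 12, 2)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  new("ObjectRegion",
      label = as.integer(label), mask = mask,
      bbox = c(min(idx[, 1]), min(idx[, 2]), max(idx[, 1]), max(idx[, 2])),
      centroid = as.numeric(cen), areaPx = area,
      elongation = sqrt(max(ev) / max(min(ev), 1e-12)))
}

#' Segment the stair bars in a phantom image
#'
#' Thresholds the image (Otsu on HU clipped to \[-200, 1200\] by default, or a
#' fixed HU level), labels 8-connected foreground components, and keeps those
#' whose size and shape match a thin aluminum stair bar: area within
#' `areaRangePx` (quoted at 0.508 mm/px and scaled by `(0.508 / spacing)^2`)
#' and principal-axis elongation at least `minElongation`. The foundation
#' strip and noise speckle fail these filters.
#'
#' @param img a [PhantomImage-class].
#' @param huThreshold `"auto"` (Otsu) or a fixed HU level; +200 HU is a
#'   reasonable fixed choice, far above water (0 HU) and far below aluminum.
#' @param areaRangePx numeric(2) allowed component area in px at 0.508 mm/px.
#' @param minElongation minimum major/minor axis ratio.
#' @return list of [ObjectRegion-class], sorted by centroid column ascending.
#' @examples
#' img <- generatePhantom(synthParams(seed = 42L))
#' length(segmentStairs(img))
#' @export
segmentStairs <- function(img, huThreshold = "auto",
                          areaRangePx = c(20, 2000), minElongation = 3) {
  stopifnot(is(img, "PhantomImage"))
  px <- pixelData(img)
  thr <- resolveThresholdHu(px, huThreshold)
  mask <- px > thr
  scale <- (0.508 / pixelSpacing(img)[1])^2
  areaRange <- areaRangePx * scale
  if (!any(mask))
    stop("no stair objects found (nothing above threshold)", call. = FALSE)
  lab <- label8(mask)
  regions <- lapply(seq_len(max(lab)), function(k) {
    regionFromMask(lab == k, k)
  })
  keep <- vapply(regions, function(r)
    r@areaPx >= areaRange[1] && r@areaPx <= areaRange[2] &&
      r@elongation >= minElongation, logical(1))
  regions <- regions[keep]
  if (length(regions) == 0L)
    stop("no stair objects found (no component passed the bar-shape filters)",
         call. = FALSE)
  regions[order(vapply(regions, function(r) r@centroid[2], numeric(1)))]
}

#' Select the middle stair bar
#'
#' Ranks the detected bars by projecting their centroids onto the principal
#' axis of the centroid cloud (the stair direction) and returns the one
#' ranked second. Projection onto the fitted stair axis makes the ranking
#' invariant to phantom rotation; for an upright phantom it reduces to
#' column/row order.
#'
#' @param regions list of [ObjectRegion-class] from [segmentStairs()].
#' @return the middle [ObjectRegion-class].
#' @export
selectMiddleObject <- function(regions) {
  if (length(regions) < 3L)
    stop(sprintf("expected at least 3 stair objects, found %d",
                 length(regions)), call. = FALSE)
  cen <- t(vapply(regions, function(r) r@centroid, numeric(2)))
  cc <- sweep(cen, 2, colMeans(cen))
  ax <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 1]
  proj <- cc %*% ax
  regions[[order(proj)[2L]]]
}

#' Crop a square window about a point
#'
#' Axis-aligned crop of side `2 * halfSizePx + 1` centered on the rounded
#' center, clipped at the image borders; pixel spacing and provenance are
#' inherited.
#'
#' @param img a [PhantomImage-class].
#' @param center numeric(2) `(row, col)` in pixels.
#' @param halfSizePx integer half-size of the window.
#' @return a [PhantomImage-class] crop.
#' @export
cropAbout <- function(img, center, halfSizePx = 32L) {
  stopifnot(is(img, "PhantomImage"), length(center) == 2L, halfSizePx >= 0L)
  px <- pixelData(img)
  r0 <- round(center[1]); c0 <- round(center[2])
  if (r0 < 1 || r0 > nrow(px) || c0 < 1 || c0 > ncol(px))
    stop(sprintf("crop center (%.1f, %.1f) lies outside the %d x %d image",
                 center[1], center[2], nrow(px), ncol(px)), call. = FALSE)
  rows <- max(1, r0 - halfSizePx):min(nrow(px), r0 + halfSizePx)
  cols <- max(1, c0 - halfSizePx):min(ncol(px), c0 + halfSizePx)
  PhantomImage(px[rows, cols, drop = FALSE], pixelSpacing(img),
               sourceId = paste0(sourceId(img), ":crop"),
               truth = groundTruth(img))
}
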