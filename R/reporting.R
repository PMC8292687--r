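# Per-series aggregation and automated-vs-manual comparison.

#' Aggregate per-frame results over a measurement series
#'
#' Mean and sample standard deviation (n - 1 denominator) of the per-frame
#' FWHM in mm; a series is typically five repeated frames of one setup.
#' Human-readable output rounds to one decimal; full precision is retained
#' internally.
#'
#' @param results list of [SliceThicknessResult-class] objects.
#' @return a [SeriesResult-class].
#' @export
aggregateFrames <- function(results) {
  if (length(results) < 1L)
    stop("aggregateFrames needs at least one result", call. = FALSE)
  stopifnot(all(vapply(results, is, logical(1), "SliceThicknessResult")))
  mm <- vapply(results, fwhmMm, numeric(1))
  new("SeriesResult",
      meanMm = mean(mm),
      sdMm = if (length(mm) > 1L) stats::sd(mm) else 0,
      nFrames = length(mm), perFrame = results)
}

#' Format a series as "mean +/- sd"
#'
#' @param series a [SeriesResult-class].
#' @return character(1) like `"5.1 ± 0.1"` (mm, one decimal, half-up).
#' @export
formatSeries <- function(series) {
  stopifnot(is(series, "SeriesResult"))
  sprintf("%.1f ± %.1f",
          roundHalfUp(series@meanMm, 1L), roundHalfUp(series@sdMm, 1L))
}

#' Percent difference between automated and manual results
#'
#' `100 * |manual - automated| / automated`, rounded half-up to one decimal.
#' The automated value is the denominator; this convention is the one that
#' reproduces the published comparison tables row-for-row.
#'
#' @param automatedMm automated slice thickness (mm), must be > 0.
#' @param manualMm manual (caliper) slice thickness (mm).
#' @return percent difference, one decimal. Vectorized.
#' @examples
#' percentDifference(5.1, 5.7)  # 11.8
#' percentDifference(3.5, 3.6)  # 2.9
#' @export
percentDifference <- function(automatedMm, manualMm) {
  if (any(!is.finite(automatedMm)) || any(automatedMm <= 0))
    stop("automated value must be positive to serve as the denominator",
         call. = FALSE)
  roundHalfUp(100 * abs(manualMm - automatedMm) / automatedMm, 1L)
}

#' Build an automated-vs-manual comparison table
#'
#' @param labels character vector of condition labels.
#' @param automatedMm,manualMm numeric vectors of means (mm).
#' @return data.frame with columns `condition`, `automated_mm`, `manual_mm`,
#'   `diff_percent`.
#' @export
comparisonTable <- function(labels, automatedMm, manualMm) {
  stopifnot(length(labels) == length(automatedMm),
            length(labels) == length(manualMm))
  data.frame(condition = as.character(labels),
             automated_mm = automatedMm,
             manual_mm = manualMm,
             diff_percent = percentDifference(automatedMm, manualMm),
             stringsAsFactors = FALSE)
}
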