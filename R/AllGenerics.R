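#' Accessors for ctsliceQC objects
#'
#' Small accessor generics so user code never reaches into slots.
#'
#' @param x an object of the corresponding class.
#' @return `pixelData`: the HU matrix; `pixelSpacing`: numeric(2) mm/px
#'   (row, col); `sourceId`: character(1); `groundTruth`: list (empty for
#'   scanner data); `angleDeg`: numeric(1) degrees; `fwhmPx`, `fwhmMm`:
#'   numeric(1); `profileValues`: numeric vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("angleDeg", function(x) standardGeneric("angleDeg"))

#' @rdname accessors
#' @export
setGeneric("fwhmPx", function(x) standardGeneric("fwhmPx"))

#' @rdname accessors
#' @export
setGeneric("fwhmMm", function(x) standardGeneric("fwhmMm"))

#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
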