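# Minimal single-frame CT DICOM I/O (uncompressed little-endian transfer
# syntaxes). Only the attributes the measurement needs are interpreted:
# Rows/Columns, PixelSpacing, RescaleSlope/Intercept, bit depth, PixelData.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_CT_STORAGE  <- "1.2.840.10008.5.1.4.1.1.2"
UID_IMPL_CLASS  <- "1.2.826.0.1.3680043.10.1463.1"

u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32raw <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

padEven <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

strRaw <- function(s, padByte = as.raw(0x20)) padEven(charToRaw(s), padByte)

# one data element, Explicit VR Little Endian
dcmElement <- function(group, element, vr, valueBytes) {
  long <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  c(u16raw(group), u16raw(element), charToRaw(vr),
    if (long) c(as.raw(c(0, 0)), u32raw(length(valueBytes)))
    else u16raw(length(valueBytes)),
    valueBytes)
}

dcmUI <- function(g, e, uid) dcmElement(g, e, "UI", strRaw(uid, as.raw(0)))
dcmCS <- function(g, e, s)   dcmElement(g, e, "CS", strRaw(s))
dcmDS <- function(g, e, s)   dcmElement(g, e, "DS", strRaw(s))
dcmUS <- function(g, e, v)   dcmElement(g, e, "US", u16raw(v))

#' Write a PhantomImage as a CT DICOM file
#'
#' Writes a single-frame CT-like DICOM (Explicit VR Little Endian, 16-bit
#' unsigned stored values with RescaleSlope 1 and RescaleIntercept -1024) so
#' synthetic frames can enter the pipeline through the same door as scanner
#' data. HU values are rounded to the stored-value grid, so a read-back
#' differs from the input by at most 0.5 HU.
#'
#' @param img a [PhantomImage-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readCTImage()]
#' @examples
#' img <- PhantomImage(matrix(0, 32, 32), spacing = 0.5)
#' f <- writeDicom(img, tempfile(fileext = ".dcm"))
#' img2 <- readCTImage(f)
#' @export
writeDicom <- function(img, path) {
  stopifnot(is(img, "PhantomImage"))
  validObject(img)
  px <- pixelData(img)
  sp <- pixelSpacing(img)
  intercept <- -2048  # headroom below -1024 HU so noisy air never clips
  stored <- round(px) - intercept
  stored <- pmin(pmax(stored, 0), 65535)
  # row-major pixel order per the DICOM standard
  storedRowMajor <- as.integer(t(stored))
  pixelBytes <- writeBin(storedRowMajor, raw(), size = 2, endian = "little")

  # deterministic instance UID derived from content
  sopUid <- sprintf("%s.%d.%d", UID_IMPL_CLASS, nrow(px) * ncol(px),
                    abs(sum(storedRowMajor)) %% 1000000L)

  meta <- c(
    dcmElement(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcmUI(0x0002, 0x0002, UID_CT_STORAGE),
    dcmUI(0x0002, 0x0003, sopUid),
    dcmUI(0x0002, 0x0010, UID_EXPLICIT_LE),
    dcmUI(0x0002, 0x0012, UID_IMPL_CLASS)
  )
  ds <- c(
    dcmCS(0x0008, 0x0008, "DERIVED\\SECONDARY"),
    dcmUI(0x0008, 0x0016, UID_CT_STORAGE),
    dcmUI(0x0008, 0x0018, sopUid),
    dcmCS(0x0008, 0x0060, "CT"),
    dcmElement(0x0010, 0x0010, "PN", strRaw("PHANTOM^AAPM")),
    dcmElement(0x0010, 0x0020, "LO", strRaw(substr(sourceId(img), 1, 64))),
    dcmUI(0x0020, 0x000D, paste0(UID_IMPL_CLASS, ".1")),
    dcmUI(0x0020, 0x000E, paste0(UID_IMPL_CLASS, ".1.1")),
    dcmUS(0x0028, 0x0002, 1L),
    dcmCS(0x0028, 0x0004, "MONOCHROME2"),
    dcmUS(0x0028, 0x0010, nrow(px)),
    dcmUS(0x0028, 0x0011, ncol(px)),
    dcmDS(0x0028, 0x0030, sprintf("%.6f\\%.6f", sp[1], sp[2])),
    dcmUS(0x0028, 0x0100, 16L),
    dcmUS(0x0028, 0x0101, 16L),
    dcmUS(0x0028, 0x0102, 15L),
    dcmUS(0x0028, 0x0103, 0L),
    dcmDS(0x0028, 0x1052, sprintf("%d", intercept)),
    dcmDS(0x0028, 0x1053, "1"),
    dcmElement(0x7FE0, 0x0010, "OW", pixelBytes)
  )
  groupLen <- dcmElement(0x0002, 0x0000, "UL", u32raw(length(meta)))
  out <- c(raw(128), charToRaw("DICM"), groupLen, meta, ds)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop(sprintf("cannot open '%s' for writing: %s", path,
                 conditionMessage(e)), call. = FALSE))
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

# --- reading ----------------------------------------------------------------

rawU16 <- function(bytes, off) {
  as.integer(bytes[off]) + 256L * as.integer(bytes[off + 1L])
}
rawU32 <- function(bytes, off) {
  as.integer(bytes[off]) + 256 * as.integer(bytes[off + 1L]) +
    65536 * as.integer(bytes[off + 2L]) + 16777216 * as.integer(bytes[off + 3L])
}

# parse data elements sequentially; returns list keyed "gggg,eeee" -> raw value
parseElements <- function(bytes, off, explicit, stopBeforeGroup = NULL) {
  n <- length(bytes)
  out <- list()
  longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (off + 7L <= n) {
    group <- rawU16(bytes, off)
    elem  <- rawU16(bytes, off + 2L)
    if (!is.null(stopBeforeGroup) && group != stopBeforeGroup) break
    if (explicit) {
      vr <- rawToChar(bytes[(off + 4L):(off + 5L)])
      if (vr %in% longVRs) {
        len <- rawU32(bytes, off + 8L)
        valOff <- off + 12L
      } else {
        len <- rawU16(bytes, off + 6L)
        valOff <- off + 8L
      }
    } else {
      vr <- NA_character_
      len <- rawU32(bytes, off + 4L)
      valOff <- off + 8L
    }
    if (len == 4294967295)  # undefined length (sequences) — not supported
      stop("unsupported DICOM element with undefined length", call. = FALSE)
    key <- sprintf("%04X,%04X", group, elem)
    if (valOff + len - 1L > n)
      stop("corrupt DICOM file: element extends past end of file",
           call. = FALSE)
    out[[key]] <- if (len > 0) bytes[valOff:(valOff + len - 1L)] else raw(0)
    attr(out, "lastOffset") <- valOff + len
    off <- valOff + len
  }
  attr(out, "nextOffset") <- off
  out
}

elemString <- function(elems, key) {
  v <- elems[[key]]
  if (is.null(v)) return(NULL)
  trimws(rawToChar(v[v != as.raw(0)]))  # drop UI NUL padding
}

elemU16 <- function(elems, key) {
  v <- elems[[key]]
  if (is.null(v)) return(NULL)
  rawU16(v, 1L)
}

#' Read a calibrated CT image from a DICOM file
#'
#' Reads a single-frame, uncompressed little-endian CT DICOM and returns a
#' [PhantomImage-class] with pixel values in Hounsfield units
#' (`stored * RescaleSlope + RescaleIntercept`) and the pixel spacing from
#' the `PixelSpacing` attribute (row, col order). Geometry is never rescaled:
#' the FWHM is measured in pixels and only the final mm conversion uses the
#' spacing.
#'
#' @param path path to a DICOM file.
#' @return a [PhantomImage-class]; its ground truth is empty.
#' @examples
#' img <- generatePhantom(synthParams(matrixSize = 128L, seed = 1L))
#' f <- writeDicom(img, tempfile(fileext = ".dcm"))
#' readCTImage(f)
#' @export
readCTImage <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140L ||
      !identical(rawToChar(bytes[129:132]), "DICM"))
    stop(sprintf("not a DICOM file (missing DICM marker): %s", path),
         call. = FALSE)
  meta <- parseElements(bytes, 133L, explicit = TRUE, stopBeforeGroup = 0x0002)
  ts <- elemString(meta, "0002,0010")
  if (is.null(ts)) ts <- UID_EXPLICIT_LE
  if (!ts %in% c(UID_EXPLICIT_LE, UID_IMPLICIT_LE))
    stop(sprintf("unsupported transfer syntax %s (only uncompressed little-endian is supported)", ts),
         call. = FALSE)
  ds <- parseElements(bytes, attr(meta, "nextOffset"),
                      explicit = ts == UID_EXPLICIT_LE)

  rows <- elemU16(ds, "0028,0010")
  cols <- elemU16(ds, "0028,0011")
  if (is.null(rows) || is.null(cols))
    stop("corrupt DICOM: missing Rows/Columns (0028,0010/0011)", call. = FALSE)
  spacingStr <- elemString(ds, "0028,0030")
  if (is.null(spacingStr) || !nzchar(spacingStr))
    stop("calibration error: missing PixelSpacing (0028,0030); cannot convert pixels to mm",
         call. = FALSE)
  spacing <- as.numeric(strsplit(spacingStr, "\\", fixed = TRUE)[[1]])
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("calibration error: malformed PixelSpacing (0028,0030)", call. = FALSE)

  slope <- elemString(ds, "0028,1053")
  intercept <- elemString(ds, "0028,1052")
  slope <- if (is.null(slope)) 1 else as.numeric(slope)
  intercept <- if (is.null(intercept)) 0 else as.numeric(intercept)

  bits <- elemU16(ds, "0028,0100")
  if (!identical(bits, 16L))
    stop(sprintf("unsupported BitsAllocated: %s (only 16 supported)", bits),
         call. = FALSE)
  signed <- identical(elemU16(ds, "0028,0103"), 1L)
  pdRaw <- ds[["7FE0,0010"]]
  if (is.null(pdRaw))
    stop("corrupt DICOM: missing PixelData (7FE0,0010)", call. = FALSE)
  npix <- as.integer(rows) * as.integer(cols)
  if (length(pdRaw) < 2L * npix)
    stop("corrupt DICOM: PixelData shorter than Rows x Columns", call. = FALSE)
  stored <- readBin(pdRaw, "integer", n = npix, size = 2,
                    signed = signed, endian = "little")
  hu <- stored * slope + intercept
  PhantomImage(matrix(hu, nrow = rows, ncol = cols, byrow = TRUE),
               spacing = spacing, sourceId = path)
}

#' Read an ordered series of CT frames
#'
#' Reads several single-frame DICOMs belonging to one acquisition and checks
#' that they share the same pixel spacing (within 1e-6 mm); the measurement
#' series in this workflow is repeated frames of the same setup.
#'
#' @param paths character vector of file paths (order preserved).
#' @return list of [PhantomImage-class] objects, one per path.
#' @export
readSeries <- function(paths) {
  if (length(paths) < 1L)
    stop("readSeries needs at least one path", call. = FALSE)
  imgs <- lapply(paths, readCTImage)
  sp <- vapply(imgs, function(i) pixelSpacing(i)[1], numeric(1))
  spc <- vapply(imgs, function(i) pixelSpacing(i)[2], numeric(1))
  bad <- abs(sp - sp[1]) > 1e-6 | abs(spc - spc[1]) > 1e-6
  if (any(bad))
    stop(sprintf("inconsistent pixel spacing across series: %s",
                 paste(sprintf("%s (%.6f mm)", basename(paths[bad]), sp[bad]),
                       collapse = ", ")), call. = FALSE)
  imgs
}
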