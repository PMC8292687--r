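# Internal numeric and image helpers shared across modules.

# round half away from zero (tables use half-up; R's round() is banker's)
roundHalfUp <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Otsu threshold on HU values clipped to [-200, 1200]; returns an HU level.
# Pixels outside the window (air at -1000) are excluded from the histogram:
# they would otherwise dominate it and pull the split to the air/water gap
# instead of the water/aluminum gap.
autoThresholdHu <- function(hu, clip = c(-200, 1200)) {
  x <- hu[hu > clip[1] & hu < clip[2]]
  if (length(x) < 2L) x <- pmin(pmax(as.vector(hu), clip[1]), clip[2])
  if (diff(range(x)) < 1) return(max(x) + 1)  # no contrast: no foreground
  norm <- (x - clip[1]) / diff(clip)
  thr <- EBImage::otsu(EBImage::Image(matrix(norm, ncol = 1)),
                       range = c(0, 1), levels = 256L)
  thr * diff(clip) + clip[1]
}

resolveThresholdHu <- function(pixels, huThreshold) {
  if (identical(huThreshold, "auto")) autoThresholdHu(pixels)
  else {
    stopifnot(is.numeric(huThreshold), length(huThreshold) == 1L)
    as.numeric(huThreshold)
  }
}

# 8-connected component labeling of a logical matrix. EBImage::bwlabel is
# 4-connected, so components are taken on the 8-adjacency graph of the
# foreground pixels instead. Returns an integer matrix of labels (0 = bg).
label8 <- function(mask) {
  stopifnot(is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  r <- ((idx - 1L) %% nr) + 1L
  co <- ((idx - 1L) %/% nr) + 1L
  # map full-image linear index -> position in idx
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  edges <- NULL
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    rn <- r + d[1]; cn <- co + d[2]
    ok <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
    nidx <- (cn[ok] - 1L) * nr + rn[ok]
    hit <- pos[nidx] > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(which(ok)[hit], pos[nidx[hit]]))
  }
  g <- igraph::make_graph(edges = if (is.null(edges)) integer(0) else
                          as.vector(t(edges)),
                          n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# separable Gaussian blur with replicated borders (no-op for sigma = 0)
gaussBlur <- function(pixels, sigmaPx) {
  if (sigmaPx <= 0) return(pixels)
  as.matrix(EBImage::gblur(pixels, sigma = sigmaPx, boundary = "replicate"))
}

# rotate image content by `deg` about the matrix center with bilinear
# interpolation; samples outside the source are set to `fill`.
rotateBilinear <- function(pixels, deg, fill) {
  if (deg == 0) return(pixels)
  nr <- nrow(pixels); nc <- ncol(pixels)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  th <- deg * pi / 180
  co <- cos(th); si <- sin(th)
  # destination grid (x = col, y = row); inverse-map into the source
  dc <- rep(seq_len(nc), each = nr) - cc
  dr <- rep(seq_len(nr), times = nc) - cr
  sx <- co * dc - si * dr + cc
  sy <- si * dc + co * dr + cr
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0;  fy <- sy - y0
  out <- rep(fill, nr * nc)
  ok <- x0 >= 1L & x0 + 1L <= nc & y0 >= 1L & y0 + 1L <= nr
  if (any(ok)) {
    i00 <- (x0[ok] - 1L) * nr + y0[ok]
    v <- (1 - fx[ok]) * (1 - fy[ok]) * pixels[i00] +
         fx[ok]       * (1 - fy[ok]) * pixels[i00 + nr] +
         (1 - fx[ok]) * fy[ok]       * pixels[i00 + 1L] +
         fx[ok]       * fy[ok]       * pixels[i00 + nr + 1L]
    out[ok] <- v
  }
  matrix(out, nr, nc)
}

# median HU of the 1-px border ring (rotation fill level)
borderMedian <- function(pixels) {
  stats::median(c(pixels[1, ], pixels[nrow(pixels), ],
                  pixels[, 1], pixels[, ncol(pixels)]))
}

# re-raise an error with the pipeline stage name prefixed
withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}
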