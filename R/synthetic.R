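# Synthetic AAPM-like phantom generator: a water cylinder in air holding
# three aluminum stair bars on a foundation strip, with known ground truth.

#' Construct synthetic phantom parameters
#'
#' Defaults emulate the reference acquisition geometry: a 512 x 512
#' reconstruction of a 260 mm field of view (0.5078 mm/px), 0.635 x 25.4 mm
#' aluminum plates imaged as bars whose in-plane width equals the nominal
#' slice thickness (45-degree ramp equivalence, `rampFactor = 1`), about
#' 900 HU of aluminum-water contrast, a Gaussian in-plane PSF of 0.6 px and
#' 10 HU of additive Gaussian noise.
#'
#' @param matrixSize image side in px.
#' @param spacingMm pixel size in mm/px.
#' @param nominalMm nominal slice thickness in mm (0.5 to 10).
#' @param barLengthMm,barContrastHu,nBars,barPitchMm,barStaggerMm stair
#'   geometry: plate length (mm), contrast over water (HU), number of bars,
#'   vertical center-to-center pitch (mm), lateral staircase step (mm).
#' @param foundation include the foundation strip.
#' @param rotationDeg in-plane rotation of the stair assembly (degrees).
#' @param offsetMm numeric(2) `(dy, dx)` offset of the whole phantom from
#'   iso-center in mm (up to about +/-4 cm).
#' @param psfSigmaPx Gaussian in-plane blur sigma in px.
#' @param noiseSigmaHu additive Gaussian noise sigma in HU.
#' @param rampFactor in-plane bar width per mm of nominal thickness.
#' @param waterRadiusMm radius of the water cylinder in mm.
#' @param seed RNG seed; same parameters and seed give an identical image.
#' @return a [SynthParams-class].
#' @seealso [generatePhantom()], [groundTruthFwhm()], [filterPreset()]
#' @export
synthParams <- function(matrixSize = 512L, spacingMm = 260 / 512,
                        nominalMm = 5, barLengthMm = 25.4,
                        barContrastHu = 900, nBars = 3L, barPitchMm = 12,
                        barStaggerMm = 6, foundation = TRUE,
                        rotationDeg = 0, offsetMm = c(0, 0),
                        psfSigmaPx = 0.6, noiseSigmaHu = 10,
                        rampFactor = 1, waterRadiusMm = 92, seed = 1L) {
  new("SynthParams", matrixSize = as.integer(matrixSize),
      spacingMm = spacingMm, nominalMm = nominalMm,
      barLengthMm = barLengthMm, barContrastHu = barContrastHu,
      nBars = as.integer(nBars), barPitchMm = barPitchMm,
      barStaggerMm = barStaggerMm, foundation = foundation,
      rotationDeg = rotationDeg, offsetMm = as.numeric(offsetMm),
      psfSigmaPx = psfSigmaPx, noiseSigmaHu = noiseSigmaHu,
      rampFactor = rampFactor, waterRadiusMm = waterRadiusMm,
      seed = as.integer(seed))
}

#' Reconstruction-filter surrogate presets
#'
#' Named PSF/noise pairs emulating the in-plane effect of smooth, standard
#' and sharp reconstruction kernels: smoother kernels blur more and denoise,
#' sharper kernels do the opposite.
#'
#' @param name one of `"smooth"`, `"standard"`, `"sharp"`.
#' @return list with `psfSigmaPx` and `noiseSigmaHu`.
#' @export
filterPreset <- function(name = c("standard", "smooth", "sharp")) {
  switch(match.arg(name),
         smooth   = list(psfSigmaPx = 0.9, noiseSigmaHu = 7),
         standard = list(psfSigmaPx = 0.6, noiseSigmaHu = 10),
         sharp    = list(psfSigmaPx = 0.4, noiseSigmaHu = 16))
}

# stair assembly geometry in the (unrotated) assembly frame, mm.
# Bars run along the assembly x axis; bar i is centered at
# (stagger * k, pitch * k) with k centered on 0, so the staircase descends
# to the right. The foundation is a wide strip left of the bar ends,
# separated by a small gap; its area exceeds the bar-shape area filter so
# segmentation rejects it.
assemblyGeometry <- function(p) {
  k <- seq_len(p@nBars) - (p@nBars + 1) / 2
  bars <- cbind(ux = p@barStaggerMm * k, uy = p@barPitchMm * k)
  halfL <- p@barLengthMm / 2
  halfW <- p@nominalMm * p@rampFactor / 2
  fnd <- NULL
  if (p@foundation) {
    leftEnd <- min(bars[, "ux"]) - halfL
    fx1 <- leftEnd - 1.3                       # gap so bars stay separate
    fnd <- list(x = c(fx1 - 16, fx1),
                y = max(abs(bars[, "uy"])) + 8)
  }
  rmax <- max(sqrt((abs(bars[, "ux"]) + halfL)^2 +
                   (abs(bars[, "uy"]) + halfW)^2),
              if (!is.null(fnd)) sqrt(max(abs(fnd$x))^2 + fnd$y^2) else 0)
  list(bars = bars, halfL = halfL, halfW = halfW, foundation = fnd,
       rmax = rmax)
}

#' Generate a synthetic phantom image
#'
#' Renders the phantom analytically: a water disc (0 HU) in air (-1000 HU)
#' containing the stair bars (partial-volume coverage computed on a 4 x 4
#' sub-pixel grid), rotates and shifts the assembly, convolves with the
#' Gaussian PSF and adds i.i.d. Gaussian noise. The returned image carries a
#' ground-truth list (`trueFwhmMm`, `trueAngleDeg`, `barCentersPx`,
#' `nominalMm`) for closed-loop validation. Identical parameters and seed
#' produce an identical image; the caller's RNG state is untouched.
#'
#' @param p a [SynthParams-class] from [synthParams()].
#' @return a [PhantomImage-class] with ground truth attached.
#' @examples
#' img <- generatePhantom(synthParams(nominalMm = 3, seed = 7L))
#' groundTruth(img)$trueFwhmMm
#' @export
generatePhantom <- function(p) {
  stopifnot(is(p, "SynthParams"))
  validObject(p)
  geo <- assemblyGeometry(p)
  off <- sqrt(sum(p@offsetMm^2))
  if (geo$rmax + off > p@waterRadiusMm)
    stop(sprintf("stair assembly (radius %.1f mm) plus offset (%.1f mm) exceeds the water disc (radius %.1f mm)",
                 geo$rmax, off, p@waterRadiusMm), call. = FALSE)

  n <- p@matrixSize
  sp <- p@spacingMm
  ctr <- (n + 1) / 2
  dy <- p@offsetMm[1]; dx <- p@offsetMm[2]
  # mm coordinates of pixel centers relative to the (offset) phantom center
  xmm <- (seq_len(n) - ctr) * sp - dx
  ymm <- (seq_len(n) - ctr) * sp - dy

  img <- matrix(-1000, n, n)
  disc <- outer(ymm^2, xmm^2, "+") <= p@waterRadiusMm^2
  img[disc] <- 0

  # sub-pixel coverage of the stair assembly within its bounding region
  marginPx <- 4L
  halfSpanPx <- ceiling(geo$rmax / sp) + marginPx
  rows <- max(1L, floor(ctr + dy / sp) - halfSpanPx):
          min(n, ceiling(ctr + dy / sp) + halfSpanPx)
  cols <- max(1L, floor(ctr + dx / sp) - halfSpanPx):
          min(n, ceiling(ctr + dx / sp) + halfSpanPx)
  ss <- 4L
  subOff <- ((seq_len(ss) - (ss + 1) / 2) / ss) * sp
  ysub <- rep(ymm[rows], each = ss) + subOff
  xsub <- rep(xmm[cols], each = ss) + subOff
  a <- p@rotationDeg * pi / 180
  ca <- cos(a); sa <- sin(a)
  X <- matrix(xsub, nrow = length(ysub), ncol = length(xsub), byrow = TRUE)
  Y <- matrix(ysub, nrow = length(ysub), ncol = length(xsub))
  U <-  ca * X + sa * Y   # assembly-frame coordinates (inverse rotation)
  V <- -sa * X + ca * Y
  # exact partial-volume coverage of each sub-sample box (side h); the box is
  # treated as axis-aligned in the assembly frame, exact at rotation 0 and a
  # negligible approximation at the small rotations of interest
  h <- sp / ss
  boxOverlap <- function(center, lo, hi)
    pmax(0, pmin(center + h / 2, hi) - pmax(center - h / 2, lo)) / h
  cov <- matrix(0, nrow(U), ncol(U))
  for (i in seq_len(p@nBars)) {
    cov <- cov +
      boxOverlap(U, geo$bars[i, "ux"] - geo$halfL,
                    geo$bars[i, "ux"] + geo$halfL) *
      boxOverlap(V, geo$bars[i, "uy"] - geo$halfW,
                    geo$bars[i, "uy"] + geo$halfW)
  }
  if (!is.null(geo$foundation)) {
    cov <- cov +
      boxOverlap(U, geo$foundation$x[1], geo$foundation$x[2]) *
      boxOverlap(V, -geo$foundation$y, geo$foundation$y)
  }
  cov <- pmin(cov, 1)
  ri <- seq(1L, nrow(cov), by = ss)
  cov <- (cov[ri, ] + cov[ri + 1L, ] + cov[ri + 2L, ] + cov[ri + 3L, ]) / ss
  ci <- seq(1L, ncol(cov), by = ss)
  cov <- (cov[, ci] + cov[, ci + 1L] + cov[, ci + 2L] + cov[, ci + 3L]) / ss
  img[rows, cols] <- img[rows, cols] + p@barContrastHu * cov

  img <- gaussBlur(img, p@psfSigmaPx)

  if (p@noiseSigmaHu > 0) {
    state <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(state))
      assign(".Random.seed", state, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv()))
    set.seed(p@seed)
    img <- img + matrix(stats::rnorm(n * n, 0, p@noiseSigmaHu), n, n)
  }

  # bar centers back in image pixel coordinates
  bx <- ca * geo$bars[, "ux"] - sa * geo$bars[, "uy"]
  by <- sa * geo$bars[, "ux"] + ca * geo$bars[, "uy"]
  centers <- cbind(row = ctr + (by + dy) / sp, col = ctr + (bx + dx) / sp)

  PhantomImage(img, spacing = sp,
               sourceId = sprintf("synthetic:%d", p@seed),
               truth = list(trueFwhmMm = groundTruthFwhm(p),
                            trueAngleDeg = p@rotationDeg,
                            barCentersPx = centers,
                            nominalMm = p@nominalMm))
}

#' Analytic ground-truth FWHM of the synthetic bar profile
#'
#' FWHM of a rectangle of width `nominalMm * rampFactor` convolved with the
#' generator's Gaussian PSF (`psfSigmaPx * spacingMm`), computed by dense 1-D
#' numeric convolution (step at most `nominalMm / 1000`) followed by linear
#' half-maximum crossing — the same definition the measurement applies to the
#' image. Equals the nominal width exactly when `psfSigmaPx = 0`, and tends
#' to the Gaussian FWHM `2 * sqrt(2 * log(2)) * sigma` as the width shrinks.
#'
#' @param p a [SynthParams-class].
#' @return ground-truth FWHM in mm.
#' @export
groundTruthFwhm <- function(p) {
  stopifnot(is(p, "SynthParams"))
  w <- p@nominalMm * p@rampFactor
  sigma <- p@psfSigmaPx * p@spacingMm
  if (sigma == 0) return(w)
  step <- min(w, sigma) / 1000
  halfRange <- w / 2 + 6 * sigma
  x <- seq(-halfRange, halfRange, by = step)
  rect <- as.numeric(abs(x) <= w / 2)
  xk <- seq(-6 * sigma, 6 * sigma, by = step)
  kern <- stats::dnorm(xk, 0, sigma)
  prof <- stats::convolve(rect, rev(kern), type = "open") * step
  half <- max(prof) / 2
  ip <- which.max(prof)
  below <- which(prof < half)
  li <- max(below[below < ip]); ri <- min(below[below > ip])
  left  <- li + (half - prof[li]) / (prof[li + 1L] - prof[li])
  right <- ri - (half - prof[ri]) / (prof[ri - 1L] - prof[ri])
  (right - left) * step
}
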