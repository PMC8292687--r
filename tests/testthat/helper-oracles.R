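# Independent oracles and small fixtures shared across tests.

# brute-force FWHM: upsample the profile 1000x by linear interpolation and
# count samples at or above the half level
bruteForceFwhm <- function(values, halfLevel, factor = 1000) {
  xs <- seq(1, length(values), by = 1 / factor)
  up <- stats::approx(seq_along(values), values, xs)$y
  sum(up >= halfLevel) / factor
}

# random unimodal profile (two-sided Gaussian with independent flank widths)
randomUnimodalProfile <- function(n = 41) {
  ctr <- runif(1, 15, n - 14)
  sl <- runif(1, 1.5, 5); sr <- runif(1, 1.5, 5)
  amp <- runif(1, 100, 800)
  x <- seq_len(n)
  amp * exp(-0.5 * ifelse(x < ctr, ((x - ctr) / sl)^2, ((x - ctr) / sr)^2))
}

asProfile <- function(values, baseline = 0) {
  peak <- max(values)
  new("IntensityProfile", values = values, baseline = baseline,
      peak = peak, halfLevel = baseline + (peak - baseline) / 2)
}

# closed-form profile of rect(w) convolved with Gaussian(sigma); the
# analytic counterpart of the generator's dense numeric oracle
rectGaussFwhm <- function(w, sigma) {
  prof <- function(x) pnorm((x + w / 2) / sigma) - pnorm((x - w / 2) / sigma)
  half <- prof(0) / 2
  2 * uniroot(function(x) prof(x) - half, c(0, w / 2 + 8 * sigma),
              tol = 1e-10)$root
}

# compact phantom for unit tests (same spacing and stair geometry as the
# defaults, smaller matrix so the water disc still covers the assembly)
smallPhantom <- function(...) {
  synthParams(matrixSize = 256L, ...)
}
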