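test_that("generation is deterministic in the seed and leaves the RNG alone", {
  p <- smallPhantom(seed = 7L)
  set.seed(123)
  before <- .Random.seed
  img1 <- generatePhantom(p)
  expect_identical(.Random.seed, before)
  img2 <- generatePhantom(p)
  expect_identical(pixelData(img1), pixelData(img2))
  img3 <- generatePhantom(smallPhantom(seed = 8L))
  expect_false(identical(pixelData(img1), pixelData(img3)))
})

test_that("without blur and noise the bar cross-section is a clean rectangle", {
  p <- smallPhantom(nominalMm = 5, psfSigmaPx = 0, noiseSigmaHu = 0, seed = 1L)
  img <- generatePhantom(p)
  ctr <- groundTruth(img)$barCentersPx[2, ]
  # cut across the middle bar only (the staggered neighbors overlap this
  # column further up and down the image)
  rows <- round(ctr[1]) + (-11:11)
  column <- pixelData(img)[rows, round(ctr[2])]
  # full-contrast core rows and a hard drop to water outside the bar
  core <- sum(column > p@barContrastHu - 1e-6)
  expect_gte(core, floor(p@nominalMm / p@spacingMm) - 1)
  expect_lte(sum(column > 0.5), ceiling(p@nominalMm / p@spacingMm) + 1)
})

test_that("the blurred bar's half-contrast width matches the nominal width", {
  p <- synthParams(nominalMm = 5, noiseSigmaHu = 0, seed = 7L)
  img <- generatePhantom(p)
  ctr <- groundTruth(img)$barCentersPx[2, ]
  rows <- round(ctr[1]) + (-11:11)
  column <- pixelData(img)[rows, round(ctr[2])]
  widthPx <- bruteForceFwhm(column, p@barContrastHu / 2)
  expect_equal(widthPx, p@nominalMm / p@spacingMm, tolerance = 0.05)
})

test_that("offsets shift the recorded bar centers by offset / spacing", {
  p0 <- synthParams(seed = 1L)
  pOff <- synthParams(offsetMm = c(-40, 0), seed = 1L)
  c0 <- groundTruth(generatePhantom(p0))$barCentersPx
  cOff <- groundTruth(generatePhantom(pOff))$barCentersPx
  expect_equal(cOff[, "row"] - c0[, "row"],
               rep(-40 / p0@spacingMm, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(cOff[, "col"], c0[, "col"], ignore_attr = TRUE)
})

test_that("assemblies that would leave the water disc are rejected", {
  expect_error(generatePhantom(synthParams(offsetMm = c(80, 0))),
               "exceeds the water disc")
  expect_error(generatePhantom(smallPhantom(barLengthMm = 200)),
               "exceeds the water disc")
})

test_that("ground-truth FWHM has the right limits", {
  # delta PSF: exactly the nominal width
  expect_identical(groundTruthFwhm(synthParams(nominalMm = 3.2,
                                               psfSigmaPx = 0)), 3.2)
  # vanishing bar: the Gaussian FWHM 2 sqrt(2 ln 2) sigma
  p <- synthParams(nominalMm = 0.01, psfSigmaPx = 2)
  expect_equal(groundTruthFwhm(p),
               2 * sqrt(2 * log(2)) * 2 * p@spacingMm, tolerance = 1e-3)
})

test_that("ground-truth FWHM matches the analytic erf-profile solution", {
  for (nm in c(0.7, 1, 2.5, 5)) {
    p <- synthParams(nominalMm = nm)
    expect_equal(groundTruthFwhm(p),
                 rectGaussFwhm(nm, p@psfSigmaPx * p@spacingMm),
                 tolerance = 1e-3)
  }
  # frozen regression value for the default 5 mm configuration
  expect_equal(groundTruthFwhm(synthParams(nominalMm = 5)), 5.000226562,
               tolerance = 1e-7)
})

test_that("ground-truth FWHM is monotone in width and blur", {
  byNominal <- vapply(c(0.5, 1, 2, 3, 4, 5), function(nm)
    groundTruthFwhm(synthParams(nominalMm = nm)), numeric(1))
  expect_true(all(diff(byNominal) >= 0))
  byPsf <- vapply(c(0, 0.3, 0.6, 0.9, 1.5), function(s)
    groundTruthFwhm(synthParams(nominalMm = 1, psfSigmaPx = s)), numeric(1))
  expect_true(all(diff(byPsf) >= 0))
})

test_that("filter presets order blur and noise as smooth < standard < sharp", {
  s <- filterPreset("smooth"); m <- filterPreset("standard")
  h <- filterPreset("sharp")
  expect_true(s$psfSigmaPx > m$psfSigmaPx && m$psfSigmaPx > h$psfSigmaPx)
  expect_true(s$noiseSigmaHu < m$noiseSigmaHu && m$noiseSigmaHu < h$noiseSigmaHu)
})
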