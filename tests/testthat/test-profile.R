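test_that("recropWindow cuts the requested window", {
  img <- PhantomImage(matrix(rnorm(65 * 65), 65, 65), spacing = 0.5)
  win <- recropWindow(img, c(33, 33), 30L)
  expect_identical(dim(pixelData(win)), c(30L, 30L))
  tiny <- recropWindow(img, c(33, 33), 1L)
  expect_identical(dim(pixelData(tiny)), c(1L, 1L))
  expect_error(recropWindow(img, c(33, 33), 0L), "degenerate")
})

test_that("the 30x30 window excludes foundation and neighbor bars", {
  for (a in c(0, 10)) {
    img <- generatePhantom(synthParams(rotationDeg = a, noiseSigmaHu = 0,
                                       seed = 2L))
    mid <- selectMiddleObject(segmentStairs(img))
    crop <- cropAbout(img, mid@centroid, 32L)
    up <- rotateToUpright(crop, houghAngle(crop))
    win <- recropWindow(up, (dim(pixelData(up)) + 1) / 2, 30L)
    px <- pixelData(win)
    # only the middle bar's band is bright; border rows/cols stay at water
    expect_lt(max(px[c(1:3, 28:30), ]), 200)
    expect_gt(max(px), 700)
  }
})

test_that("averaging a rank-1 window returns the row profile exactly", {
  rowProfile <- c(0, 0, 5, 80, 400, 800, 400, 80, 5, 0, 0)
  win <- PhantomImage(outer(rowProfile, rep(1, 30)), spacing = 0.5)
  prof <- meanProfile(win, axis = "rows", noiseFloorHu = 10)
  expect_equal(profileValues(prof), rowProfile)
  expect_equal(prof@peak, 800)
  expect_equal(prof@halfLevel, prof@baseline + (800 - prof@baseline) / 2)
})

test_that("column averaging suppresses noise as sigma over sqrt(n)", {
  set.seed(314)
  sems <- replicate(300, {
    win <- matrix(rnorm(30 * 30, 0, 10), 30, 30)
    rowMeans(win)
  })
  expect_equal(sd(as.vector(sems)), 10 / sqrt(30), tolerance = 0.05)
})

test_that("windows without contrast are rejected", {
  win <- PhantomImage(matrix(0, 30, 30), spacing = 0.5)
  expect_error(meanProfile(win), "no bar in window")
  expect_error(meanProfile(PhantomImage(matrix(0, 2, 30), spacing = 0.5),
                           axis = "rows"), "too small")
})

test_that("raw half mode measures at literal peak / 2", {
  rowProfile <- c(rep(100, 5), rep(900, 5), rep(100, 5))
  win <- PhantomImage(outer(rowProfile, rep(1, 10)), spacing = 0.5)
  expect_equal(meanProfile(win, axis = "rows")@halfLevel, 500)
  expect_equal(meanProfile(win, axis = "rows", halfMode = "raw")@halfLevel, 450)
})

test_that("fwhm matches hand-computed crossings", {
  expect_equal(fwhm(asProfile(c(0, 0, 10, 10, 10, 0, 0))), 3)
  expect_equal(fwhm(asProfile(c(0, 1, 0))), 1)
})

test_that("fwhm of a densely sampled Gaussian matches the closed form", {
  sigma <- 2
  step <- 0.1
  v <- exp(-(seq(-20, 20, by = step))^2 / (2 * sigma^2))
  expect_equal(fwhm(asProfile(v)) * step, 2 * sqrt(2 * log(2)) * sigma,
               tolerance = 0.02 / 4.71)
})

test_that("with multiple crossings the pair nearest the peak wins", {
  v <- c(0, 8, 0, 0, 10, 10, 0, 8, 0)
  p <- new("IntensityProfile", values = v, baseline = 0, peak = 10,
           halfLevel = 5)
  # side bumps at indices 2 and 8 also cross 5; the crossings adjacent to
  # the plateau at 5:6 (4.5 and 6.5) are the ones used
  expect_equal(fwhm(p), 2)
})

test_that("a peak at the window edge is reported as such", {
  p <- new("IntensityProfile", values = c(0, 2, 5, 9, 10), baseline = 0,
           peak = 10, halfLevel = 5)
  expect_error(fwhm(p), "larger window")
})

test_that("interpolated fwhm agrees with the brute-force oracle", {
  set.seed(77)
  for (i in 1:25) {
    v <- randomUnimodalProfile()
    p <- asProfile(v)
    expect_lt(abs(fwhm(p) - bruteForceFwhm(v, p@halfLevel)), 0.02)
  }
})

test_that("the end-to-end measurement recovers the ground truth", {
  img <- generatePhantom(synthParams(nominalMm = 5, psfSigmaPx = 0.6,
                                     noiseSigmaHu = 0, seed = 1L))
  res <- measureSliceThickness(img)
  expect_lt(abs(fwhmMm(res) - groundTruth(img)$trueFwhmMm), 0.1)
  expect_equal(fwhmMm(res), fwhmPx(res) * pixelSpacing(img)[1])
  # deterministic given image and config
  expect_identical(fwhmMm(measureSliceThickness(img)), fwhmMm(res))
})

test_that("a 4 cm shift changes the measurement by less than 0.2 mm", {
  at0 <- fwhmMm(measureSliceThickness(
    generatePhantom(synthParams(seed = 21L))))
  at4 <- fwhmMm(measureSliceThickness(
    generatePhantom(synthParams(offsetMm = c(40, 0), seed = 21L))))
  expect_lt(abs(at4 - at0), 0.2)
})

test_that("stage errors carry the failing stage's name", {
  water <- PhantomImage(matrix(0, 256, 256), spacing = 0.5078)
  expect_error(measureSliceThickness(water),
               "\\[segmentation\\].*no stair objects found")
})

test_that("measured thickness is strictly increasing in nominal thickness", {
  mm <- vapply(1:5, function(nm) {
    fwhmMm(measureSliceThickness(
      generatePhantom(smallPhantom(nominalMm = nm, seed = 13L))))
  }, numeric(1))
  expect_true(all(diff(mm) > 0))
})

test_that("halving the pixel spacing leaves the mm result within 2%", {
  # the same physical phantom sampled twice as finely: PSF fixed in mm
  coarse <- synthParams(nominalMm = 4, seed = 17L)
  fine <- synthParams(nominalMm = 4, matrixSize = 512L,
                      spacingMm = coarse@spacingMm / 2, psfSigmaPx = 1.2,
                      waterRadiusMm = 60, seed = 17L)
  vCoarse <- fwhmMm(measureSliceThickness(generatePhantom(coarse)))
  vFine <- fwhmMm(measureSliceThickness(generatePhantom(fine)))
  expect_lt(abs(vFine - vCoarse) / vCoarse, 0.02)
})
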