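test_that("segmentation finds exactly the three stair bars", {
  img <- generatePhantom(synthParams(seed = 42L))
  regions <- segmentStairs(img)
  expect_length(regions, 3L)
  # sorted by centroid column ascending
  cols <- vapply(regions, function(r) r@centroid[2], numeric(1))
  expect_identical(cols, sort(cols))
  # masks are pairwise disjoint
  total <- Reduce(`+`, lapply(regions, function(r) r@mask * 1))
  expect_lte(max(total), 1)
  # centroids match the generator's bar centers
  truth <- groundTruth(img)$barCentersPx
  cen <- t(vapply(regions, function(r) r@centroid, numeric(2)))
  expect_lt(max(abs(cen - truth)), 2)
})

test_that("rotation preserves bar count and areas", {
  img0 <- generatePhantom(synthParams(seed = 5L))
  img10 <- generatePhantom(synthParams(rotationDeg = 10, seed = 5L))
  r0 <- segmentStairs(img0)
  r10 <- segmentStairs(img10)
  expect_length(r10, 3L)
  a0 <- sort(vapply(r0, function(r) r@areaPx, integer(1)))
  a10 <- sort(vapply(r10, function(r) r@areaPx, integer(1)))
  expect_lt(max(abs(a10 - a0) / a0), 0.10)
})

test_that("images without bars yield a 'no stair objects found' error", {
  water <- PhantomImage(matrix(0, 128, 128), spacing = 0.5)
  expect_error(segmentStairs(water), "no stair objects found")
})

test_that("raising the threshold never grows a region", {
  img <- generatePhantom(smallPhantom(seed = 8L))
  thresholds <- c(150, 300, 450, 600)
  regionSets <- lapply(thresholds, function(t) segmentStairs(img, t))
  for (i in seq_along(thresholds)[-1]) {
    expect_length(regionSets[[i]], 3L)
    prev <- regionSets[[i - 1L]]
    cur <- regionSets[[i]]
    for (k in 1:3) {
      # match bars by centroid proximity, then compare areas
      d <- vapply(prev, function(r) sum((r@centroid - cur[[k]]@centroid)^2),
                  numeric(1))
      expect_lte(cur[[k]]@areaPx, prev[[which.min(d)]]@areaPx)
    }
  }
})

test_that("bar count and middle-bar identity survive +/-4 cm offsets", {
  for (off in list(c(0, 0), c(-40, 0), c(40, 0), c(0, -40), c(0, 40))) {
    img <- generatePhantom(synthParams(offsetMm = off, seed = 3L))
    regions <- segmentStairs(img)
    expect_length(regions, 3L)
    mid <- selectMiddleObject(regions)
    expect_lt(max(abs(mid@centroid - groundTruth(img)$barCentersPx[2, ])), 2)
  }
})

test_that("the middle object is the second along the stair axis", {
  mkRegion <- function(row, col) {
    mask <- matrix(FALSE, 300, 500)
    mask[row + (-1:1), col + (-5:5)] <- TRUE
    ctsliceQC:::regionFromMask(mask, 1L)
  }
  regions <- list(mkRegion(100, 100), mkRegion(150, 250), mkRegion(200, 400))
  expect_equal(selectMiddleObject(regions)@centroid[2], 250)
  expect_error(selectMiddleObject(regions[1:2]), "found 2")
})

test_that("the same physical bar is selected with and without rotation", {
  img0 <- generatePhantom(synthParams(seed = 4L))
  img10 <- generatePhantom(synthParams(rotationDeg = 10, seed = 4L))
  mid0 <- selectMiddleObject(segmentStairs(img0))
  mid10 <- selectMiddleObject(segmentStairs(img10))
  expect_lt(max(abs(mid0@centroid - groundTruth(img0)$barCentersPx[2, ])), 2)
  expect_lt(max(abs(mid10@centroid - groundTruth(img10)$barCentersPx[2, ])), 2)
})

test_that("cropAbout windows, clips and inherits spacing", {
  img <- PhantomImage(matrix(rnorm(512 * 512), 512, 512), spacing = 0.5078)
  crop <- cropAbout(img, c(256, 256), 32L)
  expect_identical(dim(pixelData(crop)), c(65L, 65L))
  expect_identical(pixelSpacing(crop), pixelSpacing(img))

  corner <- cropAbout(img, c(1, 1), 32L)
  expect_identical(dim(pixelData(corner)), c(33L, 33L))

  expect_error(cropAbout(img, c(-5, 600), 32L), "outside")
})

test_that("the crop contains essentially all of the middle bar", {
  img <- generatePhantom(synthParams(rotationDeg = 5, seed = 6L))
  mid <- selectMiddleObject(segmentStairs(img))
  idx <- which(mid@mask, arr.ind = TRUE)
  ctr <- round(mid@centroid)
  insideWindow <- abs(idx[, 1] - ctr[1]) <= 32 & abs(idx[, 2] - ctr[2]) <= 32
  expect_gte(mean(insideWindow), 0.95)
})
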