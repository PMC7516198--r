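test_that("monolayer generation honours count, bounds and separation", {
  expect_equal(nCells(generateMonolayer(monolayerSpec(128, 128, 0))), 0L)

  s <- monolayerSpec(512, 512, nCells = 500, minSeparation = 8, jitter = 3,
                     seed = 7)
  a <- generateMonolayer(s)
  b <- generateMonolayer(s)
  expect_identical(coords(a), coords(b))
  expect_equal(nCells(a), 500L)
  m <- coords(a)
  expect_true(all(m[, 1] >= 0 & m[, 1] <= 511 & m[, 2] >= 0 & m[, 2] <= 511))
  # exhaustive O(n^2) pairwise-distance check
  expect_gte(min(dist(m)), 8)
})

test_that("impossible densities raise a capacity error", {
  expect_error(generateMonolayer(monolayerSpec(64, 64, nCells = 500,
                                               minSeparation = 8)),
               "capacity")
})

test_that("wound carving empties the gap band and closes at t24", {
  pts <- generateMonolayer(monolayerSpec(512, 512, 2000, 8, 3, seed = 2))
  w <- woundSpec("vertical", gapCentre = 256, gapWidthT0 = 100,
                 gapWidthT24 = 0)
  t0 <- applyWound(pts, w, "t0")
  expect_true(all(abs(coords(t0)[, 1] - 256) >= 50))
  t24 <- applyWound(pts, w, "t24")
  expect_gt(sum(abs(coords(t24)[, 1] - 256) < 50), 0)
  expect_error(woundSpec("vertical", 256, gapWidthT0 = 50, gapWidthT24 = 80),
               "close")
})

test_that("gradient strength zero leaves per-stratum counts uniform", {
  pts <- generateMonolayer(monolayerSpec(1024, 1024, 5000, 8, 3, seed = 4))
  w <- woundSpec("vertical", gapCentre = 512, gapWidthT0 = 100,
                 gapWidthT24 = 100, gradientStrength = 0)
  m <- coords(applyWound(pts, w, "t24", seed = 2))
  right <- m[m[, 1] > 562, 1]
  counts <- table(cut(right, breaks = seq(562, 1023, length.out = 11)))
  expect_gt(stats::chisq.test(as.numeric(counts))$p.value, 0.01)
})

test_that("positive gradient makes nearest-neighbour spacing rise towards the gap", {
  pts <- generateMonolayer(monolayerSpec(1392, 512, 3000, 8, 3, seed = 11))
  w <- woundSpec("vertical", gapCentre = 696, gapWidthT0 = 120,
                 gapWidthT24 = 40, gradientStrength = 0.8)
  p <- applyWound(pts, w, "t24", seed = 5)
  m <- coords(p)
  dgap <- abs(m[, 1] - 696)
  nn <- 1 / localCellDensity(p, 1)
  strata <- cut(dgap, breaks = stats::quantile(dgap, 0:4 / 4),
                include.lowest = TRUE)
  spacing <- tapply(nn, strata, mean)
  expect_true(all(diff(spacing) < 0))
})

test_that("nuclear rendering places a maximum at every centre", {
  rsQuiet <- renderSpec("nuclei", nucleusSigma = 2, bitDepth = 12,
                        backgroundLevel = 0, noiseSd = 0)
  empty <- renderImage(cellCoords(width = 64, height = 64), rsQuiet)
  expect_true(all(gridData(empty) == 0))

  one <- renderImage(cellCoords(48, 48, width = 96, height = 96), rsQuiet)
  am <- arrayInd(which.max(gridData(one)), c(96, 96))
  expect_equal(c(am[1, 2] - 1, am[1, 1] - 1), c(48, 48))

  pts <- generateMonolayer(monolayerSpec(256, 256, 50, minSeparation = 10,
                                         jitter = 2, seed = 9))
  img <- gridData(renderImage(pts, rsQuiet))
  found <- oracleLocalMaxima(img, 0.05)
  r <- matchDetections(found, pts, maxDist = 1)
  expect_equal(r@fn, 0L)
})

test_that("membrane rendering is brightest along Voronoi ridges", {
  pts <- generateMonolayer(monolayerSpec(128, 128, 40, 10, 2, seed = 3))
  img <- gridData(renderImage(pts, renderSpec("membrane", bitDepth = 8,
                                              backgroundLevel = 0,
                                              noiseSd = 0)))
  m <- coords(pts)
  atCentres <- img[cbind(round(m[, 2]) + 1, round(m[, 1]) + 1)]
  # cell interiors are dark, somewhere on the ridge network is bright
  expect_lt(stats::median(atCentres), 0.2 * max(img))
  expect_gt(max(img), 0)
})

test_that("rendered intensities respect the bit depth", {
  pts <- generateMonolayer(monolayerSpec(64, 64, 20, 8, 2, seed = 5))
  img <- renderImage(pts, renderSpec("both", bitDepth = 8,
                                     backgroundLevel = 0.3, noiseSd = 0.3),
                     seed = 1)
  expect_true(all(gridData(img) >= 0 & gridData(img) <= 255))
  expect_s4_class(img, "ImageGrid")
})

test_that("noise-free rendering round-trips through local-maxima extraction", {
  # minSeparation 8 = 4 * nucleusSigma
  pts <- generateMonolayer(monolayerSpec(256, 256, 300, minSeparation = 8,
                                         jitter = 3, seed = 21))
  img <- renderImage(pts, renderSpec("nuclei", nucleusSigma = 2,
                                     bitDepth = 12, backgroundLevel = 0,
                                     noiseSd = 0))
  det <- extractLocalMaxima(gridData(img), threshold = 0.1)
  r <- matchDetections(det, pts, maxDist = 2)
  expect_gte(r@tp / nCells(pts), 0.99)
})
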