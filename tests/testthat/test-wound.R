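test_that("density mask equals the Chebyshev coverage oracle", {
  expect_false(any(densityMask(matrix(numeric(0), ncol = 2), 32, 32)))

  one <- densityMask(cbind(20, 20), 48, 48, kernel = 13)
  want <- matrix(FALSE, 48, 48)
  want[15:27, 15:27] <- TRUE
  expect_identical(one, want)

  corner <- densityMask(cbind(0, 0), 32, 32, kernel = 13)
  expect_equal(sum(corner), 49)  # 7x7 clipped at the border

  set.seed(13)
  pts <- cbind(runif(200, 0, 79), runif(200, 0, 63))
  expect_identical(densityMask(pts, 64, 80, 13),
                   oracleCoverage(pts, 64, 80, 6))
})

test_that("a confluent monolayer has no wound", {
  g <- expand.grid(x = seq(0, 120, by = 6), y = seq(0, 120, by = 6))
  w <- segmentWound(densityMask(cbind(g$x, g$y), 121, 121))
  expect_equal(woundArea(w), 0)
  expect_true(anyNA(woundCentre(w)))
  expect_error(distanceToWoundCentre(cbind(1, 1), w), "t0")
})

test_that("a vertical empty band is recovered with its geometry", {
  g <- expand.grid(x = seq(0, 399, by = 6), y = seq(0, 511, by = 6))
  keep <- abs(g$x - 200) >= 50
  w <- segmentWound(densityMask(cbind(g$x[keep], g$y[keep]), 512, 400))
  expect_gt(woundArea(w), 0)
  expect_lt(abs(woundArea(w) - 100 * 512) / (100 * 512), 0.15)
  expect_equal(woundCentre(w)[1], 200, tolerance = 4)
})

test_that("of two empty regions the larger is the wound", {
  g <- expand.grid(x = seq(0, 599, by = 6), y = seq(0, 299, by = 6))
  keep <- !(g$x > 100 & g$x < 220) & !(g$x > 400 & g$x < 480)
  w <- segmentWound(densityMask(cbind(g$x[keep], g$y[keep]), 300, 600))
  expect_gt(woundCentre(w)[1], 100)
  expect_lt(woundCentre(w)[1], 220)
})

test_that("adding cells never increases the wound area", {
  set.seed(19)
  base <- generateMonolayer(monolayerSpec(300, 300, 800, 8, 3, seed = 3))
  pts <- coords(applyWound(base, woundSpec("vertical", 150, 80), "t0"))
  a0 <- woundArea(segmentWound(densityMask(pts, 300, 300)))
  for (i in 1:5) {
    extra <- cbind(runif(10, 0, 299), runif(10, 0, 299))
    a1 <- woundArea(segmentWound(densityMask(rbind(pts, extra), 300, 300)))
    expect_lte(a1, a0)
    pts <- rbind(pts, extra)
    a0 <- a1
  }
})

test_that("wound segmentation is idempotent", {
  base <- generateMonolayer(monolayerSpec(300, 300, 800, 8, 3, seed = 6))
  pts <- coords(applyWound(base, woundSpec("vertical", 150, 80), "t0"))
  w1 <- segmentWound(densityMask(pts, 300, 300))
  # feed the segmented wound back as the empty space of a coverage mask
  w2 <- segmentWound(!woundMask(w1))
  expect_identical(woundMask(w2), woundMask(w1))
})

test_that("synthetic wounds of known width are recovered within 15%", {
  for (gap in c(60, 100, 150)) {
    base <- generateMonolayer(monolayerSpec(512, 512, 1100, 8, 3, seed = 31))
    pts <- applyWound(base, woundSpec("vertical", 256, gap), "t0")
    w <- segmentWound(densityMask(pts, 512, 512))
    expect_lt(abs(woundArea(w) - gap * 512) / (gap * 512), 0.15)
  }
})

test_that("wound-centre distances and fold change follow closed forms", {
  expect_equal(distanceToWoundCentre(cbind(0, 0), c(0, 0)), 0)
  expect_equal(distanceToWoundCentre(cbind(3, 4), c(0, 0)), 5)
  set.seed(2)
  pts <- cbind(runif(20, 0, 99), runif(20, 0, 99))
  v <- c(13.5, -7.25)
  expect_equal(distanceToWoundCentre(pts, c(40, 60)),
               distanceToWoundCentre(sweep(pts, 2, v, "+"), c(40, 60) + v))

  expect_equal(woundFoldChange(1000, 0), 0)
  expect_equal(woundFoldChange(1000, 1000), 1)
  expect_equal(woundFoldChange(2000, 500), 0.25)
  expect_error(woundFoldChange(0, 10), "baseline")
})
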