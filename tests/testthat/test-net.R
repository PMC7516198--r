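test_that("image normalisation maps the bit-depth maximum to 1", {
  expect_equal(normaliseImage(matrix(4095, 1, 1), 12)[1, 1], 1)
  expect_equal(normaliseImage(matrix(0, 1, 1), 12)[1, 1], 0)
  expect_equal(normaliseImage(matrix(255, 1, 1), 8)[1, 1], 1)
  expect_error(normaliseImage(matrix(256, 1, 1), 8), "exceed")
  g <- imageGrid(matrix(2047.5, 2, 2), 12)
  expect_equal(normaliseImage(g)[1, 1], 0.5)
})

test_that("belief maps peak at annotations and sum kernels", {
  expect_true(all(renderBeliefMap(cellCoords(), 32, 32) == 0))

  bm <- renderBeliefMap(cbind(10, 10), 32, 32, sigma = 2.5)
  am <- arrayInd(which.max(bm), dim(bm))
  expect_equal(c(am[1, 2] - 1, am[1, 1] - 1), c(10, 10))
  expect_equal(max(bm), 1)

  two <- renderBeliefMap(rbind(c(10, 16), c(26, 16)), 48, 48, sigma = 2.5)
  expect_equal(nrow(oracleLocalMaxima(two, 0.05)), 2)

  # kernel mass is position independent away from borders
  m1 <- sum(renderBeliefMap(cbind(20, 20), 64, 64, 2.5))
  m2 <- sum(renderBeliefMap(cbind(35, 29), 64, 64, 2.5))
  expect_equal(m1, m2, tolerance = 1e-6)
})

test_that("the network maps any valid input to a same-shaped belief map", {
  net <- buildModel(netSpec(depth = 4, channels = 6), seed = 1)
  out <- predictBeliefMap(net, matrix(0.5, 96, 96))
  expect_equal(dim(out), c(96, 96))
  out2 <- predictBeliefMap(net, matrix(0.5, 64, 112))
  expect_equal(dim(out2), c(64, 112))
  # encoder halves resolution four times: 96 -> 6 at the bottleneck
  fw <- scratchTopo:::unetForward(net@params, net@spec, matrix(0, 96, 96),
                                  keepCache = TRUE)
  expect_equal(c(fw$caches$bot_conv1$H, fw$caches$bot_conv1$W), c(6, 6))
  # all-zero input stays finite
  expect_true(all(is.finite(predictBeliefMap(net, matrix(0, 32, 32)))))
  expect_error(predictBeliefMap(net, matrix(0, 100, 100)), "divisible")
})

test_that("analytic gradients match finite differences", {
  spec <- netSpec(depth = 1, channels = 2, initialKernel = 3)
  net <- buildModel(spec, seed = 3)
  set.seed(5)
  x <- matrix(runif(64), 8, 8)
  tgt <- matrix(runif(64), 8, 8)
  fw <- scratchTopo:::unetForward(net@params, spec, x, keepCache = TRUE)
  gr <- scratchTopo:::unetBackward(net@params, spec, fw,
                                   2 * (fw$out - tgt) / 64)
  lossAt <- function(p)
    mean((scratchTopo:::unetForward(p, spec, x)$out - tgt)^2)
  for (nm in names(gr)) for (rep in 1:2) {
    i <- sample(length(net@params[[nm]]$W), 1)
    p2 <- net@params
    p2[[nm]]$W[i] <- p2[[nm]]$W[i] + 1e-6
    num <- (lossAt(p2) - lossAt(net@params)) / 1e-6
    expect_equal(gr[[nm]]$gW[i], num, tolerance = 1e-3)
  }
})

test_that("crop sampling follows the cell-centred branch probability", {
  img <- matrix(0.5, 48, 48)
  onecell <- cbind(30, 12)

  set.seed(1)
  cfg1 <- trainConfig(cropSize = 16, cellCentredProb = 1)
  for (i in 1:20) {
    cr <- sampleCrop(img, onecell, cfg1)
    expect_equal(nrow(cr$points), 1L)
    expect_true(all(cr$points >= -0.5 & cr$points < 15.5))
  }

  cr <- sampleCrop(img, matrix(numeric(0), ncol = 2),
                   trainConfig(cropSize = 16, cellCentredProb = 0.8))
  expect_equal(nrow(cr$points), 0L)

  expect_error(sampleCrop(matrix(0, 8, 8), onecell,
                          trainConfig(cropSize = 16)), "smaller")

  set.seed(42)
  cfg <- trainConfig(cropSize = 16, cellCentredProb = 0.8)
  hits <- vapply(seq_len(10000),
                 function(i) sampleCrop(img, onecell, cfg)$cellCentred,
                 TRUE)
  expect_gte(mean(hits), 0.78)
  expect_lte(mean(hits), 0.82)
})

test_that("augmentation transforms pixels and coordinates together", {
  set.seed(8)
  crop <- matrix(runif(96 * 96), 96, 96)
  pts <- cbind(c(10, 40, 70), c(20, 50, 33))

  ident <- augmentCrop(crop, pts, transform = list(rot = 0L, flipH = FALSE,
                                                   flipV = FALSE, scale = 1,
                                                   intensity = NULL))
  expect_identical(ident$crop, crop)
  expect_equal(unname(ident$points), unname(pts))

  fl <- augmentCrop(crop, pts, transform = list(rot = 0L, flipH = TRUE,
                                                flipV = FALSE, scale = 1,
                                                intensity = NULL))
  expect_equal(unname(fl$points[1, ]), c(85, 20))
  expect_equal(fl$crop[21, 96 - 10], crop[21, 11])

  sc <- augmentCrop(crop, pts, transform = list(rot = 0L, flipH = FALSE,
                                                flipV = FALSE, scale = 1.1,
                                                intensity = NULL))
  expect_equal(as.numeric(dist(sc$points)), as.numeric(dist(pts)) * 1.1,
               tolerance = 1e-9)

  rot <- augmentCrop(crop, pts, transform = list(rot = 1L, flipH = FALSE,
                                                 flipV = FALSE, scale = 1,
                                                 intensity = NULL))
  expect_equal(as.numeric(dist(rot$points)), as.numeric(dist(pts)),
               tolerance = 1e-9)
})

test_that("short training reduces the loss and selects the argmin epoch", {
  set.seed(12)
  patches <- lapply(1:20, function(i) {
    pts <- cbind(runif(3, 4, 27), runif(3, 4, 27))
    list(image = renderBeliefMap(pts, 32, 32, 2) * 0.8 +
           matrix(runif(1024, 0, 0.05), 32, 32),
         coords = pts)
  })
  cfg <- trainConfig(cropSize = 32, batchSize = 8, learningRate = 1e-3,
                     maxEpochs = 12, cropsPerEpoch = 32, gaussianSigma = 2,
                     seed = 3)
  net <- trainNet(patches, valSet = patches[1:4],
                  spec = netSpec(depth = 2, channels = 4), cfg = cfg,
                  augment = NULL)
  h <- net@history
  expect_equal(nrow(h), 12L)
  expect_lt(h$trainLoss[12], h$trainLoss[1])
  expect_equal(net@bestEpoch, which.min(h$valLoss))
})

test_that("training is deterministic under a fixed seed", {
  patches <- lapply(1:4, function(i) {
    set.seed(i)
    pts <- cbind(runif(2, 3, 12), runif(2, 3, 12))
    list(image = renderBeliefMap(pts, 16, 16, 1.5), coords = pts)
  })
  cfg <- trainConfig(cropSize = 16, batchSize = 4, learningRate = 1e-3,
                     maxEpochs = 2, cropsPerEpoch = 8, gaussianSigma = 1.5,
                     seed = 6)
  n1 <- trainNet(patches, spec = netSpec(depth = 1, channels = 2), cfg = cfg)
  n2 <- trainNet(patches, spec = netSpec(depth = 1, channels = 2), cfg = cfg)
  expect_identical(n1@history, n2@history)
  expect_identical(n1@params, n2@params)
})

test_that("degenerate training inputs are rejected", {
  expect_error(trainNet(list()), "empty")
  noAnn <- list(list(image = matrix(0, 16, 16),
                     coords = matrix(numeric(0), ncol = 2)))
  expect_error(trainNet(noAnn), "annotations")
})
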