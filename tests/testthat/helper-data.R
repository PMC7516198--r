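# Shared fixture builders and the (expensive, memoised) trained detection
# model used by the end-to-end checks.

hexLattice <- function(nx, ny, pitch = 10, x0 = 0, y0 = 0) {
  pts <- NULL
  for (r in seq_len(ny)) {
    off <- if (r %% 2 == 0) pitch / 2 else 0
    pts <- rbind(pts, cbind(x0 + off + (seq_len(nx) - 1) * pitch,
                            y0 + (r - 1) * pitch * sqrt(3) / 2))
  }
  pts
}

# one synthetic nuclei scratch-assay field with ground truth
synthNucleiSample <- function(seed, width = 128, height = 128, nCells = 69,
                              gapWidth = 30) {
  pts <- generateMonolayer(monolayerSpec(width, height, nCells = nCells,
                                         minSeparation = 8, jitter = 3,
                                         seed = seed))
  if (gapWidth > 0)
    pts <- applyWound(pts, woundSpec("vertical", gapCentre = width / 2,
                                     gapWidthT0 = gapWidth), "t0",
                      seed = seed)
  img <- renderImage(pts, renderSpec("nuclei", nucleusSigma = 2,
                                     bitDepth = 12, backgroundLevel = 0.05,
                                     noiseSd = 0.02), seed = seed)
  list(image = normaliseImage(img), coords = pts)
}

.acceptanceCache <- new.env(parent = emptyenv())

# Scaled-down detection experiment: train the belief-map U-Net (reduced
# width) on a fixed set of 224 synthetic nuclei crops for 30 epochs, then
# evaluate on 20 held-out synthetic images at the 10-px matching gate.
# Memoised because training takes minutes and several checks reuse it.
acceptanceDetection <- function() {
  if (exists("res", envir = .acceptanceCache))
    return(get("res", envir = .acceptanceCache))
  trainImgs <- lapply(1:6, synthNucleiSample)
  valImgs <- lapply(7:10, synthNucleiSample)
  testImgs <- lapply(11:30, synthNucleiSample)
  cfgCrop <- trainConfig(cropSize = 64, cellCentredProb = 0.8, seed = 99)
  set.seed(99)
  cropSet <- lapply(seq_len(224), function(i) {
    src <- trainImgs[[sample.int(length(trainImgs), 1)]]
    cr <- sampleCrop(src$image, src$coords, cfgCrop)
    list(image = cr$crop, coords = cr$points)
  })
  cfg <- trainConfig(cropSize = 64, batchSize = 16, learningRate = 1e-3,
                     maxEpochs = 30, cropsPerEpoch = 224,
                     cellCentredProb = 0, gaussianSigma = 2.5, seed = 7)
  net <- trainNet(cropSet, valImgs, netSpec(depth = 3, channels = 8), cfg,
                  augment = augmentConfig())
  tp <- fp <- fn <- 0L
  for (s in testImgs) {
    r <- matchDetections(detectCells(net, s$image, 0.2), s$coords, 10)
    tp <- tp + r@tp; fp <- fp + r@fp; fn <- fn + r@fn
  }
  res <- list(net = net, testImgs = testImgs,
              scores = detectionScores(list(tp = tp, fp = fp, fn = fn)))
  assign("res", res, envir = .acceptanceCache)
  res
}
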