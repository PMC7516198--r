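#' Normalise a raw image to the unit intensity scale
#'
#' Divides all pixel values by the maximum possible intensity at the given
#' bit depth (\code{2^bitDepth - 1}; 4095 for 12-bit data), mapping the
#' image into \code{[0, 1]}.
#'
#' @param image an \linkS4class{ImageGrid} (its own bit depth is used) or a
#'   numeric matrix of raw intensities.
#' @param bitDepth bit depth; required when \code{image} is a plain matrix.
#' @return A numeric matrix with values in \code{[0, 1]}.
#' @examples
#' normaliseImage(matrix(4095, 1, 1), bitDepth = 12)  # 1.0
#' @export
normaliseImage <- function(image, bitDepth = NULL) {
  if (is(image, "ImageGrid")) {
    bitDepth <- bitDepth(image)
    image <- gridData(image)
  }
  if (is.null(bitDepth)) stop("bitDepth is required for a plain matrix")
  assertScalar(bitDepth, "bitDepth", 1, 32)
  mx <- 2^bitDepth - 1
  if (any(image < 0) || any(image > mx))
    stop("pixel values exceed the [0, ", mx, "] range of ", bitDepth,
         "-bit data")
  image / mx
}

#' Render dot annotations into a belief map
#'
#' Each annotation is placed on its rounded pixel and convolved with an
#' isotropic Gaussian kernel truncated at three sigma; overlapping kernels
#' sum and kernels are truncated (not renormalised) at image borders. The
#' single-point peak is normalised to 1 so detection thresholds have a
#' stable meaning.
#'
#' @param points a \linkS4class{CellCoords} or (x, y) matrix.
#' @param height,width output map size in pixels.
#' @param sigma Gaussian kernel sigma in pixels; the appropriate value
#'   scales with apparent cell size.
#' @return A numeric matrix of size \code{height x width}.
#' @export
renderBeliefMap <- function(points, height, width, sigma = 2.5) {
  assertScalar(sigma, "sigma", 1e-6)
  m <- coordsMatrix(points)
  canvas <- matrix(0, nrow = height, ncol = width)
  if (!nrow(m)) return(canvas)
  stampGaussians(canvas, m, sigma, 1)
}

#' Training configuration
#'
#' @param cropSize side of the square training crops (pixels); must be
#'   divisible by \code{2^depth} of the network.
#' @param batchSize crops per optimiser step.
#' @param learningRate Adam step size.
#' @param maxEpochs number of training epochs.
#' @param cropsPerEpoch crops sampled per epoch (the source data define no
#'   natural epoch size for random crops).
#' @param cellCentredProb probability that a crop is chosen around a
#'   randomly selected cell rather than uniformly.
#' @param gaussianSigma belief-map kernel sigma (pixels).
#' @param setBalance when image sets are labelled (e.g. nuclei-only vs
#'   mixed-stain), sample the sets equally often.
#' @param seed integer seed governing initialisation, crop sampling and
#'   augmentation draws.
#' @return A validated list of class \code{TrainConfig}.
#' @export
trainConfig <- function(cropSize = 96, batchSize = 128,
                        learningRate = 1.28e-4, maxEpochs = 160,
                        cropsPerEpoch = 512, cellCentredProb = 0.8,
                        gaussianSigma = 2.5, setBalance = FALSE, seed = 1) {
  assertScalar(cropSize, "cropSize", 4)
  assertScalar(batchSize, "batchSize", 1)
  assertScalar(learningRate, "learningRate", 1e-12, 1)
  assertScalar(maxEpochs, "maxEpochs", 1)
  assertScalar(cropsPerEpoch, "cropsPerEpoch", 1)
  assertScalar(cellCentredProb, "cellCentredProb", 0, 1)
  assertScalar(gaussianSigma, "gaussianSigma", 1e-6)
  structure(list(cropSize = as.integer(cropSize),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate,
                 maxEpochs = as.integer(maxEpochs),
                 cropsPerEpoch = as.integer(cropsPerEpoch),
                 cellCentredProb = cellCentredProb,
                 gaussianSigma = gaussianSigma,
                 setBalance = isTRUE(setBalance),
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Augmentation configuration
#'
#' Geometric transforms (90-degree rotations, flips, scaling) are applied
#' identically to pixels and annotation coordinates; intensity perturbations
#' apply to pixels only. Scaling may move annotations out of the crop, in
#' which case they are dropped.
#'
#' @param scaleRange uniform range of the isotropic scale factor.
#' @param intensityMultRange uniform range of the multiplicative intensity
#'   perturbation.
#' @param intensityShiftRange uniform range of the additive intensity
#'   perturbation (one of the two intensity perturbations is drawn per crop).
#' @param rotations,flips enable 90-degree rotations / horizontal and
#'   vertical flips.
#' @return A validated list of class \code{AugmentConfig}.
#' @export
augmentConfig <- function(scaleRange = c(0.9, 1.1),
                          intensityMultRange = c(0.5, 1.3),
                          intensityShiftRange = c(-0.2, 0.2),
                          rotations = TRUE, flips = TRUE) {
  stopifnot(length(scaleRange) == 2L, diff(scaleRange) >= 0,
            length(intensityMultRange) == 2L,
            length(intensityShiftRange) == 2L)
  structure(list(scaleRange = scaleRange,
                 intensityMultRange = intensityMultRange,
                 intensityShiftRange = intensityShiftRange,
                 rotations = isTRUE(rotations), flips = isTRUE(flips)),
            class = "AugmentConfig")
}

#' Sample a training crop
#'
#' With probability \code{cellCentredProb} a random annotated cell is chosen
#' and the crop is drawn uniformly among windows containing it; otherwise
#' the window is uniform over the image. Annotations inside the crop are
#' returned translated to the crop frame (half-open pixel ranges).
#'
#' @param image numeric matrix (normalised image).
#' @param points a \linkS4class{CellCoords} or (x, y) matrix.
#' @param cfg a \code{\link{trainConfig}}. Uses the session RNG stream; seed
#'   via the caller (e.g. \code{\link{trainNet}}).
#' @return list with \code{crop} (matrix), \code{points} ((x, y) matrix in
#'   crop coordinates) and \code{cellCentred} (logical).
#' @export
sampleCrop <- function(image, points, cfg) {
  cs <- cfg$cropSize
  h <- nrow(image); w <- ncol(image)
  if (h < cs || w < cs)
    stop("image (", w, "x", h, ") is smaller than the crop size ", cs)
  m <- coordsMatrix(points)
  cellCentred <- nrow(m) > 0 && stats::runif(1) < cfg$cellCentredProb
  if (cellCentred) {
    i <- sample.int(nrow(m), 1L)
    ox <- sampleOffset(m[i, 1], cs, w)
    oy <- sampleOffset(m[i, 2], cs, h)
  } else {
    ox <- sample.int(w - cs + 1L, 1L) - 1L
    oy <- sample.int(h - cs + 1L, 1L) - 1L
  }
  crop <- image[oy + seq_len(cs), ox + seq_len(cs), drop = FALSE]
  inside <- m[, 1] >= ox - 0.5 & m[, 1] < ox + cs - 0.5 &
            m[, 2] >= oy - 0.5 & m[, 2] < oy + cs - 0.5
  cp <- m[inside, , drop = FALSE]
  cp[, 1] <- cp[, 1] - ox
  cp[, 2] <- cp[, 2] - oy
  list(crop = crop, points = cp, cellCentred = cellCentred)
}

# uniform 0-based crop offset whose window contains coordinate v
sampleOffset <- function(v, cs, extent) {
  lo <- max(0L, as.integer(ceiling(v)) - cs + 1L)
  hi <- min(extent - cs, as.integer(floor(v)))
  if (hi < lo) hi <- lo
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

rot90cw <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])

resizeBilinear <- function(m, s) {
  h <- nrow(m); w <- ncol(m)
  nh <- max(1L, as.integer(round(h * s)))
  nw <- max(1L, as.integer(round(w * s)))
  # output pixel centre u maps to input coordinate u / s (0-based, scaling
  # about the origin pixel so coordinates transform as p' = p * s)
  yi <- pmin(pmax((seq_len(nh) - 1) / s, 0), h - 1)
  xi <- pmin(pmax((seq_len(nw) - 1) / s, 0), w - 1)
  y0 <- pmin(floor(yi), h - 2); x0 <- pmin(floor(xi), w - 2)
  fy <- yi - y0; fx <- xi - x0
  m00 <- m[cbind(rep(y0 + 1, nw), rep(x0 + 1, each = nh))]
  m10 <- m[cbind(rep(y0 + 2, nw), rep(x0 + 1, each = nh))]
  m01 <- m[cbind(rep(y0 + 1, nw), rep(x0 + 2, each = nh))]
  m11 <- m[cbind(rep(y0 + 2, nw), rep(x0 + 2, each = nh))]
  fyv <- rep(fy, nw); fxv <- rep(fx, each = nh)
  v <- m00 * (1 - fyv) * (1 - fxv) + m10 * fyv * (1 - fxv) +
       m01 * (1 - fyv) * fxv + m11 * fyv * fxv
  matrix(v, nrow = nh, ncol = nw)
}

#' Augment a crop and its annotations
#'
#' @param crop square numeric matrix.
#' @param points (x, y) matrix in crop coordinates.
#' @param cfg an \code{\link{augmentConfig}}, or \code{NULL} for identity.
#' @param transform optional list overriding the random draw, with elements
#'   \code{rot} (0--3 clockwise quarter turns), \code{flipH}, \code{flipV},
#'   \code{scale}, \code{intensity} (\code{"mult"} or \code{"shift"}) and
#'   \code{value}; used for deterministic testing.
#' @return list with transformed \code{crop} and \code{points}.
#' @export
augmentCrop <- function(crop, points, cfg = augmentConfig(),
                        transform = NULL) {
  if (is.null(cfg) && is.null(transform))
    return(list(crop = crop, points = points))
  cs <- nrow(crop)
  stopifnot(ncol(crop) == cs)
  tr <- transform
  if (is.null(tr)) {
    tr <- list(
      rot = if (cfg$rotations) sample.int(4L, 1L) - 1L else 0L,
      flipH = cfg$flips && stats::runif(1) < 0.5,
      flipV = cfg$flips && stats::runif(1) < 0.5,
      scale = stats::runif(1, cfg$scaleRange[1], cfg$scaleRange[2]),
      intensity = if (stats::runif(1) < 0.5) "mult" else "shift")
    tr$value <- if (tr$intensity == "mult")
      stats::runif(1, cfg$intensityMultRange[1], cfg$intensityMultRange[2])
    else stats::runif(1, cfg$intensityShiftRange[1], cfg$intensityShiftRange[2])
  }
  m <- points
  # quarter turns: clockwise rotation maps (x, y) -> (W-1-y, x)
  for (r in seq_len(tr$rot %||% 0)) {
    crop <- rot90cw(crop)
    if (nrow(m)) m <- cbind(cs - 1 - m[, 2], m[, 1])
  }
  if (isTRUE(tr$flipH)) {
    crop <- crop[, rev(seq_len(cs)), drop = FALSE]
    if (nrow(m)) m[, 1] <- cs - 1 - m[, 1]
  }
  if (isTRUE(tr$flipV)) {
    crop <- crop[rev(seq_len(cs)), , drop = FALSE]
    if (nrow(m)) m[, 2] <- cs - 1 - m[, 2]
  }
  s <- tr$scale %||% 1
  if (!isTRUE(all.equal(s, 1))) {
    z <- resizeBilinear(crop, s)
    out <- matrix(0, cs, cs)
    kh <- min(cs, nrow(z)); kw <- min(cs, ncol(z))
    out[seq_len(kh), seq_len(kw)] <- z[seq_len(kh), seq_len(kw)]
    crop <- out
    if (nrow(m)) {
      m <- m * s
      keep <- m[, 1] >= -0.5 & m[, 1] < cs - 0.5 &
              m[, 2] >= -0.5 & m[, 2] < cs - 0.5
      m <- m[keep, , drop = FALSE]
    }
  }
  if (!is.null(tr$intensity)) {
    crop <- if (tr$intensity == "mult") crop * tr$value else crop - tr$value
  }
  colnames(m) <- c("x", "y")
  list(crop = crop, points = m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamInit <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adamStep <- function(params, grads, state, lr, t, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$gW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$gW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$gb
    s$vb <- beta2 * s$vb + (1 - beta2) * g$gb^2
    params[[nm]]$W <- params[[nm]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

#' Train the belief-map U-Net from dot annotations
#'
#' Minimises per-pixel mean squared error between the predicted belief map
#' and the Gaussian-rendered annotation map with the Adam optimiser.
#' Training crops are sampled per epoch (cell-centred with probability
#' \code{cellCentredProb}), optionally augmented, and optionally balanced
#' across labelled image sets. After every epoch the validation loss is
#' recorded and the returned model carries the parameters of the epoch with
#' the lowest validation loss.
#'
#' @param trainSet list of samples, each a list with \code{image} (numeric
#'   matrix on the \code{[0, 1]} scale), \code{coords}
#'   (\linkS4class{CellCoords} or (x, y) matrix) and optional \code{set}
#'   label used by \code{setBalance}.
#' @param valSet like \code{trainSet}; validation images must have sides
#'   divisible by \code{2^depth}. When \code{NULL} the training loss doubles
#'   as the selection score.
#' @param spec a \code{\link{netSpec}}.
#' @param cfg a \code{\link{trainConfig}}.
#' @param augment an \code{\link{augmentConfig}} or \code{NULL} to disable
#'   augmentation.
#' @param verbose print a line per epoch.
#' @return A trained \linkS4class{ScratchNet}; \code{@history} holds the
#'   per-epoch losses and \code{@bestEpoch} the selected epoch (1-based
#'   argmin of the validation loss).
#' @export
trainNet <- function(trainSet, valSet = NULL, spec = netSpec(),
                     cfg = trainConfig(), augment = augmentConfig(),
                     verbose = FALSE) {
  stopifnot(inherits(spec, "NetSpec"), inherits(cfg, "TrainConfig"))
  if (!length(trainSet)) stop("training set is empty")
  nAnn <- vapply(trainSet, function(s) nrow(coordsMatrix(s$coords)), 0L)
  if (all(nAnn == 0L)) stop("training set carries no annotations")
  if (cfg$cropSize %% 2^spec$depth != 0)
    stop("cropSize must be divisible by 2^depth = ", 2^spec$depth)
  sets <- vapply(trainSet, function(s) s$set %||% "all", "")
  withSeed(cfg$seed, {
    model <- buildModel(spec, seed = cfg$seed)
    params <- model@params
    state <- adamInit(params)
    steps <- ceiling(cfg$cropsPerEpoch / cfg$batchSize)
    hist <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                       valLoss = numeric(0))
    best <- list(loss = Inf, params = params, epoch = NA_integer_)
    t <- 0L
    for (epoch in seq_len(cfg$maxEpochs)) {
      epochLoss <- 0
      for (s in seq_len(steps)) {
        grads <- NULL
        batchLoss <- 0
        for (b in seq_len(cfg$batchSize)) {
          idx <- if (cfg$setBalance && length(unique(sets)) > 1L) {
            g <- sample(unique(sets), 1L)
            cand <- which(sets == g)
            cand[sample.int(length(cand), 1L)]
          } else sample.int(length(trainSet), 1L)
          smp <- trainSet[[idx]]
          cr <- sampleCrop(smp$image, smp$coords, cfg)
          if (!is.null(augment)) {
            au <- augmentCrop(cr$crop, cr$points, augment)
            cr <- list(crop = au$crop, points = au$points)
          }
          target <- renderBeliefMap(cr$points, cfg$cropSize, cfg$cropSize,
                                    cfg$gaussianSigma)
          fw <- unetForward(params, spec, cr$crop, keepCache = TRUE)
          diff <- fw$out - target
          batchLoss <- batchLoss + mean(diff^2)
          gOut <- 2 * diff / (length(diff) * cfg$batchSize)
          gb <- unetBackward(params, spec, fw, gOut)
          grads <- if (is.null(grads)) gb else
            mapply(function(a, d) list(gW = a$gW + d$gW, gb = a$gb + d$gb),
                   grads, gb, SIMPLIFY = FALSE)
        }
        batchLoss <- batchLoss / cfg$batchSize
        if (!is.finite(batchLoss))
          stop("training diverged (non-finite loss) at epoch ", epoch,
               ", step ", s, "; lower the learning rate")
        t <- t + 1L
        up <- adamStep(params, grads, state, cfg$learningRate, t)
        params <- up$params; state <- up$state
        epochLoss <- epochLoss + batchLoss
      }
      epochLoss <- epochLoss / steps
      valLoss <- if (is.null(valSet)) epochLoss else
        mean(vapply(valSet, function(s) {
          pred <- unetForward(params, spec, s$image)$out
          tgt <- renderBeliefMap(s$coords, nrow(s$image), ncol(s$image),
                                 cfg$gaussianSigma)
          mean((pred - tgt)^2)
        }, 0))
      hist <- rbind(hist, data.frame(epoch = epoch, trainLoss = epochLoss,
                                     valLoss = valLoss))
      if (valLoss < best$loss)
        best <- list(loss = valLoss, params = params, epoch = epoch)
      if (verbose)
        message(sprintf("epoch %3d  train %.4g  val %.4g", epoch,
                        epochLoss, valLoss))
    }
    initialize(model, params = best$params, history = hist,
               bestEpoch = as.numeric(best$epoch))
  })
}
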