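#' U-Net architecture specification
#'
#' The belief-map regressor is a U-Net: an encoder of \code{depth} blocks
#' (two convolutions per block, constant channel width, 2x2 max-pooling
#' between blocks), a two-convolution bottleneck, and a mirrored decoder
#' using 2x2 nearest-neighbour upsampling with skip connections merged by
#' channel concatenation. Every convolution is followed by a leaky ReLU
#' (negative slope \code{leakySlope}); there is no batch normalisation. A
#' final 1x1 linear convolution compresses to a single-channel belief map,
#' so the output always has the spatial shape of the input.
#'
#' @param depth encoder/decoder blocks (input sides must be divisible by
#'   \code{2^depth}).
#' @param channels feature maps per convolution.
#' @param initialKernel kernel size of the very first convolution.
#' @param innerKernel kernel size of all other convolutions.
#' @param leakySlope negative slope of the leaky ReLU.
#' @return A validated list of class \code{NetSpec}.
#' @export
netSpec <- function(depth = 4, channels = 48, initialKernel = 7,
                    innerKernel = 3, leakySlope = 0.1) {
  assertScalar(depth, "depth", 1, 8)
  assertScalar(channels, "channels", 1, 512)
  assertOddKernel(initialKernel, "initialKernel")
  assertOddKernel(innerKernel, "innerKernel")
  assertScalar(leakySlope, "leakySlope", 0, 1)
  structure(list(depth = as.integer(depth), channels = as.integer(channels),
                 initialKernel = as.integer(initialKernel),
                 innerKernel = as.integer(innerKernel),
                 leakySlope = leakySlope),
            class = "NetSpec")
}

# one convolution layer's parameters
newConvLayer <- function(cin, cout, k, finalLayer = FALSE) {
  sd <- if (finalLayer) sqrt(1 / (k * k * cin)) else sqrt(2 / (k * k * cin))
  list(W = matrix(stats::rnorm(k * k * cin * cout, 0, sd),
                  nrow = k * k * cin, ncol = cout),
       b = numeric(cout), k = as.integer(k), cin = as.integer(cin),
       cout = as.integer(cout))
}

layerNames <- function(spec) {
  d <- spec$depth
  c(paste0("enc", rep(seq_len(d), each = 2), "_conv", 1:2),
    "bot_conv1", "bot_conv2",
    paste0("dec", rep(rev(seq_len(d)), each = 2), "_conv", 1:2),
    "final")
}

#' Build a belief-map U-Net with seeded random initialisation
#'
#' Weights use He (fan-in) initialisation appropriate for leaky-ReLU
#' activations; the final linear layer is initialised small with zero bias
#' so an untrained network produces finite, near-zero maps.
#'
#' @param spec a \code{\link{netSpec}}.
#' @param seed integer seed for the weight draw.
#' @return A \linkS4class{ScratchNet}.
#' @examples
#' net <- buildModel(netSpec(depth = 2, channels = 4), seed = 1)
#' dim(predictBeliefMap(net, matrix(0, 32, 32)))
#' @export
buildModel <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "NetSpec"))
  C <- spec$channels
  withSeed(seed, {
    params <- list()
    for (d in seq_len(spec$depth)) {
      cin1 <- if (d == 1) 1L else C
      k1 <- if (d == 1) spec$initialKernel else spec$innerKernel
      params[[paste0("enc", d, "_conv1")]] <- newConvLayer(cin1, C, k1)
      params[[paste0("enc", d, "_conv2")]] <- newConvLayer(C, C, spec$innerKernel)
    }
    params[["bot_conv1"]] <- newConvLayer(C, C, spec$innerKernel)
    params[["bot_conv2"]] <- newConvLayer(C, C, spec$innerKernel)
    for (d in rev(seq_len(spec$depth))) {
      params[[paste0("dec", d, "_conv1")]] <- newConvLayer(2L * C, C, spec$innerKernel)
      params[[paste0("dec", d, "_conv2")]] <- newConvLayer(C, C, spec$innerKernel)
    }
    params[["final"]] <- newConvLayer(C, 1L, 1L, finalLayer = TRUE)
    new("ScratchNet", spec = unclass(spec), params = params,
        history = data.frame(epoch = integer(0), trainLoss = numeric(0),
                             valLoss = numeric(0)),
        bestEpoch = NA_real_)
  })
}

lrelu <- function(z, slope) pmax(z, 0) + slope * pmin(z, 0)
lreluGrad <- function(z, slope) ifelse(z > 0, 1, slope)

convForward <- function(layer, x, slope, keepCache) {
  H <- dim(x)[1]; W <- dim(x)[2]
  cols <- cpp_im2col(x, layer$k)
  z <- cols %*% layer$W
  z <- sweep(z, 2L, layer$b, "+")
  a <- if (is.null(slope)) z else lrelu(z, slope)
  dim(a) <- c(H, W, layer$cout)
  list(a = a, cache = if (keepCache) list(cols = cols, z = z,
                                          H = H, W = W) else NULL)
}

convBackward <- function(layer, cache, gA, slope, needGx = TRUE) {
  gZ <- matrix(gA, nrow = cache$H * cache$W, ncol = layer$cout)
  if (!is.null(slope)) gZ <- gZ * lreluGrad(cache$z, slope)
  gW <- crossprod(cache$cols, gZ)
  gb <- colSums(gZ)
  gX <- NULL
  if (needGx)
    gX <- cpp_col2im(gZ %*% t(layer$W), cache$H, cache$W, layer$cin, layer$k)
  list(gW = gW, gb = gb, gX = gX)
}

upsample2 <- function(a) {
  h <- dim(a)[1]; w <- dim(a)[2]
  a[rep(seq_len(h), each = 2L), rep(seq_len(w), each = 2L), , drop = FALSE]
}

upsample2Bwd <- function(g) {
  h2 <- dim(g)[1]; w2 <- dim(g)[2]
  g1 <- g[seq(1L, h2, 2L), , , drop = FALSE] + g[seq(2L, h2, 2L), , , drop = FALSE]
  g1[, seq(1L, w2, 2L), , drop = FALSE] + g1[, seq(2L, w2, 2L), , drop = FALSE]
}

concat3 <- function(a, b) {
  array(c(a, b), dim = c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

# Full forward pass; with keepCache = TRUE returns everything the backward
# pass needs for one sample.
unetForward <- function(params, spec, x, keepCache = FALSE) {
  depth <- spec$depth
  H <- dim(x)[1]; W <- dim(x)[2]
  if (H %% 2^depth != 0 || W %% 2^depth != 0)
    stop("input spatial size (", H, "x", W, ") must be divisible by 2^depth = ",
         2^depth)
  sl <- spec$leakySlope
  caches <- list(); skips <- list(); poolIdx <- list()
  a <- if (length(dim(x)) == 2L) array(x, dim = c(H, W, 1L)) else x
  for (d in seq_len(depth)) {
    for (j in 1:2) {
      nm <- paste0("enc", d, "_conv", j)
      r <- convForward(params[[nm]], a, sl, keepCache)
      a <- r$a; caches[[nm]] <- r$cache
    }
    skips[[d]] <- a
    p <- cpp_maxpool2(a)
    a <- p$y; poolIdx[[d]] <- p$idx
  }
  for (nm in c("bot_conv1", "bot_conv2")) {
    r <- convForward(params[[nm]], a, sl, keepCache)
    a <- r$a; caches[[nm]] <- r$cache
  }
  for (d in rev(seq_len(depth))) {
    a <- concat3(skips[[d]], upsample2(a))
    for (j in 1:2) {
      nm <- paste0("dec", d, "_conv", j)
      r <- convForward(params[[nm]], a, sl, keepCache)
      a <- r$a; caches[[nm]] <- r$cache
    }
  }
  r <- convForward(params[["final"]], a, NULL, keepCache)
  caches[["final"]] <- r$cache
  out <- matrix(r$a, nrow = H, ncol = W)
  if (keepCache)
    list(out = out, caches = caches, poolIdx = poolIdx, depth = depth)
  else list(out = out)
}

# Backward pass for one sample; returns gradients named like params.
unetBackward <- function(params, spec, fw, gOut) {
  depth <- fw$depth
  sl <- spec$leakySlope
  C <- spec$channels
  grads <- list()
  g <- array(gOut, dim = c(dim(gOut)[1], dim(gOut)[2], 1L))
  bk <- convBackward(params[["final"]], fw$caches[["final"]], g, NULL)
  grads[["final"]] <- bk[c("gW", "gb")]
  g <- bk$gX
  skipGrads <- list()
  for (d in seq_len(depth)) {  # decoder blocks, deepest-processed last in fwd
    for (j in 2:1) {
      nm <- paste0("dec", d, "_conv", j)
      bk <- convBackward(params[[nm]], fw$caches[[nm]], g, sl)
      grads[[nm]] <- bk[c("gW", "gb")]
      g <- bk$gX
    }
    # split the concat: first C channels went to the skip, rest to upsample
    skipGrads[[d]] <- g[, , seq_len(C), drop = FALSE]
    g <- upsample2Bwd(g[, , C + seq_len(C), drop = FALSE])
  }
  for (nm in c("bot_conv2", "bot_conv1")) {
    bk <- convBackward(params[[nm]], fw$caches[[nm]], g, sl)
    grads[[nm]] <- bk[c("gW", "gb")]
    g <- bk$gX
  }
  for (d in rev(seq_len(depth))) {
    gin <- cpp_maxpool2_bwd(fw$poolIdx[[d]],
                            array(g, dim = dim(fw$poolIdx[[d]])),
                            dim(skipGrads[[d]])[1], dim(skipGrads[[d]])[2])
    g <- gin + skipGrads[[d]]
    for (j in 2:1) {
      nm <- paste0("enc", d, "_conv", j)
      bk <- convBackward(params[[nm]], fw$caches[[nm]], g, sl,
                         needGx = !(d == 1 && j == 1))
      grads[[nm]] <- bk[c("gW", "gb")]
      g <- bk$gX
    }
  }
  grads
}

#' Predict a belief map for an image
#'
#' Runs the network forward on a normalised greyscale image. The output has
#' the same spatial shape as the input, one belief value per pixel.
#'
#' @param model a \linkS4class{ScratchNet}.
#' @param image an \linkS4class{ImageGrid} (normalised internally) or a
#'   numeric matrix already on the \code{[0, 1]} scale. Both sides must be
#'   divisible by \code{2^depth}.
#' @return A numeric matrix (belief map).
#' @export
predictBeliefMap <- function(model, image) {
  stopifnot(is(model, "ScratchNet"))
  m <- if (is(image, "ImageGrid")) normaliseImage(image) else image
  stopifnot(is.matrix(m))
  unetForward(model@params, model@spec, m)$out
}

#' Detect cells in an image
#'
#' Convenience wrapper: predict the belief map, then extract thresholded
#' local maxima (see \code{\link{extractLocalMaxima}}).
#'
#' @inheritParams predictBeliefMap
#' @param threshold detection threshold on the globally-normalised belief
#'   map, in \code{[0, 1]}.
#' @return A \linkS4class{CellCoords}.
#' @export
detectCells <- function(model, image, threshold = 0.2) {
  extractLocalMaxima(predictBeliefMap(model, image), threshold)
}
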