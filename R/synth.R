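#' Specification of a synthetic confluent monolayer
#'
#' Describes a jittered hexagonal point pattern emulating a confluent
#' endothelial monolayer. Confluent epithelia are close to hexagonal
#' packing, so points are placed on a hexagonal lattice whose pitch is set
#' by the target cell count, then perturbed by uniform jitter; a minimum
#' pairwise separation is guaranteed by capping the effective jitter at
#' \code{(pitch - minSeparation) / 2}.
#'
#' @param width,height image size in pixels.
#' @param nCells number of cells to place.
#' @param minSeparation minimum pairwise distance between centres (pixels).
#' @param jitter half-width of the uniform lattice perturbation (pixels).
#' @param seed integer seed; identical specs generate identical patterns.
#' @return A validated list of class \code{MonolayerSpec}.
#' @export
monolayerSpec <- function(width = 512, height = 512, nCells = 1000,
                          minSeparation = 8, jitter = 3, seed = 1) {
  assertScalar(width, "width", 1)
  assertScalar(height, "height", 1)
  assertScalar(nCells, "nCells", 0)
  assertScalar(minSeparation, "minSeparation", 1e-6)
  assertScalar(jitter, "jitter", 0)
  structure(list(width = width, height = height, nCells = as.integer(nCells),
                 minSeparation = minSeparation, jitter = jitter,
                 seed = as.integer(seed)),
            class = "MonolayerSpec")
}

#' Generate a synthetic confluent monolayer point pattern
#'
#' @param spec a \code{\link{monolayerSpec}}.
#' @return A \linkS4class{CellCoords} with exactly \code{nCells} points, all
#'   pairwise distances at least \code{minSeparation}.
#' @details The hexagonal pitch is \code{sqrt(2*W*H / (n*sqrt(3)))}. If the
#'   requested density cannot accommodate \code{minSeparation} the function
#'   raises a capacity error rather than silently returning fewer points.
#' @examples
#' pts <- generateMonolayer(monolayerSpec(256, 256, nCells = 200, seed = 3))
#' nCells(pts)
#' @export
generateMonolayer <- function(spec) {
  stopifnot(inherits(spec, "MonolayerSpec"))
  n <- spec$nCells
  W <- spec$width; H <- spec$height
  if (n == 0L)
    return(cellCoords(width = W, height = H))
  pitch <- sqrt(2 * W * H / (n * sqrt(3)))
  if (pitch <= spec$minSeparation)
    stop("capacity error: cannot place ", n, " cells with minSeparation ",
         spec$minSeparation, " in a ", W, "x", H, " domain (lattice pitch ",
         signif(pitch, 4), ")")
  jmax <- min(spec$jitter, (pitch - spec$minSeparation) / 2)
  withSeed(spec$seed, {
    dy <- pitch * sqrt(3) / 2
    rows <- seq(-pitch, H - 1 + pitch, by = dy)
    pts <- do.call(rbind, lapply(seq_along(rows), function(r) {
      off <- if (r %% 2 == 0) pitch / 2 else 0
      xs <- seq(-pitch + off, W - 1 + pitch, by = pitch)
      cbind(xs, rows[r])
    }))
    pts <- pts + matrix(stats::runif(2 * nrow(pts), -jmax, jmax),
                        ncol = 2)
    keep <- pts[, 1] >= 0 & pts[, 1] <= W - 1 &
            pts[, 2] >= 0 & pts[, 2] <= H - 1
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) > n) {
      pts <- pts[sample.int(nrow(pts), n), , drop = FALSE]
    } else if (nrow(pts) < n) {
      # fill edge losses with rejection-sampled extra points
      tries <- 0L
      while (nrow(pts) < n && tries < 200L * n) {
        cand <- c(stats::runif(1, 0, W - 1), stats::runif(1, 0, H - 1))
        d2 <- (pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2
        if (!length(d2) || min(d2) >= spec$minSeparation^2)
          pts <- rbind(pts, cand)
        tries <- tries + 1L
      }
      if (nrow(pts) < n)
        stop("capacity error: rejection sampling could not place ", n,
             " cells at minSeparation ", spec$minSeparation)
    }
    cellCoords(pts[, 1], pts[, 2], width = W, height = H)
  })
}

#' Specification of a scratch wound applied to a monolayer
#'
#' The wound is a straight empty band across the monolayer. At the later
#' timepoint the band narrows (closure) and, when
#' \code{gradientStrength > 0}, cells are thinned with retention
#' probability decreasing towards the gap, reproducing the spatially
#' coordinated spreading seen during healing: local cell density then rises
#' with distance from the wound.
#'
#' @param gapAxis \code{"vertical"} (band spans image height) or
#'   \code{"horizontal"}.
#' @param gapCentre band centre coordinate in pixels (x for a vertical band).
#' @param gapWidthT0,gapWidthT24 band width in pixels at 0 h and 24 h;
#'   \code{gapWidthT24 <= gapWidthT0}.
#' @param gradientStrength in \code{[0, 1]}; 0 keeps density spatially
#'   uniform, larger values thin cells more strongly near the gap at t24.
#' @return A validated list of class \code{WoundSpec}.
#' @export
woundSpec <- function(gapAxis = c("vertical", "horizontal"), gapCentre,
                      gapWidthT0, gapWidthT24 = gapWidthT0,
                      gradientStrength = 0) {
  gapAxis <- match.arg(gapAxis)
  assertScalar(gapCentre, "gapCentre", 0)
  assertScalar(gapWidthT0, "gapWidthT0", 0)
  assertScalar(gapWidthT24, "gapWidthT24", 0)
  assertScalar(gradientStrength, "gradientStrength", 0, 1)
  if (gapWidthT24 > gapWidthT0)
    stop("gapWidthT24 must not exceed gapWidthT0 (wounds close, not open)")
  structure(list(gapAxis = gapAxis, gapCentre = gapCentre,
                 gapWidthT0 = gapWidthT0, gapWidthT24 = gapWidthT24,
                 gradientStrength = gradientStrength),
            class = "WoundSpec")
}

#' Carve a scratch wound into a point pattern
#'
#' Removes all points inside the gap band of the requested timepoint and, at
#' t24 with positive gradient strength, thins the remaining points with
#' retention probability \code{(1 - g) + g * d / dmax} where \code{d} is the
#' distance to the gap centre line.
#'
#' @param points a \linkS4class{CellCoords}.
#' @param wound a \code{\link{woundSpec}}.
#' @param timepoint \code{"t0"} or \code{"t24"}.
#' @param seed integer seed for the thinning draw.
#' @return A \linkS4class{CellCoords}.
#' @export
applyWound <- function(points, wound, timepoint = c("t0", "t24"), seed = 1) {
  stopifnot(is(points, "CellCoords"), inherits(wound, "WoundSpec"))
  timepoint <- match.arg(timepoint)
  m <- coords(points)
  if (!nrow(m)) return(points)
  ax <- if (wound$gapAxis == "vertical") m[, 1] else m[, 2]
  halfw <- (if (timepoint == "t0") wound$gapWidthT0 else wound$gapWidthT24) / 2
  d <- abs(ax - wound$gapCentre)
  keep <- d >= halfw
  if (timepoint == "t24" && wound$gradientStrength > 0) {
    extent <- if (wound$gapAxis == "vertical") points@width else points@height
    dmax <- max(wound$gapCentre, extent - 1 - wound$gapCentre)
    p <- (1 - wound$gradientStrength) + wound$gradientStrength * pmin(d / dmax, 1)
    keep <- keep & withSeed(seed, stats::runif(length(p)) < p)
  }
  cellCoords(m[keep, 1], m[keep, 2], width = points@width,
             height = points@height)
}

#' Rendering specification for synthetic microscopy images
#'
#' @param stain \code{"nuclei"} (Gaussian blobs at cell centres),
#'   \code{"membrane"} (bright ridges along Voronoi boundaries) or
#'   \code{"both"}.
#' @param nucleusSigma Gaussian radius of a rendered nucleus (pixels).
#' @param membraneThickness Gaussian cross-section sigma of membrane ridges
#'   (pixels).
#' @param bitDepth output bit depth (values scaled to
#'   \code{[0, 2^bitDepth - 1]}).
#' @param backgroundLevel,noiseSd background intensity and additive Gaussian
#'   noise standard deviation, both on the \code{[0, 1]} fraction scale.
#' @param amplitude peak signal amplitude on the fraction scale.
#' @return A validated list of class \code{RenderSpec}.
#' @export
renderSpec <- function(stain = c("nuclei", "membrane", "both"),
                       nucleusSigma = 2, membraneThickness = 1.5,
                       bitDepth = 12, backgroundLevel = 0.05,
                       noiseSd = 0.01, amplitude = 0.7) {
  stain <- match.arg(stain)
  assertScalar(nucleusSigma, "nucleusSigma", 1e-3)
  assertScalar(membraneThickness, "membraneThickness", 1e-3)
  assertScalar(bitDepth, "bitDepth", 1, 16)
  assertScalar(backgroundLevel, "backgroundLevel", 0, 1)
  assertScalar(noiseSd, "noiseSd", 0, 1)
  assertScalar(amplitude, "amplitude", 0, 1)
  structure(list(stain = stain, nucleusSigma = nucleusSigma,
                 membraneThickness = membraneThickness,
                 bitDepth = as.integer(bitDepth),
                 backgroundLevel = backgroundLevel, noiseSd = noiseSd,
                 amplitude = amplitude),
            class = "RenderSpec")
}

# additive Gaussian blob stamping; peak amplitude `amp` per point
stampGaussians <- function(canvas, pts, sigma, amp) {
  h <- nrow(canvas); w <- ncol(canvas)
  r <- ceiling(3 * sigma)
  kseq <- -r:r
  kern <- amp * exp(-outer(kseq^2, kseq^2, "+") / (2 * sigma^2))
  for (i in seq_len(nrow(pts))) {
    cx <- round(pts[i, 1]) + 1L; cy <- round(pts[i, 2]) + 1L
    ys <- (cy - r):(cy + r); xs <- (cx - r):(cx + r)
    okY <- ys >= 1L & ys <= h; okX <- xs >= 1L & xs <= w
    canvas[ys[okY], xs[okX]] <- canvas[ys[okY], xs[okX]] +
      kern[which(okY), which(okX)]
  }
  canvas
}

# max-combined Gaussian-profile ridges along segments (x0,y0)-(x1,y1)
stampRidges <- function(canvas, segs, sigma, amp) {
  h <- nrow(canvas); w <- ncol(canvas)
  r <- ceiling(3 * sigma)
  for (i in seq_len(nrow(segs))) {
    x0 <- segs[i, 1]; y0 <- segs[i, 2]; x1 <- segs[i, 3]; y1 <- segs[i, 4]
    xs <- max(1L, floor(min(x0, x1)) + 1L - r):min(w, ceiling(max(x0, x1)) + 1L + r)
    ys <- max(1L, floor(min(y0, y1)) + 1L - r):min(h, ceiling(max(y0, y1)) + 1L + r)
    if (!length(xs) || !length(ys)) next
    px <- matrix(xs - 1, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    py <- matrix(ys - 1, nrow = length(ys), ncol = length(xs))
    vx <- x1 - x0; vy <- y1 - y0
    len2 <- vx^2 + vy^2
    t <- if (len2 > 0) pmin(pmax(((px - x0) * vx + (py - y0) * vy) / len2, 0), 1)
         else 0
    d2 <- (px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2
    patch <- amp * exp(-d2 / (2 * sigma^2))
    canvas[ys, xs] <- pmax(canvas[ys, xs], patch)
  }
  canvas
}

#' Render a synthetic microscopy image from cell centres
#'
#' Nuclear staining renders each centre as an additive Gaussian blob;
#' membrane staining renders bright Gaussian-profile ridges along the
#' Voronoi boundaries of the point pattern. The noise-free nuclear
#' rendering has a local intensity maximum at every cell centre provided
#' centres are separated by more than about four nucleus sigmas.
#'
#' @param points a \linkS4class{CellCoords} with image bounds set.
#' @param spec a \code{\link{renderSpec}}.
#' @param seed integer seed for the noise draw (ignored when
#'   \code{noiseSd = 0}).
#' @return An \linkS4class{ImageGrid} of size \code{height x width}.
#' @export
renderImage <- function(points, spec, seed = 1) {
  stopifnot(is(points, "CellCoords"), inherits(spec, "RenderSpec"))
  W <- points@width; H <- points@height
  if (is.na(W) || is.na(H))
    stop("points must carry image bounds (width/height) for rendering")
  canvas <- matrix(0, nrow = H, ncol = W)
  m <- coords(points)
  if (nrow(m)) {
    if (spec$stain %in% c("nuclei", "both"))
      canvas <- stampGaussians(canvas, m, spec$nucleusSigma, spec$amplitude)
    if (spec$stain %in% c("membrane", "both") && nrow(m) >= 4) {
      cells <- cpp_voronoi_cells(m, -0.5, -0.5, W - 0.5, H - 0.5, 1e-6)
      segs <- do.call(rbind, lapply(cells, function(cl) {
        v <- cl$vertices
        if (nrow(v) < 2) return(NULL)
        cbind(v[, 1], v[, 2], v[c(2:nrow(v), 1), 1], v[c(2:nrow(v), 1), 2])
      }))
      canvas <- stampRidges(canvas, segs, spec$membraneThickness,
                            spec$amplitude)
    }
  }
  img <- spec$backgroundLevel + canvas
  if (spec$noiseSd > 0)
    img <- img + withSeed(seed, matrix(stats::rnorm(length(img), 0,
                                                    spec$noiseSd), nrow = H))
  img <- pmin(pmax(img, 0), 1) * (2^spec$bitDepth - 1)
  imageGrid(img, spec$bitDepth)
}

#' Generate a complete synthetic scratch-assay well
#'
#' Convenience wrapper producing matched t0/t24 point patterns and images
#' for one well: a confluent monolayer, a scratch at t0, and a partially
#' closed scratch with a density gradient at t24.
#'
#' @param mono a \code{\link{monolayerSpec}}.
#' @param wound a \code{\link{woundSpec}}.
#' @param render a \code{\link{renderSpec}}.
#' @param seed integer master seed; all internal draws derive from it.
#' @return A list with elements \code{t0} and \code{t24}, each holding
#'   \code{points} (\linkS4class{CellCoords}) and \code{image}
#'   (\linkS4class{ImageGrid}).
#' @export
simulateWell <- function(mono, wound, render = renderSpec(), seed = 1) {
  base <- generateMonolayer(mono)
  # regrow at t24: an independent, denser-at-distance pattern
  p0 <- applyWound(base, wound, "t0", seed = seed + 101L)
  p24 <- applyWound(base, wound, "t24", seed = seed + 202L)
  list(t0 = list(points = p0, image = renderImage(p0, render, seed + 303L)),
       t24 = list(points = p24, image = renderImage(p24, render, seed + 404L)))
}
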