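#' Cell coverage mask from detected coordinates
#'
#' Marks every pixel that has at least one cell centre within its
#' \code{kernel x kernel} neighbourhood (Chebyshev radius
#' \code{(kernel - 1) / 2}): cell coordinates are rasterised onto their
#' pixels and dilated with a uniform square kernel.
#'
#' @param points a \linkS4class{CellCoords} or (x, y) matrix.
#' @param height,width mask size in pixels.
#' @param kernel odd square kernel size in pixels.
#' @return A logical matrix (\code{TRUE} = covered by a cell).
#' @export
densityMask <- function(points, height, width, kernel = 13) {
  assertOddKernel(kernel, "kernel")
  m <- coordsMatrix(points)
  mask <- matrix(0, nrow = height, ncol = width)
  if (nrow(m)) {
    ys <- pmin(pmax(round(m[, 2]), 0), height - 1) + 1L
    xs <- pmin(pmax(round(m[, 1]), 0), width - 1) + 1L
    mask[cbind(ys, xs)] <- 1
    mask <- EBImage::imageData(
      EBImage::dilate(mask, EBImage::makeBrush(kernel, "box")))
  }
  mask > 0
}

#' Segment the wound from a coverage mask
#'
#' The complement of the coverage mask (cell-free space) is cleaned with a
#' morphological opening using a square structuring element, which removes
#' intercellular gaps smaller than the element; connected components of the
#' remaining empty space are labelled and the largest is returned as the
#' wound. Pixels outside the image are treated as covered, so image borders
#' are not mistaken for wound.
#'
#' @param coverage logical matrix from \code{\link{densityMask}}.
#' @param openKernel odd square structuring-element size in pixels.
#' @return A \linkS4class{WoundResult}. When no empty region survives the
#'   opening the area is 0 and the centre is \code{NA}.
#' @export
segmentWound <- function(coverage, openKernel = 35) {
  assertOddKernel(openKernel, "openKernel")
  stopifnot(is.matrix(coverage), length(coverage) > 0)
  h <- nrow(coverage); w <- ncol(coverage)
  r <- (openKernel - 1L) / 2L
  empty <- matrix(0, h + 2L * r, w + 2L * r)  # padding = covered outside
  empty[r + seq_len(h), r + seq_len(w)] <- 1 - (coverage > 0)
  opened <- EBImage::imageData(
    EBImage::opening(empty, EBImage::makeBrush(openKernel, "box")))
  opened <- opened[r + seq_len(h), r + seq_len(w), drop = FALSE]
  lab <- EBImage::imageData(EBImage::bwlabel(opened > 0))
  nlab <- max(lab)
  if (nlab == 0)
    return(new("WoundResult", mask = matrix(FALSE, h, w), area = 0,
               centre = c(NA_real_, NA_real_)))
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  wid <- which.max(sizes)
  mask <- lab == wid
  idx <- which(mask)
  centre <- c(mean((idx - 1L) %/% h), mean((idx - 1L) %% h))
  new("WoundResult", mask = mask, area = sum(mask), centre = centre)
}

#' Distance of each cell to the wound centre
#'
#' Because wounds can close completely by the later timepoint, the centre
#' should be taken from the t0 segmentation.
#'
#' @param points a \linkS4class{CellCoords} or (x, y) matrix.
#' @param centre numeric length-2 (x, y), or a \linkS4class{WoundResult}.
#' @return Numeric vector of Euclidean distances in pixels.
#' @export
distanceToWoundCentre <- function(points, centre) {
  if (is(centre, "WoundResult")) centre <- woundCentre(centre)
  if (length(centre) != 2L || anyNA(centre))
    stop("wound centre is undefined; use the centre of the t0 wound ",
         "segmentation")
  m <- coordsMatrix(points)
  unname(sqrt((m[, 1] - centre[1])^2 + (m[, 2] - centre[2])^2))
}

#' Wound-area fold change between timepoints
#'
#' @param areaT0,areaT24 wound areas in square pixels (scalars or
#'   \linkS4class{WoundResult}s).
#' @return \code{areaT24 / areaT0}; 0 means complete closure.
#' @export
woundFoldChange <- function(areaT0, areaT24) {
  if (is(areaT0, "WoundResult")) areaT0 <- woundArea(areaT0)
  if (is(areaT24, "WoundResult")) areaT24 <- woundArea(areaT24)
  if (!is.finite(areaT0) || areaT0 <= 0)
    stop("undefined baseline: wound area at t0 must be positive")
  areaT24 / areaT0
}
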