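#' @useDynLib scratchTopo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Cell-centre coordinate set
#'
#' Ordered set of cell-centre points in pixel units (0-based, x = column,
#' y = row, origin at the top-left corner), optionally carrying per-point
#' labels and the bounds of the image the points live in.
#'
#' @slot coords numeric matrix with columns \code{x} and \code{y}.
#' @slot labels character vector of per-point labels (length 0 or n).
#' @slot width,height image bounds in pixels (\code{NA} if unknown).
#' @export
setClass("CellCoords",
  representation(coords = "matrix", labels = "character",
                 width = "numeric", height = "numeric"),
  prototype(coords = matrix(numeric(0), ncol = 2,
                            dimnames = list(NULL, c("x", "y"))),
            labels = character(0), width = NA_real_, height = NA_real_))

setValidity("CellCoords", function(object) {
  cc <- object@coords
  if (ncol(cc) != 2L) return("coords must have two columns (x, y)")
  if (nrow(cc) && !all(is.finite(cc))) return("coordinates must be finite")
  if (length(object@labels) && length(object@labels) != nrow(cc))
    return("labels must be empty or one per point")
  w <- object@width; h <- object@height
  if (!is.na(w) && !is.na(h) && nrow(cc)) {
    if (any(cc[, 1] < 0 | cc[, 1] > w - 1) ||
        any(cc[, 2] < 0 | cc[, 2] > h - 1))
      return("coordinates fall outside the stated image bounds")
  }
  TRUE
})

#' Construct a CellCoords object
#'
#' @param x,y numeric vectors of point coordinates (pixels, 0-based).
#' @param labels optional character vector of per-point labels.
#' @param width,height optional image bounds in pixels.
#' @return A \linkS4class{CellCoords} object.
#' @examples
#' cellCoords(c(10, 20), c(5, 15), width = 64, height = 64)
#' @export
cellCoords <- function(x = numeric(0), y = numeric(0), labels = NULL,
                       width = NA_real_, height = NA_real_) {
  stopifnot(length(x) == length(y))
  m <- cbind(x = as.numeric(x), y = as.numeric(y))
  new("CellCoords", coords = m,
      labels = if (is.null(labels)) character(0) else as.character(labels),
      width = as.numeric(width), height = as.numeric(height))
}

#' Microscopy image grid
#'
#' A 2-D intensity array together with its bit depth. Values are raw
#' intensities in \code{[0, 2^bitDepth - 1]} (use \code{\link{normaliseImage}}
#' to map to \code{[0, 1]}).
#'
#' @slot data numeric matrix, rows = image rows (y), columns = x.
#' @slot bitDepth integer bit depth (8--16).
#' @export
setClass("ImageGrid",
  representation(data = "matrix", bitDepth = "integer"),
  prototype(data = matrix(0, 1, 1), bitDepth = 12L))

setValidity("ImageGrid", function(object) {
  b <- object@bitDepth
  if (length(b) != 1L || is.na(b) || b < 1L || b > 32L)
    return("bitDepth must be a single integer in [1, 32]")
  d <- object@data
  if (any(!is.finite(d))) return("image values must be finite")
  if (any(d < 0) || any(d > 2^b - 1))
    return(sprintf("image values must lie in [0, %d]", 2^b - 1))
  TRUE
})

#' Construct an ImageGrid
#' @param data numeric matrix of intensities (rows = y, columns = x).
#' @param bitDepth integer bit depth.
#' @return An \linkS4class{ImageGrid}.
#' @export
imageGrid <- function(data, bitDepth = 12L) {
  new("ImageGrid", data = data, bitDepth = as.integer(bitDepth))
}

#' Wound segmentation result
#'
#' @slot mask logical matrix marking wound pixels (rows = y).
#' @slot area numeric, number of wound pixels.
#' @slot centre numeric length-2 centroid (x, y), \code{NA} when no wound
#'   region survives the morphological opening.
#' @export
setClass("WoundResult",
  representation(mask = "matrix", area = "numeric", centre = "numeric"))

setValidity("WoundResult", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (length(object@centre) != 2L) return("centre must be length 2 (x, y)")
  if (abs(object@area - sum(object@mask)) > 0.5)
    return("area must equal the number of TRUE mask pixels")
  TRUE
})

#' Per-cell topology table
#'
#' Per-cell record of the Voronoi tessellation: polygon side count, cell
#' area, edge/wound exclusion flag, and (after
#' \code{\link{computeCellMetrics}}) local cell density columns.
#'
#' @slot cells data.frame with one row per cell.
#' @slot neighbours list of integer vectors, the Voronoi neighbours (row
#'   indices) of each cell.
#' @export
setClass("TopologyTable",
  representation(cells = "data.frame", neighbours = "list"))

setValidity("TopologyTable", function(object) {
  if (nrow(object@cells) != length(object@neighbours))
    return("one neighbour vector is required per cell")
  need <- c("id", "x", "y", "sideCount", "area", "excluded")
  if (!all(need %in% names(object@cells)))
    return(paste("cells must contain columns:", paste(need, collapse = ", ")))
  TRUE
})

#' Detection-vs-truth matching result
#'
#' @slot predicted \linkS4class{CellCoords} of predictions.
#' @slot truth \linkS4class{CellCoords} of ground-truth annotations.
#' @slot matchedPairs data.frame with columns \code{pred}, \code{truth},
#'   \code{distance} (1-based indices, pixel distance).
#' @slot tp,fp,fn counts of true positives, false positives, false negatives.
#' @export
setClass("DetectionResult",
  representation(predicted = "CellCoords", truth = "CellCoords",
                 matchedPairs = "data.frame", tp = "integer",
                 fp = "integer", fn = "integer"))

setValidity("DetectionResult", function(object) {
  if (object@tp != nrow(object@matchedPairs))
    return("tp must equal the number of matched pairs")
  if (object@tp + object@fp != nCells(object@predicted))
    return("tp + fp must equal the number of predictions")
  if (object@tp + object@fn != nCells(object@truth))
    return("tp + fn must equal the number of truth points")
  TRUE
})

#' Belief-map regression network
#'
#' A U-Net that regresses per-pixel cell-centre belief from a greyscale
#' image. Parameters live in a plain list of weight matrices/bias vectors;
#' \code{spec} records the architecture (see \code{\link{netSpec}}) and
#' \code{history} the per-epoch training/validation loss.
#'
#' @slot spec architecture description, as returned by \code{\link{netSpec}}.
#' @slot params named list of layer parameters.
#' @slot history data.frame with columns \code{epoch}, \code{trainLoss},
#'   \code{valLoss} (empty before training).
#' @slot bestEpoch epoch whose validation loss selected these parameters
#'   (\code{NA} for an untrained network).
#' @export
setClass("ScratchNet",
  representation(spec = "list", params = "list", history = "data.frame",
                 bestEpoch = "numeric"))
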