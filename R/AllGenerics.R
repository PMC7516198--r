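#' @rdname cellCoords
#' @param object a \linkS4class{CellCoords}.
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' @rdname cellCoords
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' @rdname imageGrid
#' @param object an object with image data.
#' @export
setGeneric("gridData", function(object) standardGeneric("gridData"))

#' @rdname imageGrid
#' @export
setGeneric("bitDepth", function(object) standardGeneric("bitDepth"))

#' @rdname segmentWound
#' @param object a \linkS4class{WoundResult}.
#' @export
setGeneric("woundArea", function(object) standardGeneric("woundArea"))

#' @rdname segmentWound
#' @export
setGeneric("woundCentre", function(object) standardGeneric("woundCentre"))

#' @rdname segmentWound
#' @export
setGeneric("woundMask", function(object) standardGeneric("woundMask"))

#' @rdname voronoiTopology
#' @param object a \linkS4class{TopologyTable}.
#' @export
setGeneric("cellData", function(object) standardGeneric("cellData"))

#' @rdname voronoiTopology
#' @export
setGeneric("neighbourIds", function(object) standardGeneric("neighbourIds"))

setMethod("coords", "CellCoords", function(object) object@coords)
setMethod("nCells", "CellCoords", function(object) nrow(object@coords))
setMethod("gridData", "ImageGrid", function(object) object@data)
setMethod("bitDepth", "ImageGrid", function(object) object@bitDepth)
setMethod("woundArea", "WoundResult", function(object) object@area)
setMethod("woundCentre", "WoundResult", function(object) object@centre)
setMethod("woundMask", "WoundResult", function(object) object@mask)
setMethod("cellData", "TopologyTable", function(object) object@cells)
setMethod("neighbourIds", "TopologyTable", function(object) object@neighbours)

#' @export
setMethod("length", "CellCoords", function(x) nrow(x@coords))

#' @export
setMethod("as.data.frame", "CellCoords", function(x, ...) {
  df <- as.data.frame(x@coords)
  if (length(x@labels)) df$label <- x@labels
  df
})

setMethod("show", "CellCoords", function(object) {
  cat(sprintf("CellCoords with %d points", nrow(object@coords)))
  if (!is.na(object@width))
    cat(sprintf(" in a %g x %g image", object@width, object@height))
  cat("\n")
  if (nrow(object@coords)) {
    k <- min(3L, nrow(object@coords))
    print(utils::head(object@coords, k))
    if (nrow(object@coords) > k) cat("...\n")
  }
})

setMethod("show", "ImageGrid", function(object) {
  cat(sprintf("ImageGrid %d x %d, %d-bit, range [%.1f, %.1f]\n",
              ncol(object@data), nrow(object@data), object@bitDepth,
              min(object@data), max(object@data)))
})

setMethod("show", "WoundResult", function(object) {
  cat(sprintf("WoundResult: area %.0f px^2", object@area))
  if (!anyNA(object@centre))
    cat(sprintf(", centre (%.1f, %.1f)", object@centre[1], object@centre[2]))
  else cat(", no wound region detected")
  cat("\n")
})

setMethod("show", "TopologyTable", function(object) {
  inc <- !object@cells$excluded
  cat(sprintf("TopologyTable: %d cells (%d included, %d edge/wound-excluded)\n",
              nrow(object@cells), sum(inc), sum(!inc)))
  if (any(inc))
    cat("side counts: ",
        paste(names(table(object@cells$sideCount[inc])),
              table(object@cells$sideCount[inc]),
              sep = ":", collapse = " "), "\n")
})

setMethod("show", "DetectionResult", function(object) {
  cat(sprintf("DetectionResult: tp=%d fp=%d fn=%d\n",
              object@tp, object@fp, object@fn))
})

setMethod("show", "ScratchNet", function(object) {
  s <- object@spec
  cat(sprintf("ScratchNet: depth %d, %d channels, %dx%d initial kernel\n",
              s$depth, s$channels, s$initialKernel, s$initialKernel))
  if (nrow(object@history))
    cat(sprintf("trained %d epochs, best epoch %d (val loss %.3g)\n",
                nrow(object@history), object@bestEpoch,
                min(object@history$valLoss)))
  else cat("untrained (seeded initialisation)\n")
})
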