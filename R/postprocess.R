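#' Extract cell coordinates from a belief map
#'
#' The map is normalised by its global maximum (an all-zero map stays zero
#' and yields no detections), a 3x3 maximum filter is applied, and pixels
#' equal to their filtered value whose normalised belief exceeds the
#' threshold are retained. Plateaus of equal-valued adjacent maxima are
#' collapsed to their row-major smallest pixel so output is deterministic.
#'
#' @param map numeric matrix of belief values.
#' @param threshold detection threshold in \code{[0, 1]} on the normalised
#'   map. The useful value depends on how cleanly a model separates cells
#'   from background; 0.2 is a reasonable default.
#' @return A \linkS4class{CellCoords} (0-based pixel coordinates) with the
#'   normalised belief values as labels, ordered row-major.
#' @export
extractLocalMaxima <- function(map, threshold = 0.2) {
  stopifnot(is.matrix(map), length(map) > 0)
  assertScalar(threshold, "threshold", 0, 1)
  gmax <- max(map)
  if (gmax <= 0) return(cellCoords(width = ncol(map), height = nrow(map)))
  norm <- map / gmax
  cand <- norm >= maxFilter3(norm) & norm > threshold
  if (!any(cand)) return(cellCoords(width = ncol(map), height = nrow(map)))
  lab <- EBImage::bwlabel(cand)
  idx <- which(cand)
  comp <- lab[idx]
  # row-major order = (y, x) lexicographic on 0-based coordinates
  ord <- order((idx - 1L) %% nrow(map), (idx - 1L) %/% nrow(map))
  idx <- idx[ord]; comp <- comp[ord]
  first <- idx[!duplicated(comp)]
  x <- (first - 1L) %/% nrow(map)
  y <- (first - 1L) %% nrow(map)
  cellCoords(x, y, labels = format(norm[first], digits = 6),
             width = ncol(map), height = nrow(map))
}

#' Match predicted cells to ground-truth annotations
#'
#' Finds the one-to-one assignment between predictions and annotations that
#' maximises the number of pairs within \code{maxDist} pixels and, among
#' those, minimises total distance (optimal assignment on the distance
#' matrix with out-of-gate pairs forbidden). Unmatched predictions count as
#' false positives, unmatched annotations as false negatives.
#'
#' @param predicted,truth \linkS4class{CellCoords} or (x, y) matrices.
#' @param maxDist matching gate in pixels.
#' @param gate \code{"cost"} forbids out-of-gate pairs inside the
#'   assignment (default); \code{"post"} assigns on raw distances and drops
#'   out-of-gate matches afterwards.
#' @param greedy use globally-nearest-pair greedy matching instead of the
#'   optimal assignment (for comparison only).
#' @return A \linkS4class{DetectionResult}.
#' @examples
#' r <- matchDetections(cbind(c(5, 14), 0), cbind(c(0, 6), 0))
#' r@tp
#' @export
matchDetections <- function(predicted, truth, maxDist = 10,
                            gate = c("cost", "post"), greedy = FALSE) {
  gate <- match.arg(gate)
  assertScalar(maxDist, "maxDist", 0)
  pm <- coordsMatrix(predicted)
  tm <- coordsMatrix(truth)
  pc <- if (is(predicted, "CellCoords")) predicted else
    cellCoords(pm[, 1], pm[, 2])
  tc <- if (is(truth, "CellCoords")) truth else cellCoords(tm[, 1], tm[, 2])
  np <- nrow(pm); nt <- nrow(tm)
  pairs <- data.frame(pred = integer(0), truth = integer(0),
                      distance = numeric(0))
  if (np > 0 && nt > 0) {
    D <- sqrt(outer(pm[, 1], tm[, 1], "-")^2 + outer(pm[, 2], tm[, 2], "-")^2)
    if (greedy) {
      Dg <- D
      Dg[Dg > maxDist] <- Inf
      while (any(is.finite(Dg))) {
        k <- arrayInd(which.min(Dg), dim(Dg))
        pairs <- rbind(pairs, data.frame(pred = k[1], truth = k[2],
                                         distance = D[k[1], k[2]]))
        Dg[k[1], ] <- Inf
        Dg[, k[2]] <- Inf
      }
    } else {
      BIG <- maxDist * (np + nt) + 1e6
      C <- D
      if (gate == "cost") C[C > maxDist] <- BIG
      transposed <- np > nt
      if (transposed) C <- t(C)
      asg <- cpp_assignment(C)
      for (i in seq_along(asg)) {
        pi <- if (transposed) asg[i] else i
        ti <- if (transposed) i else asg[i]
        if (asg[i] > 0 && D[pi, ti] <= maxDist)
          pairs <- rbind(pairs, data.frame(pred = pi, truth = ti,
                                           distance = D[pi, ti]))
      }
    }
  }
  pairs <- pairs[order(pairs$pred), , drop = FALSE]
  rownames(pairs) <- NULL
  new("DetectionResult", predicted = pc, truth = tc, matchedPairs = pairs,
      tp = nrow(pairs), fp = np - nrow(pairs), fn = nt - nrow(pairs))
}

#' Precision, recall and F-score of a detection result
#'
#' \code{precision = tp / (tp + fp)}, \code{recall = tp / (tp + fn)} and
#' the F-score is their harmonic mean (0 when both are 0). A result with
#' no predictions and no annotations has no defined score.
#'
#' @param result a \linkS4class{DetectionResult}, or a list/vector with
#'   elements \code{tp}, \code{fp}, \code{fn}.
#' @return Named list with \code{precision}, \code{recall}, \code{fScore}.
#' @export
detectionScores <- function(result) {
  if (is(result, "DetectionResult")) {
    tp <- result@tp; fp <- result@fp; fn <- result@fn
  } else {
    tp <- result[["tp"]]; fp <- result[["fp"]]; fn <- result[["fn"]]
  }
  if (tp + fp + fn == 0)
    stop("undefined score: no predictions and no annotations")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, fScore = f)
}
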