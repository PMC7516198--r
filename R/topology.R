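polygonClassOf <- function(sides) {
  ifelse(is.na(sides), NA_character_,
         ifelse(sides <= 3, "degenerate",
                ifelse(sides >= 9, "9+", as.character(sides))))
}

sidesOfClass <- function(classes) {
  lut <- c(triangle = 3, tetragon = 4, pentagon = 5, hexagon = 6,
           heptagon = 7, octagon = 8, nonagon = 9, "9+" = 9)
  out <- unname(lut[classes])
  num <- suppressWarnings(as.numeric(classes))
  out[is.na(out)] <- num[is.na(out)]
  if (anyNA(out))
    stop("unknown polygon class: ",
         paste(classes[is.na(out)], collapse = ", "))
  out
}

#' Voronoi topology of a cell monolayer
#'
#' Tessellates the image with the Voronoi diagram of the cell centres: each
#' pixel belongs to its nearest centre and ridges equidistant to two
#' centres form the cell sides. A cell's side count equals its number of
#' Voronoi neighbours, counted over ridges of positive length (ridges of
#' zero length arising from four or more co-circular centres create no
#' adjacency). Cells whose region touches the image boundary, or any of
#' whose vertices falls inside the wound mask, are flagged excluded:
#' their polygon is an artefact of the clipping, not of the tissue.
#'
#' @param points a \linkS4class{CellCoords} or (x, y) matrix (at least four
#'   non-collinear points).
#' @param width,height image bounds in pixels; defaults to the bounds
#'   carried by \code{points}.
#' @param wound optional \linkS4class{WoundResult} or logical wound mask
#'   used for exclusion.
#' @return A \linkS4class{TopologyTable}; excluded cells carry \code{NA}
#'   side counts and areas.
#' @export
voronoiTopology <- function(points, width = NA, height = NA, wound = NULL) {
  m <- coordsMatrix(points)
  if (is(points, "CellCoords")) {
    if (is.na(width)) width <- points@width
    if (is.na(height)) height <- points@height
  }
  if (is.na(width) || is.na(height))
    stop("image bounds are required (width/height)")
  if (nrow(m) < 4L)
    stop("degenerate geometry: at least 4 points are required")
  if (qr(cbind(1, m))$rank < 3L)
    stop("degenerate geometry: points are collinear")
  cells <- cpp_voronoi_cells(m, -0.5, -0.5, width - 0.5, height - 0.5, 1e-6)
  wmask <- NULL
  if (!is.null(wound))
    wmask <- if (is(wound, "WoundResult")) woundMask(wound) else wound > 0
  n <- nrow(m)
  nbrs <- lapply(cells, function(cl) as.integer(cl$neighbours))
  # enforce a symmetric neighbour relation (union): the shared ridge exists
  # for both cells even if clipping order made one side's copy borderline
  for (i in seq_len(n)) for (j in nbrs[[i]])
    if (!(i %in% nbrs[[j]])) nbrs[[j]] <- sort(c(nbrs[[j]], i))
  # boundary-touching regions, and sites outside the bounds whose region
  # is clipped away entirely, are not interpretable tissue polygons
  excluded <- vapply(cells, function(cl)
    isTRUE(cl$boundary) || nrow(cl$vertices) < 3L, TRUE)
  if (!is.null(wmask)) {
    h <- nrow(wmask); w <- ncol(wmask)
    for (i in seq_len(n)) {
      if (excluded[i]) next
      v <- cells[[i]]$vertices
      ys <- pmin(pmax(round(v[, 2]), 0), h - 1) + 1L
      xs <- pmin(pmax(round(v[, 1]), 0), w - 1) + 1L
      if (any(wmask[cbind(ys, xs)])) excluded[i] <- TRUE
    }
  }
  sideCount <- lengths(nbrs)
  area <- vapply(cells, function(cl) cl$area, 0)
  df <- data.frame(id = seq_len(n), x = m[, 1], y = m[, 2],
                   sideCount = ifelse(excluded, NA_integer_, sideCount),
                   area = ifelse(excluded, NA_real_, area),
                   excluded = excluded)
  df$polygonClass <- polygonClassOf(df$sideCount)
  new("TopologyTable", cells = df, neighbours = nbrs)
}

#' Relative frequencies of polygon classes
#'
#' Frequencies of the Voronoi polygon classes (tetragon to octagon plus a
#' 9-or-more bin) over non-excluded cells; cells with three or fewer sides
#' are degenerate clipping artefacts and are discarded.
#'
#' @param table a \linkS4class{TopologyTable}.
#' @return Named numeric vector of frequencies summing to 1, names
#'   \code{"4"}, \code{"5"}, \code{"6"}, \code{"7"}, \code{"8"}, \code{"9+"}.
#' @export
polygonDistribution <- function(table) {
  stopifnot(is(table, "TopologyTable"))
  cl <- table@cells$polygonClass
  cl <- cl[!table@cells$excluded & !is.na(cl) & cl != "degenerate"]
  if (!length(cl)) stop("all cells are excluded; no polygon distribution")
  lev <- c("4", "5", "6", "7", "8", "9+")
  tab <- table(factor(cl, levels = lev))
  freq <- as.numeric(tab) / sum(tab)
  names(freq) <- lev
  freq
}

#' Expected shared sides between polygon classes under random mixing
#'
#' Under a random spatial arrangement, a focal cell with \code{s} sides is
#' expected to share \code{s * f} of them with cells of a class having
#' relative frequency \code{f}; e.g. with 36\% hexagons a hexagon shares
#' an expected 6 x 0.36 = 2.16 sides with other hexagons. Deviations of
#' observed co-occurrence from this baseline indicate spatial clustering of
#' shapes.
#'
#' @param freqs named numeric vector of class frequencies; names may be
#'   class words (\code{"tetragon"}..\code{"octagon"}) or side counts
#'   (\code{"4"}..\code{"8"}, \code{"9+"}). A warning is given when the
#'   frequencies are far from summing to 1.
#' @param rows optional class names for the focal rows (defaults to the
#'   names of \code{freqs}).
#' @return Matrix: rows = focal class, columns = neighbour class, entries =
#'   expected shared sides. Each row sums to the focal side count whenever
#'   \code{freqs} sums to 1.
#' @examples
#' expectedCooccurrence(c(hexagon = 0.36, heptagon = 0.20))["hexagon",
#'                                                          "hexagon"]
#' @export
expectedCooccurrence <- function(freqs, rows = names(freqs)) {
  if (is.null(names(freqs))) stop("freqs must be named by polygon class")
  if (any(freqs < 0) || any(freqs > 1))
    stop("frequencies must lie in [0, 1]")
  if (abs(sum(freqs) - 1) > 0.1)
    warning("class frequencies sum to ", signif(sum(freqs), 3),
            "; a full distribution sums to 1")
  sides <- sidesOfClass(rows)
  out <- outer(sides, unname(freqs))
  dimnames(out) <- list(rows, names(freqs))
  out
}

#' Observed co-occurrence of polygon classes
#'
#' For every focal polygon class, tabulates how many of the focal cell's
#' sides are shared with neighbours of each class (one shared side per
#' neighbouring pair), giving per neighbour class a distribution over the
#' number of shared sides, normalised to sum to 1 (row normalisation of the
#' co-occurrence heat maps).
#'
#' @param table a \linkS4class{TopologyTable}. Focal cells are non-excluded
#'   cells all of whose neighbours are themselves classed (edge- or
#'   wound-excluded neighbours have unreliable clipped polygons, so a focal
#'   cell touching one cannot be tabulated completely).
#' @return Named list, one element per focal class present: a matrix with
#'   rows = neighbour class and columns = shared-side count \code{0..max},
#'   each row summing to 1.
#' @export
observedCooccurrence <- function(table) {
  stopifnot(is(table, "TopologyTable"))
  df <- table@cells
  classed <- !df$excluded & !is.na(df$polygonClass) &
    df$polygonClass != "degenerate"
  focal <- which(classed &
                 vapply(table@neighbours,
                        function(nb) all(classed[nb]), TRUE))
  if (!length(focal)) stop("no focal cell has a fully classed neighbourhood")
  lev <- c("4", "5", "6", "7", "8", "9+")
  maxK <- max(df$sideCount[focal])
  counts <- list()
  for (fc in lev) counts[[fc]] <- matrix(0, length(lev), maxK + 1L,
                                         dimnames = list(lev, 0:maxK))
  for (i in focal) {
    fc <- df$polygonClass[i]
    if (!fc %in% lev) next
    nb <- table@neighbours[[i]]
    k <- table(factor(df$polygonClass[nb], levels = lev))
    for (cc in lev)
      counts[[fc]][cc, as.character(k[[cc]])] <-
        counts[[fc]][cc, as.character(k[[cc]])] + 1
  }
  present <- vapply(counts, function(m) sum(m) > 0, TRUE)
  lapply(counts[present], function(m) {
    rs <- rowSums(m)
    m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
    m
  })
}

#' Local cell density
#'
#' LCD of a cell is the inverse of the Euclidean distance to its k-th
#' nearest neighbouring cell. The default rank 36 captures both direct and
#' indirect neighbours; rank 10 probes a shorter length scale.
#'
#' @param points a \linkS4class{CellCoords} or (x, y) matrix with more than
#'   \code{k} points.
#' @param k neighbour rank.
#' @return Numeric vector of LCD values (1/pixels), strictly positive.
#' @export
localCellDensity <- function(points, k = 36) {
  assertScalar(k, "k", 1)
  m <- coordsMatrix(points)
  if (nrow(m) <= k)
    stop("insufficient neighbours: LCD at rank k = ", k, " needs more than ",
         k, " cells, got ", nrow(m))
  1 / cpp_knn_dist(m, as.integer(k))
}

#' Wound-distance-normalised LCD
#'
#' @param lcd numeric vector of LCD values.
#' @param dist numeric vector of distances to the wound centre (pixels).
#' @return \code{lcd / dist}; cells at exactly zero distance are returned
#'   as \code{NA} with a warning.
#' @export
normalisedLCD <- function(lcd, dist) {
  stopifnot(length(lcd) == length(dist))
  out <- lcd / dist
  zero <- dist == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) at zero wound-centre distance excluded")
    out[zero] <- NA_real_
  }
  out
}

#' Correlation between LCD and wound-centre distance
#'
#' During healing, cell spreading is spatially coordinated: density is
#' lowest at the leading edge and rises with distance from the wound, so
#' this correlation is positive at the later timepoint and near zero before
#' wounding takes effect.
#'
#' @param lcd,dist numeric vectors (at least 3 cells, non-constant).
#' @return Pearson correlation coefficient.
#' @export
lcdDistanceCorrelation <- function(lcd, dist) {
  ok <- is.finite(lcd) & is.finite(dist)
  lcd <- lcd[ok]; dist <- dist[ok]
  if (length(lcd) < 3L)
    stop("at least 3 cells are required for a correlation")
  if (stats::sd(lcd) == 0 || stats::sd(dist) == 0)
    stop("undefined correlation: constant input")
  stats::cor(lcd, dist)
}

#' Per-cell density metrics for one image
#'
#' Runs the full per-image topology pipeline: Voronoi tessellation with
#' edge/wound exclusion, LCD at the requested neighbour ranks, distance to
#' the wound centre and the corresponding normalised densities.
#'
#' @inheritParams voronoiTopology
#' @param woundCentre length-2 (x, y) wound centre; for t24 images pass the
#'   t0 centre. \code{NULL} leaves distance columns unset.
#' @param kRanks integer vector of LCD neighbour ranks.
#' @return A \linkS4class{TopologyTable} whose \code{cells} data.frame
#'   gains columns \code{lcd_k<r>}, \code{distToWound} and
#'   \code{nlcd_k<r>} / \code{nlcd_area}.
#' @export
computeCellMetrics <- function(points, width = NA, height = NA, wound = NULL,
                               woundCentre = NULL, kRanks = c(36, 10)) {
  topo <- voronoiTopology(points, width, height, wound)
  df <- topo@cells
  for (r in kRanks)
    df[[paste0("lcd_k", r)]] <- localCellDensity(cbind(df$x, df$y), r)
  if (is.null(woundCentre) && !is.null(wound) &&
      is(wound, "WoundResult") && !anyNA(woundCentre(wound)))
    woundCentre <- woundCentre(wound)
  if (!is.null(woundCentre)) {
    df$distToWound <- distanceToWoundCentre(cbind(df$x, df$y), woundCentre)
    for (r in kRanks)
      df[[paste0("nlcd_k", r)]] <-
        suppressWarnings(normalisedLCD(df[[paste0("lcd_k", r)]],
                                       df$distToWound))
    df$nlcd_area <- suppressWarnings(normalisedLCD(df$area, df$distToWound))
  }
  initialize(topo, cells = df)
}

sevenStats <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop("too few finite values for summary statistics")
  c(median = stats::median(x),
    skewness = e1071::skewness(x, type = 2),
    sd = stats::sd(x),
    q10 = unname(stats::quantile(x, 0.10)),
    q25 = unname(stats::quantile(x, 0.25)),
    q75 = unname(stats::quantile(x, 0.75)),
    q90 = unname(stats::quantile(x, 0.90)))
}

#' Per-well topological signature and fold change
#'
#' For each of the three density measures (LCD at the two neighbour ranks
#' and Voronoi cell area), normalised by distance to the t0 wound centre,
#' computes seven distributional statistics (median, skewness, standard
#' deviation and the 10/25/75/90\% quantiles; linear-interpolation
#' quantiles, adjusted Fisher-Pearson skewness) at each timepoint, and
#' their elementwise fold change t24 / t0.
#'
#' @param t0,t24 \linkS4class{TopologyTable}s from
#'   \code{\link{computeCellMetrics}} with wound distances set.
#' @param kRanks the LCD ranks present in the tables.
#' @return List with named vectors \code{t0}, \code{t24} and
#'   \code{foldChange}; fold-change entries with a zero t0 statistic are
#'   non-finite and flagged with a warning.
#' @export
wellSignature <- function(t0, t24, kRanks = c(36, 10)) {
  stopifnot(is(t0, "TopologyTable"), is(t24, "TopologyTable"))
  measure <- function(df, col) {
    if (!col %in% names(df))
      stop("column ", col, " missing; run computeCellMetrics with a wound ",
           "centre first")
    df[[col]]
  }
  cols <- c(paste0("nlcd_k", kRanks), "nlcd_area")
  sig <- function(tab) {
    df <- tab@cells
    unlist(lapply(cols, function(cl) {
      s <- sevenStats(measure(df, cl))
      names(s) <- paste(cl, names(s), sep = "_")
      s
    }))
  }
  s0 <- sig(t0); s24 <- sig(t24)
  fc <- s24 / s0
  if (any(!is.finite(fc)))
    warning("fold change has non-finite entries (zero t0 statistic): ",
            paste(names(fc)[!is.finite(fc)], collapse = ", "))
  list(t0 = s0, t24 = s24, foldChange = fc)
}

#' Project well signatures onto principal components
#'
#' Standardises each feature (fold changes of different statistics live on
#' different scales) and projects the wells onto the leading principal
#' components.
#'
#' @param signatures numeric matrix, rows = wells, columns = signature
#'   features (e.g. stacked \code{foldChange} vectors).
#' @param nComponents number of components to return.
#' @return List with \code{scores} (wells x components),
#'   \code{explainedVariance} (fractions, non-increasing) and
#'   \code{rotation}. Constant features are dropped with a warning.
#' @export
projectSignatures <- function(signatures, nComponents = 2) {
  X <- as.matrix(signatures)
  if (nrow(X) < 2L || ncol(X) < 2L)
    stop("at least 2 wells and 2 features are required")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant feature(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  nComponents <- min(nComponents, ncol(X), nrow(X) - 1L)
  p <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(nComponents), drop = FALSE],
       explainedVariance = ev[seq_len(nComponents)],
       rotation = p$rotation[, seq_len(nComponents), drop = FALSE])
}
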