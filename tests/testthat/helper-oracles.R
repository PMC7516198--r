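# Brute-force oracles, written independently of the implementation paths
# they check.

# exhaustive per-pixel 3x3 neighbourhood scan
oracleLocalMaxima <- function(map, threshold) {
  gmax <- max(map)
  norm <- if (gmax > 0) map / gmax else map
  h <- nrow(map); w <- ncol(map)
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    nb <- norm[max(1, i - 1):min(h, i + 1), max(1, j - 1):min(w, j + 1)]
    if (norm[i, j] >= max(nb) && norm[i, j] > threshold)
      out <- rbind(out, c(j - 1, i - 1))
  }
  out
}

# exhaustive enumeration of all gated one-to-one assignments; returns the
# maximum match count and, among those, the minimum total distance
oracleAssignment <- function(pred, truth, maxDist) {
  np <- nrow(pred); nt <- nrow(truth)
  D <- sqrt(outer(pred[, 1], truth[, 1], "-")^2 +
            outer(pred[, 2], truth[, 2], "-")^2)
  best <- list(count = -1L, cost = Inf)
  recurse <- function(i, used, count, cost) {
    if (i > np) {
      if (count > best$count ||
          (count == best$count && cost < best$cost))
        best <<- list(count = count, cost = cost)
      return(invisible())
    }
    recurse(i + 1L, used, count, cost)
    for (j in seq_len(nt)) if (!used[j] && D[i, j] <= maxDist) {
      used[j] <- TRUE
      recurse(i + 1L, used, count + 1L, cost + D[i, j])
      used[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, nt), 0L, 0)
  best
}

# half-plane intersection of the bounding rectangle with every bisector
# (no pruning, no edge bookkeeping)
oracleVoronoiCell <- function(i, pts, xmin, ymin, xmax, ymax) {
  px <- c(xmin, xmax, xmax, xmin); py <- c(ymin, ymin, ymax, ymax)
  s <- pts[i, ]
  for (j in seq_len(nrow(pts))) {
    if (j == i || !length(px)) next
    o <- pts[j, ]
    mid <- (s + o) / 2; dir <- o - s
    f <- (px - mid[1]) * dir[1] + (py - mid[2]) * dir[2]
    tol <- 1e-10 * (1 + max(abs(f)))
    keep <- f <= tol
    nx <- numeric(0); ny <- numeric(0)
    M <- length(px)
    for (k in seq_len(M)) {
      kn <- if (k == M) 1L else k + 1L
      if (keep[k]) { nx <- c(nx, px[k]); ny <- c(ny, py[k]) }
      if (keep[k] != keep[kn]) {
        t <- f[k] / (f[k] - f[kn])
        nx <- c(nx, px[k] + t * (px[kn] - px[k]))
        ny <- c(ny, py[k] + t * (py[kn] - py[k]))
      }
    }
    px <- nx; py <- ny
  }
  list(x = px, y = py)
}

# adjacency from the oracle cells: an edge of positive length whose
# midpoint is equidistant to exactly one other site
oracleVoronoiAdjacency <- function(pts, xmin, ymin, xmax, ymax,
                                   eps = 1e-6) {
  n <- nrow(pts)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    cell <- oracleVoronoiCell(i, pts, xmin, ymin, xmax, ymax)
    cx <- cell$x; cy <- cell$y
    M <- length(cx)
    found <- integer(0)
    if (M >= 2) for (k in seq_len(M)) {
      kn <- if (k == M) 1L else k + 1L
      len <- sqrt((cx[kn] - cx[k])^2 + (cy[kn] - cy[k])^2)
      if (len <= eps) next
      mx <- (cx[k] + cx[kn]) / 2; my <- (cy[k] + cy[kn]) / 2
      di <- sqrt((mx - pts[i, 1])^2 + (my - pts[i, 2])^2)
      dall <- sqrt((pts[, 1] - mx)^2 + (pts[, 2] - my)^2)
      j <- setdiff(which(abs(dall - di) < 1e-7 * (1 + di)), i)
      if (length(j) == 1L) found <- c(found, j)
    }
    adj[[i]] <- sort(unique(found))
  }
  adj
}

# per-pixel Chebyshev-radius coverage check
oracleCoverage <- function(pts, height, width, radius = 6) {
  mask <- matrix(FALSE, height, width)
  rx <- round(pts[, 1]); ry <- round(pts[, 2])
  for (yy in seq_len(height)) for (xx in seq_len(width))
    mask[yy, xx] <- any(pmax(abs(rx - (xx - 1)), abs(ry - (yy - 1))) <= radius)
  mask
}

# type-7 (linear interpolation) quantile, written out by hand
oracleQuantile <- function(x, p) {
  xs <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  xs[lo + 1] + (h - lo) * (xs[min(lo + 2, length(x))] - xs[lo + 1])
}

# adjusted Fisher-Pearson skewness, written out by hand
oracleSkewness <- function(x) {
  n <- length(x); m <- mean(x)
  g1 <- mean((x - m)^3) / mean((x - m)^2)^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}
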