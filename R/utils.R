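# Internal helpers shared across modules.

# Evaluate expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards so package functions never disturb the session stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

assertOddKernel <- function(k, what) {
  if (length(k) != 1L || k < 1 || k %% 2 != 1)
    stop(what, " must be a positive odd integer, got ", k)
  invisible(as.integer(k))
}

assertScalar <- function(x, what, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.finite(x) || x < min || x > max)
    stop(what, " must be a single value in [", min, ", ", max, "]")
  invisible(as.numeric(x))
}

coordsMatrix <- function(points) {
  if (is(points, "CellCoords")) return(coords(points))
  m <- as.matrix(points)
  if (ncol(m) != 2L) stop("points must be a CellCoords or an (x, y) matrix")
  colnames(m) <- c("x", "y")
  m
}

# 3x3 maximum filter via 8 shifted comparisons; outside pixels count as -Inf.
maxFilter3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  pad <- matrix(-Inf, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- pmax(out, pad[(2:(h + 1L)) + dy, (2:(w + 1L)) + dx])
  }
  out
}
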