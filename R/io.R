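#' Read a greyscale microscopy image
#'
#' Reads a TIFF or PNG as an \linkS4class{ImageGrid} of raw integer
#' intensities, inferring the container bit depth from the file. Only the
#' first page of a multi-page TIFF is used (with a warning); colour images
#' are rejected.
#'
#' @param path file path (.tif/.tiff/.png).
#' @param bitDepth override the inferred bit depth (e.g. 12-bit data stored
#'   in a 16-bit container).
#' @return An \linkS4class{ImageGrid}.
#' @export
readImageGrid <- function(path, bitDepth = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (length(pages) > 1L)
      warning("multi-page TIFF; using the first page of ", length(pages))
    img <- pages[[1]]
    bits <- attr(img, "bits.per.sample") %||% 16L
    attributes(img) <- list(dim = dim(img))
  } else if (ext == "png") {
    img <- png::readPNG(path)
    bits <- 8L
    if (is.matrix(img)) {
      # png values arrive on [0,1]; recover container integers
      bits <- if (any(abs(img * 255 - round(img * 255)) > 1e-9)) 16L else 8L
      img <- round(img * (2^bits - 1))
    }
  } else stop("unsupported image format: .", ext)
  if (!is.matrix(img))
    stop("colour image (", paste(dim(img), collapse = "x"),
         "); a single-channel greyscale image is required")
  imageGrid(img, bitDepth %||% bits)
}

#' Write an ImageGrid to disk
#'
#' TIFF output uses an 8-bit container for bit depths up to 8 and a 16-bit
#' container otherwise; integer values round-trip exactly.
#'
#' @param image an \linkS4class{ImageGrid}.
#' @param path output path (.tif/.tiff or .png).
#' @export
writeImageGrid <- function(image, path) {
  stopifnot(is(image, "ImageGrid"))
  bits <- if (bitDepth(image) <= 8) 8L else 16L
  scaled <- round(gridData(image)) / (2^bits - 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(scaled, path, bits.per.sample = bits)
  else if (ext == "png") png::writePNG(scaled, path)
  else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Read or write cell coordinates as CSV
#'
#' The on-disk convention is a CSV with header \code{x,y} (optional
#' \code{label}), coordinates 0-based in pixels, x = column, y = row,
#' origin at the top-left.
#'
#' @param path CSV path.
#' @param width,height optional bounds for validation.
#' @return \code{readCoords}: a \linkS4class{CellCoords}.
#' @export
readCoords <- function(path, width = NA_real_, height = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = NA, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df)))
    stop("coordinate CSV must have columns x,y: ", path)
  for (col in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " at data row ", bad[1], " of ", path)
    if (anyNA(v)) stop("missing ", col, " at data row ",
                       which(is.na(v))[1], " of ", path)
    df[[col]] <- v
  }
  if (!is.na(width)) {
    bad <- which(df$x < 0 | df$x > width - 1 | df$y < 0 | df$y > height - 1)
    if (length(bad))
      stop("coordinate out of bounds at data row ", bad[1], " of ", path)
  }
  cellCoords(df$x, df$y, labels = df$label, width = width, height = height)
}

#' @rdname readCoords
#' @param points a \linkS4class{CellCoords} or (x, y) matrix.
#' @export
writeCoords <- function(points, path) {
  df <- if (is(points, "CellCoords")) as.data.frame(points)
        else as.data.frame(coordsMatrix(points))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
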