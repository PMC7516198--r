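#' Pipeline run configuration
#'
#' Collects the fixed constants of the analysis: the detection threshold,
#' the 10-pixel matching gate, the 13-pixel density kernel, the 35-pixel
#' opening kernel, the 2.5-pixel belief kernel and the LCD neighbour ranks
#' (36 and 10). Values can be overridden per call or loaded from a YAML
#' file with \code{\link{loadRunConfig}}.
#'
#' @param bitDepth raw image bit depth.
#' @param detectionThreshold local-maxima threshold in \code{[0, 1]}.
#' @param maxMatchDistance matching gate in pixels.
#' @param densityKernel coverage kernel (odd, pixels).
#' @param openingKernel wound opening kernel (odd, pixels).
#' @param gaussianSigma belief-map kernel sigma (pixels).
#' @param lcdRanks integer vector of LCD neighbour ranks.
#' @param seed integer master seed for the run.
#' @return A validated list of class \code{RunConfig}.
#' @export
runConfig <- function(bitDepth = 12, detectionThreshold = 0.2,
                      maxMatchDistance = 10, densityKernel = 13,
                      openingKernel = 35, gaussianSigma = 2.5,
                      lcdRanks = c(36, 10), seed = 1) {
  assertScalar(bitDepth, "bitDepth", 1, 16)
  assertScalar(detectionThreshold, "detectionThreshold", 0, 1)
  assertScalar(maxMatchDistance, "maxMatchDistance", 0)
  assertOddKernel(densityKernel, "densityKernel")
  assertOddKernel(openingKernel, "openingKernel")
  assertScalar(gaussianSigma, "gaussianSigma", 1e-6)
  stopifnot(length(lcdRanks) >= 1, all(lcdRanks >= 1))
  structure(list(bitDepth = as.integer(bitDepth),
                 detectionThreshold = detectionThreshold,
                 maxMatchDistance = maxMatchDistance,
                 densityKernel = as.integer(densityKernel),
                 openingKernel = as.integer(openingKernel),
                 gaussianSigma = gaussianSigma,
                 lcdRanks = as.integer(lcdRanks),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' @rdname runConfig
#' @param path YAML file whose keys override the defaults.
#' @export
loadRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(runConfig, vals)
}

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Run the detection-to-signature pipeline on paired wells
#'
#' For every well, detects cells in the t0 and t24 images, segments the
#' wound at both timepoints, computes per-cell topology/density metrics
#' (wound distances always against the t0 centre) and the per-well
#' fold-change signature. Per image a coordinates CSV, a wound JSON and a
#' topology CSV are written; per well a signature CSV; and a run manifest
#' JSON records the configuration hash, seed and per-well status. A failing
#' well is reported in the manifest without aborting the batch.
#'
#' @param model a trained \linkS4class{ScratchNet}.
#' @param wells named list; each element is a list with elements \code{t0}
#'   and \code{t24}, each an \linkS4class{ImageGrid}, a numeric matrix of
#'   raw intensities, or a file path.
#' @param outDir output directory (created if needed).
#' @param config a \code{\link{runConfig}}.
#' @return Invisibly, the manifest as a list.
#' @export
runPipeline <- function(model, wells, outDir, config = runConfig()) {
  stopifnot(is(model, "ScratchNet"), inherits(config, "RunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(names(wells)) && length(wells))
    names(wells) <- sprintf("well%02d", seq_along(wells))
  loadImage <- function(x) {
    if (is.character(x)) x <- readImageGrid(x, bitDepth = config$bitDepth)
    if (is(x, "ImageGrid")) normaliseImage(x)
    else normaliseImage(x, config$bitDepth)
  }
  manifest <- list(configHash = configHash(config), seed = config$seed,
                   rVersion = as.character(getRversion()),
                   wells = list())
  if (!length(wells)) warning("no wells supplied; writing empty manifest")
  for (wn in names(wells)) {
    status <- tryCatch({
      imgs <- lapply(wells[[wn]][c("t0", "t24")], loadImage)
      det <- lapply(imgs, function(im) {
        extractLocalMaxima(predictBeliefMap(model, im),
                           config$detectionThreshold)
      })
      for (tp in c("t0", "t24"))
        writeCoords(det[[tp]], file.path(outDir,
                                         paste0(wn, "_", tp, "_coords.csv")))
      wounds <- lapply(det, function(d) {
        segmentWound(densityMask(d, nrow(imgs$t0), ncol(imgs$t0),
                                 config$densityKernel),
                     config$openingKernel)
      })
      woundJson <- list(
        t0 = list(area_px2 = woundArea(wounds$t0),
                  centre = as.list(woundCentre(wounds$t0))),
        t24 = list(area_px2 = woundArea(wounds$t24),
                   centre = as.list(woundCentre(wounds$t24))),
        foldChange = tryCatch(woundFoldChange(wounds$t0, wounds$t24),
                              error = function(e) NA_real_))
      jsonlite::write_json(woundJson,
                           file.path(outDir, paste0(wn, "_wound.json")),
                           auto_unbox = TRUE, digits = NA, na = "null")
      centre0 <- woundCentre(wounds$t0)
      tabs <- list()
      for (tp in c("t0", "t24")) {
        tabs[[tp]] <- computeCellMetrics(
          det[[tp]], ncol(imgs[[tp]]), nrow(imgs[[tp]]),
          wound = wounds[[tp]], woundCentre = centre0,
          kRanks = config$lcdRanks)
        utils::write.csv(cellData(tabs[[tp]]),
                         file.path(outDir,
                                   paste0(wn, "_", tp, "_topology.csv")),
                         row.names = FALSE, quote = FALSE)
      }
      sig <- wellSignature(tabs$t0, tabs$t24, kRanks = config$lcdRanks)
      utils::write.csv(
        data.frame(feature = names(sig$foldChange), t0 = sig$t0,
                   t24 = sig$t24, foldChange = sig$foldChange,
                   row.names = NULL),
        file.path(outDir, paste0(wn, "_signature.csv")),
        row.names = FALSE, quote = FALSE)
      "ok"
    }, error = function(e) paste("error:", conditionMessage(e)))
    manifest$wells[[wn]] <- status
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
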