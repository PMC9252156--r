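# Frame-stack persistence: multi-page 32-bit float TIFF holding the frames
# rescaled to [0, 1], plus a JSON sidecar (<base>.json) with times, grid
# spacing, q-map parameters and the affine scale needed to reconstruct the
# original values.  Plain-text sidecar + TIFF keeps the format inspectable
# and language-neutral.

stackScale <- function(a) {
  lo <- min(a); hi <- max(a)
  if (hi == lo) hi <- lo + 1
  list(offset = lo, range = hi - lo)
}

writeStack <- function(a, base, meta) {
  sc <- stackScale(a)
  frames <- lapply(seq_len(dim(a)[3]),
                   function(f) (a[, , f] - sc$offset) / sc$range)
  tiff::writeTIFF(frames, paste0(base, ".tif"), bits.per.sample = 32L)
  meta$scale <- sc
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(base)
}

readStack <- function(base) {
  tifPath <- paste0(base, ".tif")
  jsonPath <- paste0(base, ".json")
  for (p in c(tifPath, jsonPath))
    if (!file.exists(p))
      stop("missing file '", p, "' (expected a <base>.tif/.json pair)",
           call. = FALSE)
  meta <- tryCatch(jsonlite::read_json(jsonPath, simplifyVector = TRUE),
                   error = function(e)
                     stop("corrupt sidecar '", jsonPath, "': ",
                          conditionMessage(e), call. = FALSE))
  frames <- tryCatch(tiff::readTIFF(tifPath, all = TRUE),
                     error = function(e)
                       stop("corrupt TIFF '", tifPath, "': ",
                            conditionMessage(e), call. = FALSE))
  if (!is.list(frames)) frames <- list(frames)
  if (is.null(meta$scale) || length(meta$times) != length(frames))
    stop("sidecar '", jsonPath, "' does not match the TIFF stack ",
         "(missing scale or times/frame-count mismatch)", call. = FALSE)
  a <- array(0, c(dim(frames[[1]])[1:2], length(frames)))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (length(dim(fr)) == 3L) fr <- fr[, , 1]
    a[, , f] <- fr * meta$scale$range + meta$scale$offset
  }
  list(a = a, meta = meta)
}

#' Write a field series to a TIFF + JSON pair
#'
#' Frames are stored as a multi-page 32-bit float TIFF scaled to \[0, 1\];
#' `<base>.json` records times, `dx` and the scale for lossless (float32)
#' reconstruction.
#'
#' @param series a [FieldSeries]
#' @param base output path without extension
#' @return `base`, invisibly
#' @export
writeFieldSeries <- function(series, base) {
  stopifnot(is(series, "FieldSeries"))
  writeStack(series@u, base,
             list(type = "FieldSeries", times = series@times,
                  dx = series@dx))
}

#' Read a field series written by [writeFieldSeries()]
#' @param base path without extension
#' @return a [FieldSeries]
#' @export
readFieldSeries <- function(base) {
  s <- readStack(base)
  if (!identical(s$meta$type, "FieldSeries"))
    stop("'", base, "' does not hold a FieldSeries (type = ",
         s$meta$type %||% "missing", ")", call. = FALSE)
  new("FieldSeries", u = s$a, times = as.numeric(s$meta$times),
      dx = as.numeric(s$meta$dx))
}

#' Write a speckle series to a TIFF + JSON pair
#' @param series a [SpeckleSeries]
#' @param base output path without extension
#' @return `base`, invisibly
#' @export
writeSpeckleSeries <- function(series, base) {
  stopifnot(is(series, "SpeckleSeries"))
  writeStack(series@I, base,
             list(type = "SpeckleSeries", times = series@times,
                  qUnit = series@qUnit, qmapMax = max(series@qmap),
                  gridN = nrow(series@qmap)))
}

#' Read a speckle series written by [writeSpeckleSeries()]
#'
#' The simulation-unit q-map is reconstructed from the stored grid size;
#' physical q-maps are rebuilt when a [Geometry] is supplied.
#'
#' @param base path without extension
#' @param geom optional [Geometry]
#' @return a [SpeckleSeries]
#' @export
readSpeckleSeries <- function(base, geom = NULL) {
  s <- readStack(base)
  if (!identical(s$meta$type, "SpeckleSeries"))
    stop("'", base, "' does not hold a SpeckleSeries", call. = FALSE)
  n <- dim(s$a)[1]
  a <- s$a
  a[a < 0] <- 0  # float32 round-off can graze below zero
  if (!is.null(geom)) {
    qmap <- qMapPhysical(geom, dim(a)[1:2]); unit <- "nm^-1"
  } else if (identical(s$meta$qUnit, "simulation")) {
    qmap <- qMapSimulation(n); unit <- "simulation"
  } else {
    stop("stored series has a physical q-map; supply `geom` to rebuild it",
         call. = FALSE)
  }
  new("SpeckleSeries", I = a, times = as.numeric(s$meta$times),
      qmap = qmap, qUnit = unit)
}

#' Import detector frames from a plain multi-page TIFF stack
#'
#' Accepts externally produced stacks that carry no sidecar: intensities are
#' taken as stored, timestamps are synthesized as 0, 1, 2, ... frames (with
#' a warning), and the q-map comes from the supplied [Geometry] (or
#' simulation units when omitted).
#'
#' @param path TIFF file
#' @param geom optional [Geometry]
#' @return a [SpeckleSeries]
#' @export
readFrameStack <- function(path, geom = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                     error = function(e)
                       stop("cannot read TIFF '", path, "': ",
                            conditionMessage(e), call. = FALSE))
  if (!is.list(frames)) frames <- list(frames)
  n <- dim(frames[[1]])[1:2]
  a <- array(0, c(n, length(frames)))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (length(dim(fr)) == 3L) fr <- fr[, , 1]
    a[, , f] <- fr
  }
  a[a < 0] <- 0
  warning("no timestamps in plain TIFF stack; using uniform frame times ",
          "0..", length(frames) - 1L)
  if (is.null(geom)) {
    qmap <- qMapSimulation(n[1]); unit <- "simulation"
  } else {
    qmap <- qMapPhysical(geom, n); unit <- "nm^-1"
  }
  new("SpeckleSeries", I = a, times = seq_along(frames) - 1,
      qmap = qmap, qUnit = unit)
}

#' Export a TTC matrix as CSV
#'
#' Writes `G` with times as header metadata comment lines, readable back by
#' [readTTC()].
#'
#' @param ttc a [TwoTimeCorrelation]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeTTC <- function(ttc, path) {
  stopifnot(is(ttc, "TwoTimeCorrelation"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# qCenter=%.12g qHalfwidth=%.12g ringSize=%d estimator=%s",
            ttc@qCenter, ttc@qHalfwidth, ttc@ringSize, ttc@estimator),
    paste0("# times=", paste(ttc@times, collapse = ","))), con)
  utils::write.table(ttc@G, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a TTC written by [writeTTC()]
#' @param path CSV path
#' @return a [TwoTimeCorrelation]
#' @export
readTTC <- function(path) {
  hdr <- readLines(path, n = 2L)
  kv <- strsplit(sub("^# ", "", hdr[1]), " ")[[1]]
  meta <- stats::setNames(
    lapply(kv, function(x) strsplit(x, "=")[[1]][2]),
    vapply(kv, function(x) strsplit(x, "=")[[1]][1], character(1)))
  times <- as.numeric(strsplit(sub("^# times=", "", hdr[2]), ",")[[1]])
  G <- as.matrix(utils::read.table(path, sep = ",", skip = 2L))
  dimnames(G) <- NULL
  new("TwoTimeCorrelation", G = (G + t(G)) / 2, times = times,
      qCenter = as.numeric(meta$qCenter),
      qHalfwidth = as.numeric(meta$qHalfwidth),
      ringSize = as.integer(meta$ringSize),
      validFrames = rep(TRUE, length(times)),
      estimator = as.character(meta$estimator))
}

#' Export a feature report
#'
#' Writes one CSV row per detected feature point and a JSON summary with
#' the scalar statistics.
#'
#' @param report a [FeatureReport]
#' @param base output path without extension (writes `<base>.csv` and
#'   `<base>.json`)
#' @return `base`, invisibly
#' @export
writeFeatureReport <- function(report, base) {
  stopifnot(is(report, "FeatureReport"))
  rows <- data.frame(feature = character(), tAge = numeric(),
                     value = numeric())
  if (length(report@tailTimes))
    rows <- rbind(rows, data.frame(feature = "tail",
                                   tAge = report@tailTimes, value = NA))
  if (nrow(report@xiPoints))
    rows <- rbind(rows, data.frame(feature = "xi",
                                   tAge = report@xiPoints$tAge,
                                   value = report@xiPoints$xi))
  utils::write.csv(rows, paste0(base, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(
    nTails = length(report@tailTimes),
    squareStrength = report@squareStrength,
    modulation = report@modulation[c("mean", "sd", "nonUniform",
                                     "insufficientPeaks")],
    powerLaw = report@powerLaw
  ), paste0(base, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
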