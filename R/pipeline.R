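#' Validate a pipeline configuration
#'
#' A configuration is a nested list (or a YAML file) with blocks:
#' \describe{
#'   \item{source}{exactly one of `kind = "ch"` (phase-field: `gridN`, `dt`,
#'     `quench`, `nSteps`, `sampleEvery`, optional `binarize`,
#'     `dilatePixelsPerFrame`), `kind = "particles"` (`scenario`, optional
#'     `overrides`, `nFrames`), or `kind = "frames"` (`path` to a TIFF
#'     stack, optional `geometry` block with `photonEnergy`,
#'     `detectorDistance`, `pixelSize`, `beamCenter`).}
#'   \item{scattering}{optional `noiseFraction` (default 0).}
#'   \item{analysis}{`qMode` `"early_peak"` (default) or `"fixed"` with
#'     `qCenter`; `qHalfwidthPixels` ring half width in q-pixel spacings
#'     (default 1.5); `estimator`; `prominence`; optional `tSplit`;
#'     `earlyFrames`.}
#'   \item{output}{logical `writeFields`, `writeSpeckle` (defaults FALSE).}
#' }
#' Scalars omitted fall back to the documented defaults.  Stage seeds are
#' derived deterministically from the master seed.
#'
#' @param config nested list or path to a YAML file
#' @return the normalized config list
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$source) ||
      is.null(config$source$kind))
    stop("config must contain a source block with a 'kind'", call. = FALSE)
  kind <- config$source$kind
  if (!kind %in% c("ch", "particles", "frames"))
    stop("source$kind must be one of ch, particles, frames", call. = FALSE)
  if (kind == "frames" && is.null(config$source$path))
    stop("source$kind = 'frames' requires source$path", call. = FALSE)
  if (kind == "particles" && is.null(config$source$scenario))
    stop("source$kind = 'particles' requires source$scenario", call. = FALSE)
  config$scattering <- config$scattering %||% list()
  config$scattering$noiseFraction <- config$scattering$noiseFraction %||% 0
  a <- config$analysis %||% list()
  a$qMode <- a$qMode %||% "early_peak"
  if (!a$qMode %in% c("early_peak", "fixed"))
    stop("analysis$qMode must be 'early_peak' or 'fixed'", call. = FALSE)
  if (a$qMode == "fixed" && is.null(a$qCenter))
    stop("analysis$qMode = 'fixed' requires analysis$qCenter", call. = FALSE)
  a$qHalfwidthPixels <- a$qHalfwidthPixels %||% 1.5
  a$estimator <- a$estimator %||% "pearson"
  a$prominence <- a$prominence %||% 0.05
  a$earlyFrames <- a$earlyFrames %||% 5L
  config$analysis <- a
  config$output <- config$output %||% list()
  config$output$writeFields <- isTRUE(config$output$writeFields)
  config$output$writeSpeckle <- isTRUE(config$output$writeSpeckle)
  config
}

#' Run the full simulation-to-features pipeline
#'
#' Executes source -> speckle synthesis -> ring selection -> two-time
#' correlation -> feature extraction, writes all artefacts plus a
#' provenance log (config, derived seeds, package version) to `outDir`, and
#' returns the in-memory objects.  Two runs with the same config and seed
#' produce identical artefacts.
#'
#' @param config pipeline configuration (list or YAML path); see
#'   [validatePipelineConfig()]
#' @param outDir output directory (created if missing)
#' @param seed master seed; stage seeds are derived from it
#' @return invisible list with `fields`, `speckle`, `ring`, `ttc`,
#'   `features`
#' @export
runPipeline <- function(config, outDir, seed = 1L) {
  config <- validatePipelineConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(source = seed, noise = seed + 1000L)
  src <- config$source
  fields <- NULL
  if (src$kind == "ch") {
    params <- CHParams(gridN = src$gridN %||% 256L, dt = src$dt %||% 0.05,
                       quench = src$quench %||% 0.7,
                       meanU = src$meanU %||% 0,
                       initNoiseAmp = src$initNoiseAmp %||% 0.01,
                       seed = seeds$source)
    fields <- evolve(params, src$nSteps %||% 2000L,
                     src$sampleEvery %||% 20L)
    if (isTRUE(src$binarize)) fields <- binarize(fields)
    dil <- src$dilatePixelsPerFrame %||% 0L
    if (dil > 0L) {
      if (!isTRUE(src$binarize))
        stop("dilatePixelsPerFrame requires source$binarize = TRUE",
             call. = FALSE)
      fields <- dilateDomains(fields, dil)
    }
    speckle <- speckleSeries(fields)
  } else if (src$kind == "particles") {
    ov <- src$overrides %||% list()
    ov$seed <- seeds$source
    spec <- buildScenario(src$scenario, ov)
    fields <- simulateParticles(spec, src$nFrames %||%
                                  spec@recommendedFrames)
    speckle <- speckleSeries(fields)
  } else {
    geom <- NULL
    if (!is.null(src$geometry)) {
      g <- src$geometry
      geom <- geometry(g$photonEnergy, g$detectorDistance, g$pixelSize,
                       g$beamCenter)
    }
    speckle <- readFrameStack(src$path, geom)
  }
  if (config$scattering$noiseFraction > 0)
    speckle <- addNoise(speckle, config$scattering$noiseFraction,
                        seeds$noise)
  a <- config$analysis
  qc <- if (a$qMode == "fixed") a$qCenter
  else selectAnalysisQ(speckle, a$earlyFrames)
  dq <- a$qHalfwidthPixels * 2 * pi / nrow(speckle@qmap)
  if (speckle@qUnit != "simulation")
    dq <- a$qHalfwidthPixels * diff(range(speckle@qmap)) /
      nrow(speckle@qmap)
  ring <- makeQRing(speckle, qc, dq)
  ttc <- computeTTC(speckle, ring, a$estimator)
  features <- featureReport(ttc, prominence = a$prominence,
                            tSplit = a$tSplit %||% NA)
  if (config$output$writeFields && !is.null(fields))
    writeFieldSeries(fields, file.path(outDir, "fields"))
  if (config$output$writeSpeckle)
    writeSpeckleSeries(speckle, file.path(outDir, "speckle"))
  writeTTC(ttc, file.path(outDir, "ttc.csv"))
  cp <- contrastProfile(ttc, 1L)
  utils::write.csv(data.frame(tAge = cp@ageTimes, contrast = cp@values),
                   file.path(outDir, "contrast.csv"), row.names = FALSE)
  writeFeatureReport(features, file.path(outDir, "features"))
  jsonlite::write_json(sanitizeForJSON(list(
    package = "xpcsre",
    version = as.character(utils::packageVersion("xpcsre")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    masterSeed = seed, stageSeeds = seeds, config = config,
    qCenter = qc, ringPixels = length(ring@pixels)
  )), file.path(outDir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(fields = fields, speckle = speckle, ring = ring,
                 ttc = ttc, features = features))
}

# Provenance logs hold arbitrary config trees; S4 objects (schedules,
# motion specs) are flattened to named slot lists for JSON.
sanitizeForJSON <- function(x) {
  if (isS4(x)) {
    sl <- methods::slotNames(class(x))
    out <- lapply(stats::setNames(sl, sl), function(s)
      sanitizeForJSON(methods::slot(x, s)))
    c(list(.class = as.character(class(x))), out)
  } else if (is.list(x)) {
    lapply(x, sanitizeForJSON)
  } else x
}

#' Generate a seeded on-disk fixture dataset
#'
#' Writes a small, fully reproducible field-series dataset for tests and
#' demos.  `tiny` fixtures are 64^2 with 60 frames (seconds to build);
#' `standard` mirrors the preset defaults (256^2).
#'
#' @param name one of `"linear_growth"`, `"two_step"`, `"brownian"`,
#'   `"ch_binary"`
#' @param size `"tiny"` or `"standard"`
#' @param dir output directory
#' @param seed RNG seed
#' @return the written base path, invisibly
#' @export
generateFixture <- function(name, size = c("tiny", "standard"), dir = ".",
                            seed = 101L) {
  size <- match.arg(size)
  known <- c("linear_growth", "two_step", "brownian", "ch_binary")
  if (!name %in% known)
    stop("unknown fixture '", name, "'; valid names: ",
         paste(known, collapse = ", "), call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tiny <- size == "tiny"
  fs <- switch(name,
    linear_growth = {
      ov <- list(seed = seed)
      if (tiny) ov <- c(ov, list(
        boxN = 64L, nParticles = 8L,
        radiusSchedules = schedule(c(0, 60), c(1, 6)),
        recommendedFrames = 60L))
      simulateParticles(buildScenario("linear_growth", ov))
    },
    two_step = {
      ov <- list(seed = seed)
      if (tiny) ov <- c(ov, list(
        boxN = 64L, nParticles = 8L,
        radiusSchedules = schedule(c(0, 30, 60), c(1, 6, 1.5)),
        recommendedFrames = 60L))
      simulateParticles(buildScenario("two_step_growth_dissolution", ov))
    },
    brownian = {
      ov <- list(seed = seed)
      if (tiny) ov <- c(ov, list(boxN = 64L, nParticles = 15L,
                                 radiusMean = 3,
                                 recommendedFrames = 60L))
      simulateParticles(buildScenario("brownian", ov))
    },
    ch_binary = {
      p <- CHParams(gridN = if (tiny) 64L else 256L, seed = seed)
      steps <- if (tiny) 590L else 2000L
      binarize(evolve(p, steps, max(1L, steps %/% 59L)))
    })
  base <- file.path(dir, paste0(name, "_", size))
  writeFieldSeries(fs, base)
  invisible(base)
}
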