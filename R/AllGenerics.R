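#' Number of frames in a series
#' @param x a [FieldSeries], [SpeckleSeries] or [Ensemble]
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame times of a series
#' @param x a [FieldSeries], [SpeckleSeries], [Ensemble] or
#'   [TwoTimeCorrelation]
#' @return numeric vector of times
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Extract a single frame
#' @param x a series object
#' @param i frame index (1-based)
#' @return a [ConcentrationField] or [SpeckleFrame]
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' Map a field or every frame of a series to a binary two-phase field
#'
#' Pixels with `u > 0` map to +1 (dense phase) and `u <= 0` to -1 (dilute
#' phase; the measure-zero tie at exactly 0 is assigned to the dilute side).
#' Idempotent; frame times are preserved.
#'
#' @param x a [ConcentrationField] or [FieldSeries]
#' @return object of the same class with values in \{-1, +1\}
#' @export
setGeneric("binarize", function(x) standardGeneric("binarize"))

#' @export
setMethod("nFrames", "FieldSeries", function(x) dim(x@u)[3])
#' @export
setMethod("nFrames", "SpeckleSeries", function(x) dim(x@I)[3])
#' @export
setMethod("nFrames", "Ensemble", function(x) dim(x@positions)[3])

#' @export
setMethod("frameTimes", "FieldSeries", function(x) x@times)
#' @export
setMethod("frameTimes", "SpeckleSeries", function(x) x@times)
#' @export
setMethod("frameTimes", "Ensemble", function(x) x@times)
#' @export
setMethod("frameTimes", "TwoTimeCorrelation", function(x) x@times)

#' @export
setMethod("getFrame", "FieldSeries", function(x, i) {
  stopifnot(i >= 1L, i <= nFrames(x))
  new("ConcentrationField", values = x@u[, , i], time = x@times[i], dx = x@dx)
})
#' @export
setMethod("getFrame", "SpeckleSeries", function(x, i) {
  stopifnot(i >= 1L, i <= nFrames(x))
  new("SpeckleFrame", intensity = x@I[, , i], time = x@times[i])
})

#' @describeIn fieldValues accessors for field containers
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' Raw values of a concentration field
#' @param x a [ConcentrationField]
#' @return numeric matrix
#' @name fieldValues
#' @export
setMethod("fieldValues", "ConcentrationField", function(x) x@values)

#' TTC matrix accessor
#' @param x a [TwoTimeCorrelation]
#' @return the `G(t1, t2)` matrix
#' @export
setGeneric("ttcMatrix", function(x) standardGeneric("ttcMatrix"))
#' @export
setMethod("ttcMatrix", "TwoTimeCorrelation", function(x) x@G)

#' Ring size accessor
#' @param x a [QRing] or [TwoTimeCorrelation]
#' @return integer number of pixels in the ring
#' @export
setGeneric("ringSize", function(x) standardGeneric("ringSize"))
#' @export
setMethod("ringSize", "QRing", function(x) length(x@pixels))
#' @export
setMethod("ringSize", "TwoTimeCorrelation", function(x) x@ringSize)

setMethod("show", "CHParams", function(object) {
  cat(sprintf(
    "CHParams: %d^2 grid, dx=%g, dt=%g, quench a=%g, mobility=%s, u0=%g\n",
    object@gridN, object@dx, object@dt, object@quench, object@mobilityModel,
    object@meanU))
  invisible(NULL)
})

setMethod("show", "ConcentrationField", function(object) {
  v <- object@values
  cat(sprintf("ConcentrationField %dx%d at t=%g, range [%.3g, %.3g]\n",
              nrow(v), ncol(v), object@time, min(v), max(v)))
  invisible(NULL)
})

setMethod("show", "FieldSeries", function(object) {
  d <- dim(object@u)
  cat(sprintf("FieldSeries: %d frames of %dx%d, t in [%g, %g], dx=%g\n",
              d[3], d[1], d[2], object@times[1], object@times[d[3]],
              object@dx))
  invisible(NULL)
})

setMethod("show", "SpeckleSeries", function(object) {
  d <- dim(object@I)
  cat(sprintf("SpeckleSeries: %d frames of %dx%d, q up to %.4g (%s)\n",
              d[3], d[1], d[2], max(object@qmap), object@qUnit))
  invisible(NULL)
})

setMethod("show", "QRing", function(object) {
  cat(sprintf("QRing: q = %.4g +/- %.4g, %d pixels\n",
              object@qCenter, object@qHalfwidth, length(object@pixels)))
  invisible(NULL)
})

setMethod("show", "TwoTimeCorrelation", function(object) {
  n <- length(object@times)
  cat(sprintf(
    "TwoTimeCorrelation: %d x %d frames, q = %.4g +/- %.4g, ring %d px (%s)\n",
    n, n, object@qCenter, object@qHalfwidth, object@ringSize,
    object@estimator))
  if (!all(object@validFrames))
    cat(sprintf("  %d frame(s) with zero ring variance masked to 0\n",
                sum(!object@validFrames)))
  invisible(NULL)
})

setMethod("show", "Ensemble", function(object) {
  d <- dim(object@positions)
  cat(sprintf("Ensemble: %d particles, %d frames, box %d^2\n",
              d[1], d[3], object@spec@boxN))
  invisible(NULL)
})

setMethod("show", "FeatureReport", function(object) {
  cat("FeatureReport\n")
  cat(sprintf("  tails at t_age: %s\n",
              if (length(object@tailTimes))
                paste(signif(object@tailTimes, 4), collapse = ", ")
              else "none"))
  if (nrow(object@xiPoints))
    cat(sprintf("  xi points: %d (xi in [%.3g, %.3g])\n",
                nrow(object@xiPoints), min(object@xiPoints$xi),
                max(object@xiPoints$xi)))
  if (!is.na(object@squareStrength))
    cat(sprintf("  square strength: %.4f\n", object@squareStrength))
  if (length(object@powerLaw))
    cat(sprintf("  power-law exponent: %.4f +/- %.4f\n",
                object@powerLaw$exponent, object@powerLaw$stderr))
  invisible(NULL)
})
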