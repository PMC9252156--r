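#' @import methods
NULL

# ---------------------------------------------------------------------------
# Phase-field containers
# ---------------------------------------------------------------------------

#' Parameters of the rescaled 2D Cahn-Hilliard model
#'
#' Holds the grid, timestep and physics parameters for the rescaled
#' Cahn-Hilliard equation with temperature-jump quench,
#' \deqn{\partial u/\partial t = \nabla\cdot[m(u)\,\nabla(u^3 - a u -
#'   \kappa \nabla^2 u)],}
#' where `u` is the rescaled local concentration (dense phase positive,
#' dilute negative), `a = (Tc - T)/Tc` is the dimensionless quench depth and
#' `kappa` the interface-energy coefficient.  The mobility `m(u)` is either
#' constant (classical spinodal decomposition) or suppressed above a gelation
#' threshold (`m(u) = mMin` for `u >= uGel`), modelling slow dynamics of the
#' dense gelled phase.
#'
#' @slot gridN integer, pixels per side (powers of two recommended).
#' @slot dx numeric, grid spacing in rescaled units.
#' @slot dt numeric, timestep in rescaled time units.
#' @slot quench numeric in \[0, 1\], dimensionless quench depth
#'   `a = (Tc - T)/Tc`; 0 means at/above the critical temperature.
#' @slot mobilityModel `"constant"` or `"gel"`.
#' @slot uGel numeric, gel threshold concentration (gel model only).
#' @slot mMin numeric in (0, 1\], reduced mobility above the threshold.
#' @slot meanU numeric in (-1, 1), mean rescaled concentration.
#' @slot initNoiseAmp numeric >= 0, amplitude of initial uniform fluctuations.
#' @slot gradientCoeff numeric > 0, interface coefficient kappa.
#' @slot seed integer RNG seed.
#' @export
setClass("CHParams", representation(
  gridN = "integer", dx = "numeric", dt = "numeric", quench = "numeric",
  mobilityModel = "character", uGel = "numeric", mMin = "numeric",
  meanU = "numeric", initNoiseAmp = "numeric", gradientCoeff = "numeric",
  seed = "integer"
))

setValidity("CHParams", function(object) {
  msg <- character()
  if (length(object@gridN) != 1L || object@gridN < 16L)
    msg <- c(msg, "gridN must be a single integer >= 16")
  if (object@dx <= 0) msg <- c(msg, "dx must be positive")
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@quench < 0 || object@quench > 1)
    msg <- c(msg, "quench must lie in [0, 1]")
  if (!object@mobilityModel %in% c("constant", "gel"))
    msg <- c(msg, "mobilityModel must be 'constant' or 'gel'")
  if (object@mMin <= 0 || object@mMin > 1)
    msg <- c(msg, "mMin must lie in (0, 1]")
  if (abs(object@meanU) >= 1) msg <- c(msg, "meanU must satisfy |meanU| < 1")
  if (object@initNoiseAmp < 0) msg <- c(msg, "initNoiseAmp must be >= 0")
  if (object@gradientCoeff <= 0) msg <- c(msg, "gradientCoeff must be positive")
  if (length(msg)) msg else TRUE
})

#' A single 2D rescaled concentration field
#'
#' Real-space snapshot `u(r, t)` of the rescaled concentration.  Values lie
#' in \[-1, 1\] for phase-field evolution (small numerical overshoot is
#' tolerated); binarized fields take values in \{-1, +1\}.  Positive values
#' are the dense phase, negative the dilute phase.
#'
#' @slot values numeric matrix of rescaled concentration.
#' @slot time numeric, simulation time (rescaled/arbitrary units).
#' @slot dx numeric, grid spacing.
#' @export
setClass("ConcentrationField", representation(
  values = "matrix", time = "numeric", dx = "numeric"
))

setValidity("ConcentrationField", function(object) {
  if (!all(is.finite(object@values))) return("values must be finite")
  if (object@dx <= 0) return("dx must be positive")
  TRUE
})

#' A time-ordered stack of concentration fields
#'
#' Frames are stored as an `N x N x nFrames` array with strictly increasing,
#' uniformly spaced times.
#'
#' @slot u numeric 3D array, `N x N x nFrames`.
#' @slot times numeric vector of frame times.
#' @slot dx numeric grid spacing shared by all frames.
#' @export
setClass("FieldSeries", representation(
  u = "array", times = "numeric", dx = "numeric"
))

setValidity("FieldSeries", function(object) {
  d <- dim(object@u)
  if (length(d) != 3L) return("u must be a 3D array (N x N x frames)")
  if (d[3] != length(object@times))
    return("length(times) must equal the number of frames")
  if (length(object@times) > 1L) {
    dt <- diff(object@times)
    if (any(dt <= 0)) return("times must be strictly increasing")
    if (max(dt) - min(dt) > 1e-8 * max(abs(dt)))
      return("times must be uniformly spaced")
  }
  TRUE
})

# ---------------------------------------------------------------------------
# Particle-based heuristic model
# ---------------------------------------------------------------------------

#' Piecewise-linear schedule of a scalar quantity over time
#'
#' Used for particle radii, ellipse axis ratios, interior/background
#' concentrations and random-walk step sizes.  Evaluation outside the control
#' points clamps to the nearest endpoint.
#'
#' @slot times numeric, strictly increasing control times.
#' @slot values numeric, schedule values at the control times.
#' @export
setClass("Schedule", representation(times = "numeric", values = "numeric"))

setValidity("Schedule", function(object) {
  if (length(object@times) < 1L) return("schedule needs >= 1 control point")
  if (length(object@times) != length(object@values))
    return("times and values must have equal length")
  if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
  TRUE
})

#' Motion model of the domains
#'
#' Either static, or an uncorrelated Gaussian random walk with per-frame RMS
#' step `stepSigma` per axis (pixels); the step size may itself follow a
#' [Schedule] to emulate size- or viscosity-dependent slowdown.
#'
#' @slot kind `"static"` or `"random_walk"`.
#' @slot stepSigma a [Schedule] of the per-frame step (pixels).
#' @export
setClass("MotionSpec", representation(kind = "character",
                                      stepSigma = "Schedule"))

setValidity("MotionSpec", function(object) {
  if (!object@kind %in% c("static", "random_walk"))
    return("kind must be 'static' or 'random_walk'")
  if (any(object@stepSigma@values < 0)) return("stepSigma must be >= 0")
  if (object@kind == "static" && any(object@stepSigma@values != 0))
    return("static motion requires stepSigma == 0")
  TRUE
})

#' Specification of a particle (domain) ensemble
#'
#' The reverse-engineering heuristic model: phase domains as 2D
#' disks/ellipses with programmable radius, shape, concentration and motion
#' schedules, rasterized onto a periodic concentration map.  The interior
#' concentration defaults to -1 (dilute droplets) and the background to +1
#' (dense phase).  Multiple radius schedules with population fractions
#' support Ostwald-ripening-like scenarios where one fraction grows while
#' another dissolves.
#'
#' @slot nParticles integer >= 1.
#' @slot boxN integer >= 32, grid pixels per side.
#' @slot radiusSchedules list of [Schedule] for the mean radius trajectory,
#'   one per population.
#' @slot fractions numeric population fractions (sums to 1).
#' @slot radiusSpread numeric >= 0, SD of the per-particle radius offset
#'   (normal, truncated so initial radii stay positive).
#' @slot shapeRatio [Schedule] of ellipse minor/major axis ratio in (0, 1\];
#'   shapes preserve the area of the equivalent disk.
#' @slot motion [MotionSpec].
#' @slot uIn,uOut [Schedule]s of interior and background concentration.
#' @slot minSeparation numeric >= 0, minimum centre separation at placement.
#' @slot seed integer RNG seed.
#' @slot recommendedFrames integer, window the schedules were designed for.
#' @export
setClass("ParticleEnsembleSpec", representation(
  nParticles = "integer", boxN = "integer",
  radiusSchedules = "list", fractions = "numeric", radiusSpread = "numeric",
  shapeRatio = "Schedule", motion = "MotionSpec",
  uIn = "Schedule", uOut = "Schedule",
  minSeparation = "numeric", seed = "integer", recommendedFrames = "integer"
))

setValidity("ParticleEnsembleSpec", function(object) {
  msg <- character()
  if (object@nParticles < 1L) msg <- c(msg, "nParticles must be >= 1")
  if (object@boxN < 32L) msg <- c(msg, "boxN must be >= 32")
  if (!length(object@radiusSchedules) ||
      !all(vapply(object@radiusSchedules, is, TRUE, "Schedule")))
    msg <- c(msg, "radiusSchedules must be a non-empty list of Schedule")
  if (length(object@fractions) != length(object@radiusSchedules) ||
      abs(sum(object@fractions) - 1) > 1e-8 || any(object@fractions <= 0))
    msg <- c(msg, "fractions must be positive and sum to 1, one per schedule")
  if (object@radiusSpread < 0) msg <- c(msg, "radiusSpread must be >= 0")
  if (any(object@shapeRatio@values <= 0 | object@shapeRatio@values > 1))
    msg <- c(msg, "shapeRatio values must lie in (0, 1]")
  if (object@minSeparation < 0) msg <- c(msg, "minSeparation must be >= 0")
  # u_in and u_out must never coincide over the common schedule support
  tt <- sort(unique(c(object@uIn@times, object@uOut@times)))
  vin <- scheduleAt(object@uIn, tt); vout <- scheduleAt(object@uOut, tt)
  if (any(abs(vin - vout) < 1e-12))
    msg <- c(msg, "uIn must differ from uOut at all times")
  if (length(msg)) msg else TRUE
})

#' A realized particle ensemble
#'
#' Positions are a `nParticles x 2 x nFrames` trajectory array wrapped into
#' `[0, boxN)` (periodic box); radius offsets, population assignment and
#' ellipse orientations are fixed per particle at placement.
#'
#' @slot positions numeric 3D array `nParticles x 2 x nFrames`.
#' @slot radiusOffsets numeric per-particle offsets added to the schedule.
#' @slot population integer schedule index per particle.
#' @slot orientations numeric per-particle ellipse orientation (radians).
#' @slot times numeric frame times.
#' @slot spec the generating [ParticleEnsembleSpec].
#' @export
setClass("Ensemble", representation(
  positions = "array", radiusOffsets = "numeric", population = "integer",
  orientations = "numeric", times = "numeric", spec = "ParticleEnsembleSpec"
))

setValidity("Ensemble", function(object) {
  d <- dim(object@positions)
  if (length(d) != 3L || d[2] != 2L)
    return("positions must be nParticles x 2 x nFrames")
  if (d[3] != length(object@times))
    return("trajectory length must equal the frame count")
  if (any(object@positions < 0) ||
      any(object@positions >= object@spec@boxN))
    return("positions must be wrapped into [0, boxN)")
  TRUE
})

# ---------------------------------------------------------------------------
# Reciprocal space
# ---------------------------------------------------------------------------

#' Experimental scattering geometry
#'
#' Converts detector pixels to momentum transfer.  The wavelength is derived
#' from the photon energy via `lambda[A] = 12.398419843 / E[keV]`.
#'
#' @slot photonEnergy numeric, keV.
#' @slot wavelength numeric, Angstrom (derived).
#' @slot detectorDistance numeric, metres.
#' @slot pixelSize numeric, micrometres.
#' @slot beamCenter numeric length-2, (row, col) in pixels.
#' @export
setClass("Geometry", representation(
  photonEnergy = "numeric", wavelength = "numeric",
  detectorDistance = "numeric", pixelSize = "numeric", beamCenter = "numeric"
))

setValidity("Geometry", function(object) {
  msg <- character()
  if (object@photonEnergy <= 0) msg <- c(msg, "photonEnergy must be positive")
  if (object@detectorDistance <= 0)
    msg <- c(msg, "detectorDistance must be positive")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (length(object@beamCenter) != 2L || any(object@beamCenter <= 0))
    msg <- c(msg, "beamCenter must be two positive pixel coordinates")
  lam <- 12.398419843 / object@photonEnergy
  if (abs(object@wavelength - lam) > 1e-6 * lam)
    msg <- c(msg, "wavelength inconsistent with photonEnergy")
  if (length(msg)) msg else TRUE
})

#' A single speckle frame (reciprocal space)
#'
#' Non-negative intensity map with the zero-frequency pixel shifted to the
#' centre.  For real input fields the intensity is point symmetric,
#' `I(q) = I(-q)`, up to floating-point error.
#'
#' @slot intensity numeric matrix, >= 0, zero-frequency centred.
#' @slot time numeric frame time.
#' @export
setClass("SpeckleFrame", representation(intensity = "matrix",
                                        time = "numeric"))

setValidity("SpeckleFrame", function(object) {
  if (any(object@intensity < 0)) return("intensity must be non-negative")
  TRUE
})

#' A time series of speckle frames with a shared q-map
#'
#' Frames are `N x N x nFrames`; the q-map gives per-pixel `|q|`, either in
#' simulation units `2*pi*k/(N*dx)` or in physical nm^-1 when built from a
#' [Geometry].
#'
#' @slot I numeric 3D array of intensities.
#' @slot times numeric frame times.
#' @slot qmap numeric matrix of per-pixel `|q|`.
#' @slot qUnit `"simulation"` or `"nm^-1"`.
#' @export
setClass("SpeckleSeries", representation(
  I = "array", times = "numeric", qmap = "matrix", qUnit = "character"
))

setValidity("SpeckleSeries", function(object) {
  d <- dim(object@I)
  if (length(d) != 3L) return("I must be a 3D array")
  if (!all(d[1:2] == dim(object@qmap)))
    return("qmap dimensions must match the frames")
  if (d[3] != length(object@times))
    return("length(times) must equal the number of frames")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (min(object@I) < 0) return("intensities must be non-negative")
  TRUE
})

#' A ring of detector pixels at fixed momentum transfer
#'
#' Pixel set `{p : |q_p - qCenter| <= qHalfwidth}`, excluding the
#' zero-frequency pixel.  Averaging the intensity over such a ring is the
#' pixel average entering the two-time correlation function.
#'
#' @slot qCenter,qHalfwidth numeric ring centre and half width.
#' @slot pixels integer linear indices into a frame matrix.
#' @export
setClass("QRing", representation(qCenter = "numeric", qHalfwidth = "numeric",
                                 pixels = "integer"))

setValidity("QRing", function(object) {
  if (!length(object@pixels)) return("ring pixel set must be non-empty")
  if (object@qHalfwidth <= 0) return("qHalfwidth must be positive")
  TRUE
})

# ---------------------------------------------------------------------------
# Correlation containers
# ---------------------------------------------------------------------------

#' Two-time correlation function at one q-ring
#'
#' `G(t1, t2)` is the normalized covariance (Pearson) of the ring-pixel
#' intensities between frames `t1` and `t2`: symmetric, unit diagonal for
#' frames with non-zero ring variance, values in \[-1, 1\].  Frames with zero
#' ring variance are flagged in `validFrames` and their rows/columns set to 0.
#'
#' @slot G numeric symmetric matrix, `nFrames x nFrames`.
#' @slot times numeric frame times.
#' @slot qCenter,qHalfwidth numeric ring parameters.
#' @slot ringSize integer number of ring pixels.
#' @slot validFrames logical per-frame variance flag.
#' @slot estimator `"pearson"` or `"intensity"` (unnormalized
#'   `<I1 I2>/(<I1><I2>)` variant).
#' @export
setClass("TwoTimeCorrelation", representation(
  G = "matrix", times = "numeric", qCenter = "numeric",
  qHalfwidth = "numeric", ringSize = "integer", validFrames = "logical",
  estimator = "character"
))

setValidity("TwoTimeCorrelation", function(object) {
  n <- length(object@times)
  if (!all(dim(object@G) == c(n, n))) return("G must be nFrames x nFrames")
  if (length(object@validFrames) != n)
    return("validFrames must have one entry per frame")
  if (max(abs(object@G - t(object@G))) > 1e-8) return("G must be symmetric")
  TRUE
})

#' Contrast profile along the TTC diagonal
#'
#' Values of `G` at a fixed off-diagonal offset (default one frame), indexed
#' by the age time `t_age = (t1 + t2)/2` of each pair.  Oscillations of this
#' profile are the tail/modulation signature of domain growth.
#'
#' @slot values numeric, `G(k, k + offset)`.
#' @slot ageTimes numeric pair midpoints.
#' @slot offset integer frame offset.
#' @export
setClass("ContrastProfile", representation(values = "numeric",
                                           ageTimes = "numeric",
                                           offset = "integer"))

setValidity("ContrastProfile", function(object) {
  if (length(object@values) != length(object@ageTimes))
    return("values and ageTimes must have equal length")
  TRUE
})

#' One-time correlation cut through a TTC
#'
#' `g2`-like correlation versus delay tau at fixed age time, either a single
#' row of the TTC or an average over a diagonal band of ages.
#'
#' @slot values numeric correlation values.
#' @slot tau numeric delays (>= 0).
#' @slot tAge numeric age time of the cut.
#' @slot mode `"row"` or `"diagonal_band"`.
#' @export
setClass("G2Cut", representation(values = "numeric", tau = "numeric",
                                 tAge = "numeric", mode = "character"))

setValidity("G2Cut", function(object) {
  if (length(object@values) != length(object@tau))
    return("values and tau must have equal length")
  if (any(object@tau < 0)) return("tau must be >= 0")
  TRUE
})

#' Report of detected TTC features
#'
#' @slot tailTimes numeric age times of detected contrast maxima.
#' @slot xiPoints data.frame with columns `tAge`, `xi` from the
#'   integer-multiple rule.
#' @slot squareStrength numeric (NA when not computed).
#' @slot modulation list with mean/sd spacing and non-uniformity flag.
#' @slot powerLaw list with exponent, prefactor, stderr (empty if not fit).
#' @export
setClass("FeatureReport", representation(
  tailTimes = "numeric", xiPoints = "data.frame", squareStrength = "numeric",
  modulation = "list", powerLaw = "list"
))
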