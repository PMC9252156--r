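#' Build a piecewise-linear schedule
#'
#' @param times strictly increasing control times (frame units)
#' @param values schedule values at the control times
#' @return a [Schedule]
#' @examples
#' s <- schedule(c(0, 100), c(2, 12))
#' scheduleAt(s, 50)  # 7
#' @export
schedule <- function(times, values) {
  if (length(times) == 1L && length(values) == 1L)
    return(new("Schedule", times = as.numeric(times),
               values = as.numeric(values)))
  new("Schedule", times = as.numeric(times), values = as.numeric(values))
}

#' Constant schedule shorthand
#' @param value the constant value
#' @return a single-point [Schedule]
#' @export
constantSchedule <- function(value) schedule(0, value)

#' Evaluate a schedule
#'
#' Linear interpolation between control points; evaluation outside the
#' control range clamps to the nearest endpoint.
#'
#' @param sched a [Schedule]
#' @param t times at which to evaluate
#' @return numeric values
#' @export
scheduleAt <- function(sched, t) {
  stopifnot(is(sched, "Schedule"))
  if (length(sched@times) == 1L)
    return(rep(sched@values, length(t)))
  stats::approx(sched@times, sched@values, xout = t, rule = 2)$y
}

#' Motion specification
#'
#' @param kind `"static"` or `"random_walk"`
#' @param stepSigma per-frame RMS displacement per axis in pixels; a scalar
#'   or a [Schedule] over frame time
#' @return a [MotionSpec]
#' @export
motionSpec <- function(kind = c("static", "random_walk"), stepSigma = 0) {
  kind <- match.arg(kind)
  if (!is(stepSigma, "Schedule")) stepSigma <- constantSchedule(stepSigma)
  new("MotionSpec", kind = kind, stepSigma = stepSigma)
}

#' Specify a particle (domain) ensemble
#'
#' Domains are modelled as disks (or area-preserving ellipses) on a periodic
#' 2D map, with the concentration constant inside (`uIn`, default -1, the
#' dilute phase) and outside (`uOut`, default +1, the dense phase).  All
#' kinetic content lives in the schedules: radii, axis ratio, concentrations
#' and the random-walk step are piecewise-linear functions of frame time.
#'
#' @param nParticles number of domains (>= 1)
#' @param boxN grid pixels per side (>= 32)
#' @param radiusMean initial mean radius in pixels; used to build a constant
#'   radius schedule when `radiusSchedules` is not given
#' @param radiusSpread SD (pixels) of the per-particle normal radius offset,
#'   truncated so initial radii stay positive
#' @param radiusSchedules a [Schedule] or list of Schedules (one per
#'   population) for the mean radius trajectory
#' @param fractions population fractions, one per radius schedule
#' @param shapeRatio ellipse minor/major axis ratio in (0, 1\]; scalar or
#'   [Schedule]; 1 = disk; ellipses preserve the equivalent-disk area
#' @param motion a [MotionSpec]
#' @param uIn,uOut interior/background concentration; scalar or [Schedule]
#' @param minSeparation minimum centre separation at placement (pixels)
#' @param recommendedFrames window length the schedules were designed for
#' @param seed RNG seed
#' @return a validated [ParticleEnsembleSpec]
#' @export
particleEnsembleSpec <- function(nParticles = 200L, boxN = 512L,
                                 radiusMean = 4, radiusSpread = 0,
                                 radiusSchedules = NULL, fractions = NULL,
                                 shapeRatio = 1,
                                 motion = motionSpec("static"),
                                 uIn = -1, uOut = 1, minSeparation = 0,
                                 recommendedFrames = 100L, seed = 1L) {
  if (is.null(radiusSchedules))
    radiusSchedules <- list(constantSchedule(radiusMean))
  if (is(radiusSchedules, "Schedule"))
    radiusSchedules <- list(radiusSchedules)
  if (is.null(fractions))
    fractions <- rep(1 / length(radiusSchedules), length(radiusSchedules))
  if (!is(shapeRatio, "Schedule")) shapeRatio <- constantSchedule(shapeRatio)
  if (!is(uIn, "Schedule")) uIn <- constantSchedule(uIn)
  if (!is(uOut, "Schedule")) uOut <- constantSchedule(uOut)
  new("ParticleEnsembleSpec", nParticles = as.integer(nParticles),
      boxN = as.integer(boxN), radiusSchedules = radiusSchedules,
      fractions = fractions, radiusSpread = radiusSpread,
      shapeRatio = shapeRatio, motion = motion, uIn = uIn, uOut = uOut,
      minSeparation = minSeparation, seed = as.integer(seed),
      recommendedFrames = as.integer(recommendedFrames))
}

#' Displace particle positions by one random-walk step
#'
#' Each particle moves by an i.i.d. Gaussian displacement with SD
#' `stepSigma` per axis and is wrapped back into the periodic box, so the
#' ensemble mean-squared displacement grows as `2 * n * stepSigma^2` with
#' step count (2D).  Uses the current RNG stream.
#'
#' @param positions `n x 2` matrix of positions in `[0, boxN)`
#' @param stepSigma per-axis step SD (pixels)
#' @param boxN box side (pixels)
#' @return displaced, wrapped `n x 2` matrix
#' @export
stepPositions <- function(positions, stepSigma, boxN) {
  if (stepSigma == 0) return(positions)
  n <- nrow(positions)
  wrapPeriodic(positions + matrix(stats::rnorm(2 * n, 0, stepSigma), n, 2),
               boxN)
}

#' Realize an ensemble: placement, size draw and full trajectories
#'
#' Positions are drawn uniformly in the box (with rejection sampling when a
#' minimum separation is requested, up to 1e5 attempts); per-particle radius
#' offsets are normal with SD `radiusSpread`, redrawn until the initial
#' radius is positive; ellipse orientations are uniform and fixed for life.
#' Random-walk trajectories are then integrated over `nFrames` frames with
#' the (possibly time-dependent) step size.  Fully seeded and reproducible.
#'
#' @param spec a [ParticleEnsembleSpec]
#' @param nFrames number of frames to simulate
#' @return an [Ensemble]
#' @export
sampleEnsemble <- function(spec, nFrames) {
  stopifnot(is(spec, "ParticleEnsembleSpec"))
  validObject(spec)
  checkThat(nFrames >= 1L, "nFrames", "must be >= 1")
  n <- spec@nParticles; bn <- spec@boxN
  withSeed(spec@seed, {
    if (spec@minSeparation > 0) {
      pos <- matrix(NA_real_, n, 2)
      placed <- 0L
      attempts <- 0L
      while (placed < n) {
        attempts <- attempts + 1L
        if (attempts > 1e5L)
          stop("could not place ", n, " particles with minSeparation = ",
               spec@minSeparation, " in ", attempts - 1L,
               " attempts; reduce the separation or the count",
               call. = FALSE)
        cand <- stats::runif(2, 0, bn)
        ok <- TRUE
        if (placed > 0L) {
          d <- abs(pos[seq_len(placed), , drop = FALSE] -
                     matrix(cand, placed, 2, byrow = TRUE))
          d <- pmin(d, bn - d)  # toroidal metric
          ok <- all(sqrt(rowSums(d^2)) >= spec@minSeparation)
        }
        if (ok) { placed <- placed + 1L; pos[placed, ] <- cand }
      }
    } else {
      pos <- matrix(stats::runif(2 * n, 0, bn), n, 2)
    }
    population <- rep(seq_along(spec@fractions),
                      times = diff(round(cumsum(c(0, spec@fractions)) * n)))
    length(population) <- n
    population[is.na(population)] <- length(spec@fractions)
    offsets <- numeric(n)
    if (spec@radiusSpread > 0) {
      r0 <- vapply(population, function(p)
        scheduleAt(spec@radiusSchedules[[p]], 0), numeric(1))
      for (i in seq_len(n)) {
        repeat {
          o <- stats::rnorm(1, 0, spec@radiusSpread)
          if (r0[i] + o > 0) break
        }
        offsets[i] <- o
      }
    }
    orient <- stats::runif(n, 0, pi)
    times <- seq_len(nFrames) - 1
    traj <- array(0, c(n, 2, nFrames))
    traj[, , 1] <- pos
    if (spec@motion@kind == "random_walk" && nFrames > 1L) {
      for (f in 2:nFrames) {
        sig <- scheduleAt(spec@motion@stepSigma, times[f - 1])
        pos <- stepPositions(pos, sig, bn)
        traj[, , f] <- pos
      }
    } else if (nFrames > 1L) {
      for (f in 2:nFrames) traj[, , f] <- pos
    }
    new("Ensemble", positions = traj, radiusOffsets = offsets,
        population = as.integer(population), orientations = orient,
        times = times, spec = spec)
  })
}

# Per-particle radii at time t (>= 0, schedule + fixed offset).
ensembleRadii <- function(ensemble, t) {
  spec <- ensemble@spec
  base <- vapply(spec@radiusSchedules, scheduleAt, numeric(1), t = t)
  pmax(0, base[ensemble@population] + ensemble@radiusOffsets)
}

#' Mean domain diameter of an ensemble at a time
#'
#' Ground-truth characteristic length of the heuristic model, for comparing
#' against sizes recovered from the two-time correlation tails.
#'
#' @param ensemble an [Ensemble]
#' @param t time (frame units)
#' @return mean diameter `2 * mean(radius)` in pixels
#' @export
meanDiameter <- function(ensemble, t) 2 * mean(ensembleRadii(ensemble, t))

#' Rasterize one frame of an ensemble to a concentration field
#'
#' Every pixel whose centre falls inside any (periodically wrapped) particle
#' ellipse receives the interior concentration `uIn(t)`; all others receive
#' the background `uOut(t)`.  Overlaps are resolved as a union: the interior
#' value wins regardless of how many particles cover a pixel.  An axis ratio
#' `rho < 1` turns the disk of radius `r` into an ellipse with semi-axes
#' `r/sqrt(rho)` and `r*sqrt(rho)` (equal area), rotated to the particle's
#' fixed orientation.
#'
#' @param ensemble an [Ensemble]
#' @param frame frame index (1-based)
#' @return a [ConcentrationField] with `dx = 1`
#' @export
rasterize <- function(ensemble, frame) {
  stopifnot(is(ensemble, "Ensemble"))
  checkThat(frame >= 1L && frame <= dim(ensemble@positions)[3], "frame",
            "outside the simulated trajectory")
  spec <- ensemble@spec
  bn <- spec@boxN
  t <- ensemble@times[frame]
  uin <- scheduleAt(spec@uIn, t)
  uout <- scheduleAt(spec@uOut, t)
  rho <- scheduleAt(spec@shapeRatio, t)
  radii <- ensembleRadii(ensemble, t)
  inside <- matrix(FALSE, bn, bn)
  a <- radii / sqrt(rho)   # semi-major
  b <- radii * sqrt(rho)   # semi-minor
  for (i in seq_len(spec@nParticles)) {
    if (radii[i] <= 0) next
    cx <- ensemble@positions[i, 1, frame]
    cy <- ensemble@positions[i, 2, frame]
    hw <- ceiling(a[i])
    if (2 * hw + 1 >= bn) {
      # particle comparable to the box: evaluate all pixels with toroidal
      # offsets (duplicate wrapped indices would clash in the fast path)
      dxs <- (0:(bn - 1)) - cx; dxs <- dxs - bn * round(dxs / bn)
      dys <- (0:(bn - 1)) - cy; dys <- dys - bn * round(dys / bn)
      co <- cos(ensemble@orientations[i]); si <- sin(ensemble@orientations[i])
      dxm <- matrix(dxs, bn, bn)
      dym <- matrix(dys, bn, bn, byrow = TRUE)
      xr <- co * dxm + si * dym
      yr <- -si * dxm + co * dym
      inside <- inside | ((xr / a[i])^2 + (yr / b[i])^2 <= 1)
      next
    }
    xs <- floor(cx - hw):ceiling(cx + hw)
    ys <- floor(cy - hw):ceiling(cy + hw)
    # pixel centres at integer coordinates 0..bn-1, offsets before wrapping
    dxs <- xs - cx
    dys <- ys - cy
    dxm <- matrix(dxs, length(dxs), length(dys))
    dym <- matrix(dys, length(dxs), length(dys), byrow = TRUE)
    if (rho == 1) {
      # disks need no rotation (and stay exact at boundary pixels)
      hit <- dxm^2 + dym^2 <= radii[i]^2
    } else {
      co <- cos(ensemble@orientations[i])
      si <- sin(ensemble@orientations[i])
      xr <- co * dxm + si * dym
      yr <- -si * dxm + co * dym
      hit <- (xr / a[i])^2 + (yr / b[i])^2 <= 1
    }
    if (!any(hit)) next
    ix <- wrapPeriodic(xs, bn) + 1L
    iy <- wrapPeriodic(ys, bn) + 1L
    inside[ix, iy] <- inside[ix, iy] | hit
  }
  vals <- matrix(uout, bn, bn)
  vals[inside] <- uin
  new("ConcentrationField", values = vals, time = t, dx = 1)
}

#' Simulate a particle scenario to a field series
#'
#' Realizes the ensemble ([sampleEnsemble()]) and rasterizes every frame,
#' producing a [FieldSeries] directly usable by the speckle-synthesis and
#' correlation machinery.  `(spec, seed, nFrames)` fully determine the
#' output.
#'
#' @param spec a [ParticleEnsembleSpec]
#' @param nFrames number of frames (defaults to the spec's recommended
#'   window)
#' @return a [FieldSeries]
#' @examples
#' spec <- buildScenario("brownian", list(nParticles = 20L, boxN = 64L))
#' fs <- simulateParticles(spec, nFrames = 10)
#' @export
simulateParticles <- function(spec, nFrames = spec@recommendedFrames) {
  ens <- sampleEnsemble(spec, nFrames)
  fieldSeriesFromEnsemble(ens)
}

#' Rasterize a whole ensemble trajectory
#' @param ensemble an [Ensemble]
#' @return a [FieldSeries]
#' @export
fieldSeriesFromEnsemble <- function(ensemble) {
  nf <- dim(ensemble@positions)[3]
  bn <- ensemble@spec@boxN
  u <- array(0, c(bn, bn, nf))
  for (f in seq_len(nf)) u[, , f] <- rasterize(ensemble, f)@values
  new("FieldSeries", u = u, times = ensemble@times, dx = 1)
}
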