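#' Preset particle scenarios
#'
#' Fully parameterized specifications of the canonical reverse-engineering
#' scenarios, each isolating one dynamical sub-phenomenon of phase
#' separation and the TTC feature it produces:
#'
#' * `linear_growth` -- identical disks growing at constant speed (radius
#'   2 to 14 px over 120 frames): periodic modulation and tail features.
#' * `growth_distribution` -- same growth with a per-particle size spread
#'   (knob `spreadFraction`, default 0.2 of the run-mean radius): smears the
#'   modulation.
#' * `nonlinear_growth` -- accelerating growth: modulation spacing shrinks
#'   with age.
#' * `two_step_growth_dissolution` -- growth for 60 frames then dissolution;
#'   knob `rateRatio` = (growth rate)/(|dissolution rate|), `Inf` meaning no
#'   dissolution.  Controls the square-feature strength.
#' * `shape_change` -- fixed-size domains whose axis ratio drops rapidly from
#'   1 to 0.5 mid-run (area preserved): a square feature without any size
#'   kinetics.
#' * `concentration_ramp` -- fixed domains whose interior concentration
#'   deepens from -0.2 to -1: contrast-driven square feature.
#' * `brownian` -- 200 fixed-radius (6 px) disks in Brownian motion (knob
#'   via `motion` override); the equilibrium reference.
#' * `brownian_plus_growth` -- linear growth plus a fixed Brownian step, for
#'   the growth/motion dominance crossover.
#' * `early_stage_llps` -- simultaneous growth and strongly decreasing
#'   Brownian step, emulating the early stage of liquid-liquid phase
#'   separation where thermal motion dominates and then dies away.
#'
#' All presets use a 256^2 periodic box; scenario boxes, counts and schedule
#' values are the package's reference choices (the phenomena are generic).
#' Overrides are applied last and change only the named fields; scenario
#' knobs (`rateRatio`, `spreadFraction`) may also be overridden.
#'
#' @param name one of the scenario names above
#' @param overrides named list of [particleEnsembleSpec()] arguments (or
#'   scenario knobs) to replace
#' @return a [ParticleEnsembleSpec]
#' @examples
#' spec <- buildScenario("linear_growth", list(nParticles = 10L))
#' @export
buildScenario <- function(name, overrides = list()) {
  presets <- c("linear_growth", "growth_distribution", "nonlinear_growth",
               "two_step_growth_dissolution", "shape_change",
               "concentration_ramp", "brownian", "brownian_plus_growth",
               "early_stage_llps")
  if (!is.character(name) || length(name) != 1L || !name %in% presets)
    stop("unknown scenario '", paste(name, collapse = ","),
         "'; valid presets: ", paste(presets, collapse = ", "),
         call. = FALSE)
  # brownian_plus_growth fixes the walk step so motion is visible but does
  # not decorrelate the whole window (relaxation ~ 2/(q^2 sigma^2) ~ 50
  # frames at the default analysis ring)
  knobs <- list(rateRatio = 4, spreadFraction = 0.2,
                growthRate = 0.1, stepSigma = 0.25)
  for (k in intersect(names(overrides), names(knobs))) {
    knobs[[k]] <- overrides[[k]]
    overrides[[k]] <- NULL
  }
  growth <- schedule(c(0, 120), c(2, 14))
  args <- switch(name,
    linear_growth = list(
      nParticles = 40L, boxN = 256L, radiusSchedules = growth,
      radiusSpread = 0, recommendedFrames = 120L, seed = 11L),
    growth_distribution = list(
      nParticles = 40L, boxN = 256L, radiusSchedules = growth,
      radiusSpread = knobs$spreadFraction * 8,  # 8 px = run-mean radius
      recommendedFrames = 120L, seed = 12L),
    nonlinear_growth = list(
      nParticles = 40L, boxN = 256L,
      radiusSchedules = schedule(c(0, 60, 120), c(2, 5, 14)),
      recommendedFrames = 120L, seed = 13L),
    two_step_growth_dissolution = {
      # stage 1: growth 2 -> 14 px over 40 frames (rate 0.3 px/frame);
      # stage 2: dissolution at rate 0.3/rateRatio over the remaining 80
      # frames, running to completion (empty box) when it gets there --
      # at rateRatio = 1 the dissolution fully reverses the growth
      rGrow <- 0.3
      sch <- if (is.infinite(knobs$rateRatio))
        schedule(c(0, 40, 120), c(2, 14, 14))
      else {
        rDiss <- rGrow / knobs$rateRatio
        rEnd <- 14 - 80 * rDiss
        if (rEnd >= 0) schedule(c(0, 40, 120), c(2, 14, rEnd))
        else schedule(c(0, 40, 40 + 14 / rDiss, 120), c(2, 14, 0, 0))
      }
      list(nParticles = 40L, boxN = 256L, radiusSchedules = sch,
           recommendedFrames = 120L, seed = 14L)
    },
    shape_change = list(
      nParticles = 40L, boxN = 256L, radiusMean = 10,
      shapeRatio = schedule(c(0, 55, 65, 120), c(1, 1, 0.5, 0.5)),
      recommendedFrames = 120L, seed = 15L),
    concentration_ramp = list(
      nParticles = 40L, boxN = 256L, radiusMean = 10,
      uIn = schedule(c(0, 120), c(-0.2, -1)),
      recommendedFrames = 120L, seed = 16L),
    brownian = list(
      nParticles = 200L, boxN = 256L, radiusMean = 6,
      motion = motionSpec("random_walk", 1),
      # non-overlapping droplets give the structure-factor peak the
      # analysis ring is centred on
      minSeparation = 13, recommendedFrames = 100L, seed = 17L),
    brownian_plus_growth = list(
      nParticles = 40L, boxN = 256L,
      radiusSchedules = schedule(c(0, 120), c(2, 2 + 120 * knobs$growthRate)),
      motion = motionSpec("random_walk", knobs$stepSigma),
      recommendedFrames = 120L, seed = 18L),
    early_stage_llps = list(
      nParticles = 40L, boxN = 256L, radiusSchedules = growth,
      motion = motionSpec("random_walk",
                          schedule(c(0, 120), c(3, 0.05))),
      recommendedFrames = 120L, seed = 19L)
  )
  bad <- setdiff(names(overrides), names(formals(particleEnsembleSpec)))
  if (length(bad))
    stop("unknown override field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  args[names(overrides)] <- overrides
  do.call(particleEnsembleSpec, args)
}
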