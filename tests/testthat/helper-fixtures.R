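# Shared small fixtures, built in code.  Expensive objects are memoised per
# test session.

fixtureEnv <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = fixtureEnv)) assign(key, builder(), fixtureEnv)
  get(key, envir = fixtureEnv)
}

# A small phase-separating CH run (96^2) used by several modules.
smallCHSeries <- function() memo("smallCH", function() {
  evolve(CHParams(gridN = 96L, quench = 0.7, seed = 42L),
         nSteps = 1500L, sampleEvery = 25L)
})

# Synthetic speckle series with i.i.d. exponential intensities (no dynamics,
# no radial structure): the estimator null.
iidSpeckle <- function(n = 64L, frames = 40L, seed = 7L) {
  I <- withr::with_seed(seed,
    array(stats::rexp(n * n * frames), c(n, n, frames)))
  new("SpeckleSeries", I = I, times = seq_len(frames) - 1,
      qmap = xpcsre:::qMapSimulation(n), qUnit = "simulation")
}

# Frozen speckle: one random frame repeated.
frozenSpeckle <- function(n = 64L, frames = 12L, seed = 5L) {
  f <- withr::with_seed(seed, matrix(stats::rexp(n * n), n, n))
  new("SpeckleSeries", I = array(f, c(n, n, frames)),
      times = seq_len(frames) - 1,
      qmap = xpcsre:::qMapSimulation(n), qUnit = "simulation")
}

# Wide mid-map ring (plenty of pixels) on an n^2 simulation q-map.
midRing <- function(series, width = 4) {
  n <- nrow(series@qmap)
  makeQRing(series, max(series@qmap) / 2 / sqrt(2), width * 2 * pi / n)
}

# Growth scenario at reduced size used by feature tests: identical disks,
# constant-speed growth.
growthSeries <- function() memo("growth", function() {
  spec <- buildScenario("linear_growth")
  simulateParticles(spec)
})

growthSpeckle <- function() memo("growthSpeckle", function() {
  speckleSeries(growthSeries())
})
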