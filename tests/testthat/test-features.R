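mkProfile <- function(values, times = seq_along(values) - 1) {
  new("ContrastProfile", values = values, ageTimes = times, offset = 1L)
}

test_that("tail detection finds prominent interior maxima only", {
  expect_length(detectTails(mkProfile(exp(-(0:30) / 5))), 0L)

  t <- 0:99
  sine <- mkProfile(0.5 + 0.3 * cos(2 * pi * t / 21), t)
  tails <- detectTails(sine, 0.1)
  expect_true(all(abs(diff(tails) - 21) <= 1))
  # endpoints excluded even though t = 0 is a maximum of the cosine
  expect_false(0 %in% tails)

  # prominence filters shallow ripples (interior maxima at t = 33, 66)
  ripple <- mkProfile(0.5 + 0.3 * cos(2 * pi * t / 33) +
                        0.02 * cos(2 * pi * t / 5), t)
  expect_equal(length(detectTails(ripple, 0.1)), 2L)
})

test_that("the integer-multiple rule converts tails to lengths", {
  xi <- xiFromTails(c(10, 30, 60), q = 0.1, n0 = 1L)
  expect_equal(xi$xi, c(62.8, 125.7, 188.5), tolerance = 1e-3)
  expect_equal(xi$tAge, c(10, 30, 60))
  expect_equal(nrow(xiFromTails(numeric(), 0.1)), 0L)
  expect_equal(anchorTailIndex(125, 0.1), 2L)
  expect_equal(anchorTailIndex(1, 0.1), 1L)  # floor at 1
})

test_that("square strength is 1 for frozen maps and ~0 for i.i.d. frames", {
  spF <- frozenSpeckle(frames = 20L)
  ttcF <- computeTTC(spF, midRing(spF))
  expect_equal(squareStrength(ttcF, 9.5), 1, tolerance = 1e-10)

  sp0 <- iidSpeckle(100L, 30L, seed = 19L)
  ring <- makeQRing(sp0, max(sp0@qmap) / 2, max(sp0@qmap) / 2.5)
  ttc0 <- computeTTC(sp0, ring)
  block <- 15 * 15
  expect_lt(abs(squareStrength(ttc0, 14.5)),
            2 / sqrt(block * ringSize(ring) / 30))

  tiny <- computeTTC(frozenSpeckle(frames = 4L), midRing(frozenSpeckle()))
  expect_error(squareStrength(tiny, 0.5), "degenerate")
  expect_error(squareStrength(ttc0, 40), "tSplit")
})

test_that("modulation spacing separates constant from accelerating growth", {
  t <- 0:119
  even <- mkProfile(0.5 + 0.3 * cos(2 * pi * t / 28), t)
  m <- modulationSpacing(even, 0.1)
  expect_false(m$insufficientPeaks)
  expect_equal(m$mean, 28, tolerance = 0.05)
  expect_false(m$nonUniform)

  # synthetic evenly spaced peaks at spacing 7
  vals <- rep(0, 70); vals[seq(7, 63, by = 7)] <- 1
  m7 <- modulationSpacing(mkProfile(vals), 0.5)
  expect_equal(m7$mean, 7)
  expect_equal(m7$sd, 0)

  # accelerating phase -> shrinking spacings flagged non-uniform
  phase <- 2 * pi * (t / 40)^2
  acc <- modulationSpacing(mkProfile(0.5 + 0.3 * cos(phase), t), 0.1)
  expect_true(all(diff(acc$spacings) <= 0))
  expect_lt(acc$spacings[length(acc$spacings)], acc$spacings[1])
  expect_true(acc$nonUniform)

  expect_true(modulationSpacing(mkProfile(exp(-t / 30)),
                                0.1)$insufficientPeaks)
})

test_that("power-law fits recover exact and noisy exponents", {
  t <- seq(10, 1000, length.out = 10)
  # lm warns about an essentially perfect fit on exact data
  exact <- suppressWarnings(fitPowerLaw(data.frame(tAge = t,
                                                   xi = 2 * t^(1 / 3))))
  expect_equal(exact$exponent, 1 / 3, tolerance = 1e-6)
  expect_equal(exact$prefactor, 2, tolerance = 1e-6)
  expect_lt(exact$stderr, 1e-6)

  set.seed(8)
  noisy <- fitPowerLaw(data.frame(
    tAge = t, xi = 2 * t^(1 / 3) * exp(rnorm(10, 0, 0.05))))
  expect_lt(abs(noisy$exponent - 1 / 3), 0.03)

  expect_error(fitPowerLaw(data.frame(tAge = t, xi = -t)), "positive")
  expect_error(fitPowerLaw(data.frame(tAge = t[1:3], xi = t[1:3])), "points")
})

test_that("tail spacing tracks 2*pi/q in diameter and scales with q", {
  # identical-disk constant growth: consecutive tails are separated by a
  # diameter increment of exactly 2*pi/q, and larger q sees tails earlier
  ens <- sampleEnsemble(buildScenario("linear_growth"), 120)
  sp <- growthSpeckle()
  res <- lapply(c(8, 6), function(Lq) {
    ring <- makeQRing(sp, 2 * pi / Lq, 1.5 * 2 * pi / 256)
    cp <- contrastProfile(computeTTC(sp, ring))
    tails <- detectTails(cp, 0.1)
    list(Lq = Lq, tails = tails,
         dia = vapply(tails, function(t) meanDiameter(ens, t), numeric(1)))
  })
  for (r in res) {
    expect_gte(length(r$tails), 2L)
    dDia <- diff(r$dia)
    expect_lt(max(abs(dDia - r$Lq) / r$Lq), 0.25)
  }
  # larger q (smaller probed length): first tail earlier, at least as many
  expect_lt(res[[2]]$tails[1], res[[1]]$tails[1])
  expect_gte(length(res[[2]]$tails), length(res[[1]]$tails))
})

test_that("feature reports aggregate tails, spacing and square strength", {
  sp <- growthSpeckle()
  ring <- makeQRing(sp, 2 * pi / 8, 1.5 * 2 * pi / 256)
  ttc <- computeTTC(sp, ring)
  rep <- featureReport(ttc, prominence = 0.1, tSplit = NA)
  expect_s4_class(rep, "FeatureReport")
  expect_gte(length(rep@tailTimes), 2L)
  expect_equal(nrow(rep@xiPoints), length(rep@tailTimes))
  expect_true(is.na(rep@squareStrength))
  expect_false(rep@modulation$insufficientPeaks)
})
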