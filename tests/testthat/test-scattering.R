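test_that("energy-wavelength conversion reproduces the beamline value", {
  expect_equal(round(energyToWavelength(8.54), 3), 1.452)
  expect_equal(energyToWavelength(12.398419843), 1)
  expect_equal(energyToWavelength(4), 2 * energyToWavelength(8))
  expect_error(energyToWavelength(0), "energyKeV")
})

test_that("physical q-map is zero at the beam centre, monotone, and matches
          the small-angle limit at the USAXS geometry", {
  geom <- geometry(photonEnergy = 8.54, detectorDistance = 21.2,
                   pixelSize = 75, beamCenter = c(65, 65))
  qm <- qMapPhysical(geom, c(129, 129))
  expect_equal(qm[65, 65], 0)
  # strictly increasing along a row away from the centre
  expect_true(all(diff(qm[65, 65:129]) > 0))
  # small-angle approximation within 0.01%
  d <- (0:64) * 75e-6
  qApprox <- 2 * pi * d / (geom@wavelength * 1e-10 * 21.2) * 1e-9
  expect_lt(max(abs(qm[65, 65:129] - qApprox) /
                  pmax(qApprox, 1e-12)), 1e-4)
  # the USAXS configuration reaches beyond 3.2e-3 nm^-1
  expect_gt(max(qm), 3.2e-3)
})

test_that("speckle synthesis removes the mean and satisfies Parseval", {
  n <- 64L
  set.seed(31)
  u <- matrix(rnorm(n * n), n, n)
  f <- new("ConcentrationField", values = u, time = 0, dx = 1)
  s <- speckleFromField(f)
  centre <- floor(n / 2) + 1L
  expect_equal(s@intensity[centre, centre], 0)
  # Parseval under the unnormalized FFT convention
  expect_equal(sum(s@intensity), n^2 * sum((u - mean(u))^2),
               tolerance = 1e-8)
  # point symmetry I(q) = I(-q) for real fields
  idx <- 2:n
  expect_equal(s@intensity[idx, idx],
               s@intensity[rev(idx), rev(idx)], tolerance = 1e-6)

  # a pure cosine lights up exactly one +/- frequency pair
  k <- 5
  x <- outer(0:(n - 1), rep(1, n))
  fc <- new("ConcentrationField", values = cos(2 * pi * k * x / n),
            time = 0, dx = 1)
  I <- speckleFromField(fc)@intensity
  nz <- which(I > max(I) * 1e-20, arr.ind = TRUE)
  expect_equal(nrow(nz), 2L)
  expect_setequal(nz[, 1], c(centre - k, centre + k))
})

test_that("radial profiles bin correctly on constructed inputs", {
  n <- 64L
  qmap <- xpcsre:::qMapSimulation(n)
  flat <- matrix(2.5, n, n)
  p <- radialProfile(flat, qmap, 16L)
  expect_true(all(abs(p$intensity[p$n > 0] - 2.5) < 1e-12))

  # indicator ring at one radius lands in the covering bin only
  kr <- 2 * pi * 10 / n
  ringI <- ifelse(abs(qmap - kr) < 2 * pi * 0.5 / n, 1, 0)
  p2 <- radialProfile(ringI, qmap, 16L)
  hot <- which(p2$intensity > 0 & p2$n > 0)
  expect_lte(length(hot), 2L)
  expect_lt(abs(p2$q[hot[1]] - kr), diff(p2$q)[1] * 1.5)

  # isotropic gaussian bump peaks at the right bin
  q0 <- max(qmap) / 3
  I <- exp(-(qmap - q0)^2 / (0.1 * q0)^2)
  p3 <- radialProfile(I, qmap, 32L)
  expect_lt(abs(p3$q[which.max(p3$intensity)] - q0), diff(p3$q)[1])
})

test_that("xi extraction follows 2*pi/q and flags out-of-window peaks", {
  prof <- data.frame(q = seq(0.01, 0.1, length.out = 20),
                     intensity = dnorm(seq(0.01, 0.1, length.out = 20),
                                       0.0314, 0.01), n = 50)
  res <- xiUsaxs(prof, smooth = 1L, refine = FALSE)
  expect_equal(res$xi, 2 * pi / res$qPeak)
  expect_lt(abs(res$qPeak - 0.0314), 0.005)

  flat <- data.frame(q = 1:10, intensity = rep(1, 10), n = 5)
  expect_error(xiUsaxs(flat), "window")
  increasing <- data.frame(q = 1:10, intensity = 1:10, n = 5)
  expect_error(xiUsaxs(increasing), "window")
})

test_that("q-rings collect the right pixels", {
  sp <- iidSpeckle(128L, 2L)
  qmax <- max(sp@qmap)
  ring <- makeQRing(sp, qmax / 2, 2 * pi / 128)
  expect_gte(ringSize(ring), 8L)
  expect_true(all(abs(sp@qmap[ring@pixels] - qmax / 2) <= 2 * pi / 128))

  # full cover: every pixel except the centre
  all_ring <- makeQRing(sp, qmax / 2, qmax)
  expect_equal(ringSize(all_ring), 128L * 128L - 1L)

  # point symmetry of ring membership
  mask <- matrix(FALSE, 128, 128)
  mask[ring@pixels] <- TRUE
  idx <- 2:128
  expect_identical(mask[idx, idx], mask[rev(idx), rev(idx)])

  expect_error(makeQRing(sp, qmax * 2, 1e-9), "empty")
})

test_that("analysis q tracks a constructed early-stage peak", {
  n <- 64L
  qmap <- xpcsre:::qMapSimulation(n)
  mkFrame <- function(q0) exp(-(qmap - q0)^2 / (0.05 * max(qmap))^2)
  q1 <- max(qmap) / 4; q2 <- max(qmap) / 3
  I <- array(0, c(n, n, 3))
  I[, , 1] <- mkFrame(q1); I[, , 2] <- mkFrame(q2); I[, , 3] <- mkFrame(q2)
  sp <- new("SpeckleSeries", I = I, times = 0:2, qmap = qmap,
            qUnit = "simulation")
  qc <- selectAnalysisQ(sp, 2L)
  expect_gt(qc, q1 - 0.05); expect_lt(qc, q2 + 0.05)
  expect_lt(abs(qc - (q1 + q2) / 2), diff(range(qmap)) / 16)
  expect_warning(selectAnalysisQ(sp, 10L), "clipped")
})

test_that("noise injection is uniform, seeded and amplitude-anchored", {
  sp <- iidSpeckle(64L, 6L)
  expect_identical(addNoise(sp, 0)@I, sp@I)
  n1 <- addNoise(sp, 0.04, seed = 3L)
  n2 <- addNoise(sp, 0.04, seed = 3L)
  expect_identical(n1@I, n2@I)
  expect_true(all(n1@I >= sp@I))
  amp <- 0.04 * max(sp@I)
  lift <- mean(n1@I - sp@I)
  expect_lt(abs(lift - amp / 2) / (amp / 2), 0.01)
  expect_true(all(n1@I - sp@I <= amp))
})
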