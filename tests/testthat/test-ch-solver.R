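test_that("parameter validation names the offending field", {
  expect_error(CHParams(gridN = 8L), "gridN")
  expect_error(CHParams(dt = -1), "dt")
  expect_error(CHParams(meanU = 1.2), "meanU")
  expect_error(CHParams(mMin = 0), "mMin")
  # quench is clipped, not rejected
  expect_equal(CHParams(quench = 1.7)@quench, 1)
})

test_that("initial field is seeded, mean-correct and degenerate without noise", {
  pFlat <- CHParams(gridN = 32L, meanU = 0.2, initNoiseAmp = 0)
  expect_equal(fieldValues(initializeField(pFlat)),
               matrix(0.2, 32, 32))

  p <- CHParams(gridN = 64L, meanU = -0.1, initNoiseAmp = 0.05, seed = 9L)
  f1 <- initializeField(p)
  f2 <- initializeField(p)
  expect_identical(fieldValues(f1), fieldValues(f2))
  expect_true(all(abs(fieldValues(f1) + 0.1) <= 0.05))

  # law of large numbers: mean of a 512^2 draw with amp 0.01
  pBig <- CHParams(gridN = 512L, meanU = 0.3, initNoiseAmp = 0.01, seed = 2L)
  expect_lt(abs(mean(fieldValues(initializeField(pBig))) - 0.3), 1e-3)
})

test_that("homogeneous fields are fixed points and mass is conserved", {
  p <- CHParams(gridN = 48L, quench = 0.8, meanU = 0.15, initNoiseAmp = 0)
  f <- initializeField(p)
  stepped <- chStep(f, p)
  expect_equal(fieldValues(stepped), fieldValues(f), tolerance = 1e-12)

  pn <- CHParams(gridN = 48L, quench = 0.8, initNoiseAmp = 0.2, seed = 4L)
  f <- initializeField(pn)
  m0 <- mean(fieldValues(f))
  for (i in 1:50) {
    f <- chStep(f, pn)
    expect_lt(abs(mean(fieldValues(f)) - m0), 1e-10)
  }

  # gel mobility conserves mass too
  pg <- CHParams(gridN = 48L, quench = 0.8, dt = 0.01,
                 mobilityModel = "gel", initNoiseAmp = 0.2, seed = 4L)
  fg <- initializeField(pg)
  for (i in 1:20) fg <- chStep(fg, pg)
  expect_lt(abs(mean(fieldValues(fg)) - m0), 1e-10)
})

test_that("mirror-symmetric initial data stays mirror symmetric", {
  p <- CHParams(gridN = 64L, quench = 0.7, initNoiseAmp = 0.1, seed = 6L)
  v <- fieldValues(initializeField(p))
  # symmetrize under the periodic reflection j -> N + 2 - j
  mir <- function(m) m[, c(1, ncol(m):2)]
  v <- (v + mir(v)) / 2
  f <- new("ConcentrationField", values = v, time = 0, dx = 1)
  for (i in 1:100) f <- chStep(f, p)
  expect_lt(max(abs(fieldValues(f) - mir(fieldValues(f)))), 1e-8)
})

test_that("free energy matches an independent finite-difference oracle", {
  p <- CHParams(gridN = 24L, quench = 0.6, gradientCoeff = 1.3)
  # closed forms
  z <- new("ConcentrationField", values = matrix(0, 24, 24), time = 0, dx = 1)
  expect_equal(freeEnergy(z, p), 0)
  ueq <- sqrt(p@quench)
  u <- new("ConcentrationField", values = matrix(ueq, 24, 24), time = 0,
           dx = 1)
  expect_equal(freeEnergy(u, p), -p@quench^2 / 4 * 24^2, tolerance = 1e-12)

  # brute-force loop oracle on a random field, dx != 1
  set.seed(11)
  n <- 16L; dx <- 0.5
  vals <- matrix(rnorm(n * n), n, n)
  f <- new("ConcentrationField", values = vals, time = 0, dx = dx)
  oracle <- 0
  for (i in 1:n) for (j in 1:n) {
    ip <- if (i == n) 1L else i + 1L; im <- if (i == 1L) n else i - 1L
    jp <- if (j == n) 1L else j + 1L; jm <- if (j == 1L) n else j - 1L
    gx <- (vals[ip, j] - vals[im, j]) / (2 * dx)
    gy <- (vals[i, jp] - vals[i, jm]) / (2 * dx)
    oracle <- oracle + (-p@quench / 2 * vals[i, j]^2 + vals[i, j]^4 / 4 +
                          p@gradientCoeff / 2 * (gx^2 + gy^2)) * dx^2
  }
  expect_equal(freeEnergy(f, p), oracle, tolerance = 1e-10)
})

test_that("free energy is non-increasing along a constant-mobility run", {
  fs <- smallCHSeries()
  p <- CHParams(gridN = 96L, quench = 0.7, seed = 42L)
  fe <- sapply(seq_len(nFrames(fs)), function(i)
    freeEnergy(getFrame(fs, i), p))
  expect_true(all(diff(fe) <= 1e-8 * pmax(abs(fe[-length(fe)]), 1)))
})

test_that("no quench means no spinodal instability: fluctuations decay", {
  p <- CHParams(gridN = 64L, quench = 0, initNoiseAmp = 0.05, seed = 3L)
  fs <- evolve(p, 400L, 100L)
  amp0 <- max(speckleFromField(getFrame(fs, 1))@intensity)
  ampEnd <- max(speckleFromField(getFrame(fs, nFrames(fs)))@intensity)
  expect_lt(ampEnd, amp0)
})

test_that("binarization maps signs, is idempotent and counts area", {
  f <- new("ConcentrationField",
           values = matrix(c(0.3, -0.7, 0, 1e-9), 2, 2), time = 3, dx = 1)
  b <- binarize(f)
  expect_equal(fieldValues(b), matrix(c(1, -1, -1, 1), 2, 2))
  expect_equal(b@time, 3)
  expect_identical(fieldValues(binarize(b)), fieldValues(b))

  fs <- smallCHSeries()
  bs <- binarize(fs)
  u <- fieldValues(getFrame(fs, nFrames(fs)))
  expect_equal(sum(fieldValues(getFrame(bs, nFrames(bs))) == 1),
               sum(u > 0))
})

test_that("gel mobility slows late-stage coarsening at matched times", {
  mkParams <- function(model) CHParams(
    gridN = 64L, quench = 0.8, dt = 0.01, mobilityModel = model,
    uGel = 0.3, mMin = 0.05, initNoiseAmp = 0.1, seed = 13L)
  nSteps <- 3000L
  xiEnd <- function(model) {
    fs <- evolve(mkParams(model), nSteps, nSteps)
    sp <- speckleSeries(fs)
    xiUsaxs(radialProfile(sp@I[, , 2], sp@qmap))$xi
  }
  expect_lt(xiEnd("gel"), xiEnd("constant"))
})

test_that("domain dilation grows the chosen phase as a diamond front", {
  # single +1 disk on a -1 background
  n <- 64L
  xy <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
  disk <- matrix(ifelse((xy$x - 32)^2 + (xy$y - 32)^2 <= 10^2, 1, -1), n, n)
  fs <- new("FieldSeries", u = array(rep(disk, 3), c(n, n, 3)),
            times = 0:2, dx = 1)

  expect_identical(dilateDomains(fs, 0L)@u, fs@u)
  expect_error(dilateDomains(new("FieldSeries",
                                 u = fs@u * 0.5, times = 0:2, dx = 1)),
               "binarized")

  d <- dilateDomains(fs, 1L, phase = "dense")
  area <- apply(d@u, 3, function(m) sum(m == 1))
  # frame 0 untouched; frame k dilated k times: each 4-neighbour dilation
  # adds about one perimeter of pixels (diamond growth of the radius)
  expect_equal(area[1], sum(disk == 1))
  a1 <- sum(outer(0:(n - 1), 0:(n - 1), function(x, y)
    (x - 32)^2 + (y - 32)^2 <= 11^2))
  expect_lt(abs(area[2] - a1), 2 * pi * 11)
  expect_true(all(diff(area) > 0))
})
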