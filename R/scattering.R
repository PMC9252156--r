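#' Photon energy to X-ray wavelength
#'
#' `lambda[Angstrom] = 12.398419843 / E[keV]` (hc in keV Angstrom).
#'
#' @param energyKeV photon energy in keV (> 0)
#' @return wavelength in Angstrom
#' @examples
#' energyToWavelength(8.54)  # 1.452
#' @export
energyToWavelength <- function(energyKeV) {
  checkThat(all(is.finite(energyKeV)) && all(energyKeV > 0), "energyKeV",
            "must be positive")
  12.398419843 / energyKeV
}

#' Construct a scattering geometry
#'
#' @param photonEnergy keV
#' @param detectorDistance sample-to-detector distance in metres
#' @param pixelSize detector pixel size in micrometres
#' @param beamCenter (row, col) of the direct beam in pixels
#' @return a [Geometry]
#' @export
geometry <- function(photonEnergy, detectorDistance, pixelSize, beamCenter) {
  new("Geometry", photonEnergy = photonEnergy,
      wavelength = energyToWavelength(photonEnergy),
      detectorDistance = detectorDistance, pixelSize = pixelSize,
      beamCenter = as.numeric(beamCenter))
}

#' Per-pixel momentum transfer of a detector
#'
#' Elastic scattering: a pixel at radial distance `d` from the beam centre
#' sees scattering angle `2*theta = arctan(d * pixelSize / distance)` and
#' momentum transfer `q = (4*pi/lambda) * sin(theta)`, returned in nm^-1.
#'
#' @param geom a [Geometry]
#' @param shape integer (rows, cols) of the detector
#' @return numeric matrix of `|q|` in nm^-1
#' @export
qMapPhysical <- function(geom, shape) {
  stopifnot(is(geom, "Geometry"))
  validObject(geom)
  rows <- seq_len(shape[1]) - geom@beamCenter[1]
  cols <- seq_len(shape[2]) - geom@beamCenter[2]
  d <- sqrt(outer(rows^2, cols^2, `+`)) * geom@pixelSize * 1e-6  # metres
  theta <- atan2(d, geom@detectorDistance) / 2
  lambdaNm <- geom@wavelength * 0.1
  4 * pi / lambdaNm * sin(theta)
}

# q-map in simulation units for an N x N FFT frame, zero-frequency centred:
# |q| = 2*pi*|k|/(N*dx) with integer frequencies k.
qMapSimulation <- function(n, dx = 1) {
  k <- fftshift2(matrix(fftFreqs(n), n, n))
  kT <- t(k)
  2 * pi * sqrt(k^2 + kT^2) / (n * dx)
}

#' Speckle pattern of a concentration field
#'
#' The coherent-scattering intensity is the squared magnitude of the 2D FFT
#' of the concentration fluctuations, `I = |FFT2(u - mean(u))|^2`, with the
#' zero-frequency pixel shifted to the centre (and identically zero, since
#' the mean is removed).  The forward transform is unnormalized; only
#' intensity ratios enter the correlation analysis.
#'
#' @param field a [ConcentrationField]
#' @return a [SpeckleFrame]
#' @export
speckleFromField <- function(field) {
  stopifnot(is(field, "ConcentrationField"))
  u <- field@values
  I <- fftshift2(Mod(stats::fft(u - mean(u)))^2)
  new("SpeckleFrame", intensity = I, time = field@time)
}

#' Speckle series of a field series
#'
#' Applies [speckleFromField()] frame by frame and attaches the q-map
#' (simulation units `2*pi*k/(N*dx)`, or physical nm^-1 when a [Geometry]
#' is supplied).
#'
#' @param series a [FieldSeries]
#' @param geom optional [Geometry] for a physical q-map (beam centre then
#'   defaults to the zero-frequency pixel)
#' @return a [SpeckleSeries]
#' @export
speckleSeries <- function(series, geom = NULL) {
  stopifnot(is(series, "FieldSeries"))
  d <- dim(series@u)
  I <- array(0, d)
  for (f in seq_len(d[3]))
    I[, , f] <- fftshift2(Mod(stats::fft(series@u[, , f] -
                                           mean(series@u[, , f])))^2)
  if (is.null(geom)) {
    qmap <- qMapSimulation(d[1], series@dx)
    unit <- "simulation"
  } else {
    qmap <- qMapPhysical(geom, d[1:2])
    unit <- "nm^-1"
  }
  new("SpeckleSeries", I = I, times = series@times, qmap = qmap,
      qUnit = unit)
}

#' Azimuthally averaged intensity profile
#'
#' Mean intensity in equal-width `|q|` bins, excluding the zero-frequency
#' pixel.  Empty bins are reported with count 0 and `NA` intensity.
#'
#' @param frame a [SpeckleFrame] or intensity matrix
#' @param qmap per-pixel `|q|` matrix
#' @param nBins number of bins (>= 4; default `N/4`)
#' @return data.frame with columns `q` (bin centres), `intensity`, `n`
#' @export
radialProfile <- function(frame, qmap, nBins = NULL) {
  I <- if (is(frame, "SpeckleFrame")) frame@intensity else frame
  stopifnot(all(dim(I) == dim(qmap)))
  if (is.null(nBins)) nBins <- max(4L, nrow(I) %/% 4L)
  checkThat(nBins >= 4L, "nBins", "must be >= 4")
  keep <- qmap > 0
  qv <- qmap[keep]; iv <- I[keep]
  edges <- seq(0, max(qv), length.out = nBins + 1L)
  bin <- pmin(findInterval(qv, edges, rightmost.closed = TRUE), nBins)
  counts <- tabulate(bin, nBins)
  sums <- vapply(seq_len(nBins), function(b) sum(iv[bin == b]), numeric(1))
  data.frame(q = (edges[-1] + edges[-(nBins + 1L)]) / 2,
             intensity = ifelse(counts > 0, sums / pmax(counts, 1), NA),
             n = counts)
}

#' Scattering peak position and USAXS characteristic length
#'
#' Finds the maximum of the (optionally smoothed) radial profile, excluding
#' the first and last bins, and returns `xi = 2*pi/q_peak`.  A maximum on a
#' boundary bin raises an error: the peak has left the measurement window,
#' the failure mode that limits peak-based sizing of late-stage coarsening.
#' With `refine = TRUE` the peak position is interpolated quadratically
#' through the three bins around the maximum.
#'
#' @param profile data.frame from [radialProfile()]
#' @param smooth moving-average window (bins; 1 = no smoothing)
#' @param refine logical, sub-bin quadratic peak interpolation
#' @return list with `qPeak` and `xi`
#' @export
xiUsaxs <- function(profile, smooth = 3L, refine = TRUE) {
  ok <- !is.na(profile$intensity)
  q <- profile$q[ok]; I <- profile$intensity[ok]
  if (length(q) < 3L) stop("profile too short for peak search", call. = FALSE)
  Is <- movingAverage(I, smooth)
  i <- which.max(Is)
  if (i == 1L || i == length(Is))
    stop("intensity maximum lies on a boundary bin: ",
         "the peak is outside the measurement window", call. = FALSE)
  qPeak <- q[i]
  if (refine) {
    y0 <- Is[i - 1]; y1 <- Is[i]; y2 <- Is[i + 1]
    den <- y0 - 2 * y1 + y2
    if (den < 0) {
      delta <- 0.5 * (y0 - y2) / den
      qPeak <- q[i] + delta * (q[i + 1] - q[i])
    }
  }
  list(qPeak = qPeak, xi = 2 * pi / qPeak)
}

#' Select the analysis momentum transfer from the early-stage peak
#'
#' Averages the radial-profile peak position over the first `earlyFrames`
#' frames; the correlation analysis is then performed near the q of the
#' early-stage structure-factor peak, mirroring how the experimental q-ring
#' is chosen.
#'
#' @param series a [SpeckleSeries]
#' @param earlyFrames number of initial frames to average (clipped with a
#'   warning if larger than the series)
#' @param skipUniform skip frames whose profile has no interior peak (e.g.
#'   an initial homogeneous field); default TRUE
#' @return the analysis `qCenter`
#' @export
selectAnalysisQ <- function(series, earlyFrames = 5L, skipUniform = TRUE) {
  stopifnot(is(series, "SpeckleSeries"))
  checkThat(earlyFrames >= 1L, "earlyFrames", "must be >= 1")
  nf <- nFrames(series)
  if (earlyFrames > nf) {
    warning("earlyFrames clipped to the ", nf, " available frames")
    earlyFrames <- nf
  }
  peaks <- numeric(0)
  for (f in seq_len(earlyFrames)) {
    p <- radialProfile(series@I[, , f], series@qmap)
    pk <- tryCatch(xiUsaxs(p)$qPeak, error = function(e) NA_real_)
    if (!is.na(pk)) peaks <- c(peaks, pk)
    else if (!skipUniform) stop("no interior peak in frame ", f,
                                call. = FALSE)
  }
  if (!length(peaks))
    stop("no early-stage intensity peak found in the first ", earlyFrames,
         " frames", call. = FALSE)
  mean(peaks)
}

#' Build a q-ring pixel set
#'
#' Selects all pixels with `|q - qCenter| <= qHalfwidth`, excluding the
#' zero-frequency pixel; the set is point symmetric because the q-map is.
#'
#' @param series a [SpeckleSeries] (or a q-map matrix)
#' @param qCenter ring centre
#' @param qHalfwidth ring half width (delta q)
#' @return a [QRing]
#' @export
makeQRing <- function(series, qCenter, qHalfwidth) {
  qmap <- if (is(series, "SpeckleSeries")) series@qmap else series
  pix <- which(abs(qmap - qCenter) <= qHalfwidth & qmap > 0)
  if (!length(pix))
    stop("empty q-ring at q = ", signif(qCenter, 4),
         "; increase qHalfwidth", call. = FALSE)
  new("QRing", qCenter = qCenter, qHalfwidth = qHalfwidth,
      pixels = as.integer(pix))
}

#' Grow a q-ring until it holds at least a target pixel count
#'
#' Doubles the half width (starting from one q-pixel spacing) until the ring
#' holds `minPixels` pixels; used to guarantee estimator precision, which
#' scales as `1/sqrt(ring size)`.
#'
#' @param series a [SpeckleSeries]
#' @param qCenter ring centre
#' @param minPixels required pixel count
#' @return a [QRing]
#' @export
makeQRingMinPixels <- function(series, qCenter, minPixels = 1000L) {
  dq <- 2 * pi / (nrow(series@qmap) * 1)
  if (series@qUnit != "simulation")
    dq <- diff(range(series@qmap)) / nrow(series@qmap)
  repeat {
    ring <- makeQRing(series, qCenter, dq)
    if (length(ring@pixels) >= minPixels) return(ring)
    if (dq > max(series@qmap)) return(ring)
    dq <- dq * 2
  }
}

#' Add constant-amplitude detector noise to a speckle series
#'
#' Adds i.i.d. uniform noise on `[0, fraction * Imax]` per pixel per frame,
#' where `Imax` is the maximum intensity over the whole input series, so the
#' noise amplitude is constant in time while the signal evolves.  As the
#' signal-to-noise ratio tracks the scattering intensity, the near-diagonal
#' TTC contrast acquires the intensity's time dependence -- the mechanism
#' behind experimental contrast fluctuations (around 4% of `Imax`
#' reproduces typical experimental behaviour).
#'
#' @param series a [SpeckleSeries]
#' @param fraction noise amplitude as a fraction of the series maximum
#' @param seed RNG seed
#' @return the noisy [SpeckleSeries]
#' @export
addNoise <- function(series, fraction = 0.04, seed = 1L) {
  stopifnot(is(series, "SpeckleSeries"))
  checkThat(fraction >= 0, "fraction", "must be >= 0")
  if (fraction == 0) return(series)
  amp <- fraction * max(series@I)
  I <- withSeed(seed, {
    series@I + array(stats::runif(length(series@I), 0, amp), dim(series@I))
  })
  initialize(series, I = I)
}
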