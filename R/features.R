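#' Detect tail features in a contrast profile
#'
#' Tails are local maxima of the off-diagonal contrast profile: during
#' domain growth the intensity peaks sweep through the analysis ring and the
#' contrast revives each time the characteristic length crosses an integer
#' multiple of `2*pi/q`.  Maxima are called at interior points with
#' topographic prominence at least `prominence`; endpoints are excluded.
#'
#' @param profile a [ContrastProfile] (length >= 5)
#' @param prominence minimum peak prominence (correlation units)
#' @return numeric age times of detected maxima (possibly empty)
#' @export
detectTails <- function(profile, prominence = 0.05) {
  stopifnot(is(profile, "ContrastProfile"))
  checkThat(length(profile@values) >= 5L, "profile",
            "needs at least 5 samples")
  idx <- localMaxima(profile@values, prominence)
  profile@ageTimes[idx]
}

#' Characteristic lengths from tail times (integer-multiple rule)
#'
#' A tail appears approximately when the characteristic length equals an
#' integer multiple of the probed length `2*pi/q`; consecutive tails
#' correspond to consecutive integers.  The k-th detected tail (0-based) is
#' therefore assigned `xi = (n0 + k) * 2*pi/q`, where `n0` anchors the first
#' tail's integer index (user-supplied, or estimated from an independent
#' early size estimate via [anchorTailIndex()]).  Points from several
#' q-rings can be concatenated into one growth curve.
#'
#' @param tailTimes sorted age times of detected tails
#' @param q analysis momentum transfer
#' @param n0 integer index of the first tail (>= 1)
#' @return data.frame with columns `tAge`, `xi`
#' @export
xiFromTails <- function(tailTimes, q, n0 = 1L) {
  checkThat(n0 >= 1L, "n0", "must be >= 1")
  checkThat(!is.unsorted(tailTimes), "tailTimes", "must be sorted")
  if (!length(tailTimes))
    return(data.frame(tAge = numeric(), xi = numeric()))
  data.frame(tAge = tailTimes,
             xi = (n0 + seq_along(tailTimes) - 1) * 2 * pi / q)
}

#' Anchor the first tail index from an independent size estimate
#'
#' @param xiEstimate independent characteristic length at the first tail
#'   time (e.g. `xi` from the scattering-peak position, [xiUsaxs()])
#' @param q analysis momentum transfer
#' @return integer `n0 >= 1`
#' @export
anchorTailIndex <- function(xiEstimate, q) {
  max(1L, as.integer(round(xiEstimate * q / (2 * pi))))
}

#' Square-feature strength of a TTC
#'
#' The square feature is a block of frozen-in correlation between the epochs
#' before and after a kinetic transition (e.g. growth turning into slow
#' dissolution).  Its strength is measured as the mean of `G` over the
#' off-diagonal block `{t1 < tSplit < t2}` (the symmetric block is pooled by
#' symmetry).
#'
#' @param ttc a [TwoTimeCorrelation]
#' @param tSplit split time, strictly inside the time range; `NULL` selects
#'   it automatically as the point of maximum curvature of the smoothed
#'   contrast profile (change point of the diagonal dynamics)
#' @return scalar mean block correlation
#' @export
squareStrength <- function(ttc, tSplit = NULL) {
  stopifnot(is(ttc, "TwoTimeCorrelation"))
  if (is.null(tSplit)) tSplit <- autoSplitTime(ttc)
  tt <- ttc@times
  checkThat(tSplit > min(tt) && tSplit < max(tt), "tSplit",
            "must be strictly inside the time range")
  pre <- which(tt < tSplit)
  post <- which(tt > tSplit)
  if (length(pre) * length(post) < 4L)
    stop("degenerate square block (< 4 entries); move tSplit inward",
         call. = FALSE)
  mean(ttc@G[pre, post])
}

# Change point of the diagonal dynamics: age of maximum |curvature| of the
# smoothed offset-1 contrast profile.
autoSplitTime <- function(ttc) {
  cp <- contrastProfile(ttc, 1L)
  v <- movingAverage(cp@values, 7L)
  if (length(v) < 5L) return(stats::median(ttc@times))
  curv <- abs(diff(v, differences = 2))
  cp@ageTimes[which.max(curv) + 1L]
}

#' Spacing statistics of modulation peaks
#'
#' Mean and SD of the gaps between consecutive contrast maxima.  Uniform
#' spacing (SD/mean <= 0.25) indicates constant growth speed; decreasing
#' spacings flag accelerating growth (the profile is periodic only when the
#' speed is constant).
#'
#' @param profile a [ContrastProfile]
#' @param prominence peak prominence passed to [detectTails()]
#' @return list with `spacings`, `mean`, `sd`, `nonUniform`,
#'   `insufficientPeaks`
#' @export
modulationSpacing <- function(profile, prominence = 0.05) {
  tails <- detectTails(profile, prominence)
  if (length(tails) < 2L)
    return(list(spacings = numeric(), mean = NA_real_, sd = NA_real_,
                nonUniform = NA, insufficientPeaks = TRUE))
  sp <- diff(tails)
  m <- mean(sp)
  s <- if (length(sp) > 1L) stats::sd(sp) else 0
  list(spacings = sp, mean = m, sd = s, nonUniform = (s / m) > 0.25,
       insufficientPeaks = FALSE)
}

#' Fit a coarsening power law to characteristic lengths
#'
#' Least-squares line on `(log t, log xi)`; diffusive/coalescence coarsening
#' predicts an exponent of 1/3.
#'
#' @param xiPoints data.frame with columns `tAge`, `xi` (all positive;
#'   `tAge = 0` points are dropped)
#' @return list with `exponent`, `prefactor`, `stderr`
#' @export
fitPowerLaw <- function(xiPoints) {
  checkThat(is.data.frame(xiPoints) && all(c("tAge", "xi") %in%
                                             names(xiPoints)),
            "xiPoints", "needs columns tAge and xi")
  xiPoints <- xiPoints[xiPoints$tAge > 0, ]
  checkThat(nrow(xiPoints) >= 4L, "xiPoints",
            "needs >= 4 points with tAge > 0")
  checkThat(all(xiPoints$xi > 0), "xiPoints", "xi must be positive")
  fit <- stats::lm(log(xi) ~ log(tAge), data = xiPoints)
  s <- summary(fit)$coefficients
  list(exponent = unname(s["log(tAge)", "Estimate"]),
       prefactor = exp(unname(s["(Intercept)", "Estimate"])),
       stderr = unname(s["log(tAge)", "Std. Error"]))
}

#' Assemble a feature report for a TTC
#'
#' Runs tail detection on the offset-1 contrast profile, converts tails to
#' characteristic lengths via the integer-multiple rule, computes modulation
#' spacing statistics and (optionally) the square strength, and fits a
#' power law to the recovered lengths when at least four tails exist.
#'
#' @param ttc a [TwoTimeCorrelation]
#' @param prominence tail prominence threshold
#' @param n0 first-tail integer index for [xiFromTails()]
#' @param tSplit square-feature split time (`NA` skips the square strength,
#'   `NULL` selects it automatically)
#' @return a [FeatureReport]
#' @export
featureReport <- function(ttc, prominence = 0.05, n0 = 1L, tSplit = NULL) {
  cp <- contrastProfile(ttc, 1L)
  tails <- detectTails(cp, prominence)
  xi <- xiFromTails(tails, ttc@qCenter, n0)
  modu <- modulationSpacing(cp, prominence)
  sq <- if (length(tSplit) == 1L && is.na(tSplit)) NA_real_
  else squareStrength(ttc, tSplit)
  pl <- if (nrow(xi) >= 4L && all(xi$tAge > 0)) fitPowerLaw(xi) else list()
  new("FeatureReport", tailTimes = tails, xiPoints = xi,
      squareStrength = sq, modulation = modu, powerLaw = pl)
}
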