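#' Two-time correlation function over a q-ring
#'
#' For each pair of frames, correlates the intensities of the ring pixels.
#' The default estimator is the normalized covariance (Pearson) over pixels,
#' \deqn{G(t_1, t_2) = \frac{\mathrm{cov}_p[I(t_1), I(t_2)]}
#'   {\sigma_p[I(t_1)]\,\sigma_p[I(t_2)]},}
#' for which the limiting values are exact: `G = 1` for frozen speckle and
#' `G = 0` for fully decorrelated frames.  The `"intensity"` variant
#' `<I1 I2> / (<I1><I2>)` (pixel averages) is provided for comparison with
#' conventional XPCS software.  Frames whose ring variance is zero (e.g. a
#' homogeneous field) are masked: their rows/columns are set to 0 and
#' flagged in `validFrames`.
#'
#' The estimator noise scales as `1/sqrt(ring size)`; a warning is issued
#' below 100 pixels and an error below 16.
#'
#' With `normalizeProfile = TRUE` (default) each ring pixel is first
#' divided by the per-frame azimuthal mean of its q-sub-shell (pixels at
#' the same radial spacing), the standard flat-fielding by the smooth
#' `I(|q|)` profile.  Without it, a ring wide enough to span a varying
#' radial profile correlates that static trend between otherwise
#' independent frames, biasing the decorrelated limit above zero.
#'
#' @param series a [SpeckleSeries]
#' @param ring a [QRing]
#' @param estimator `"pearson"` (default) or `"intensity"`
#' @param normalizeProfile logical, flat-field by the per-frame radial
#'   profile across the ring
#' @return a [TwoTimeCorrelation]
#' @export
computeTTC <- function(series, ring, estimator = c("pearson", "intensity"),
                       normalizeProfile = TRUE) {
  stopifnot(is(series, "SpeckleSeries"), is(ring, "QRing"))
  estimator <- match.arg(estimator)
  npix <- length(ring@pixels)
  if (npix < 16L)
    stop("q-ring has only ", npix, " pixels (< 16); widen the ring",
         call. = FALSE)
  if (npix < 100L)
    warning("q-ring has ", npix, " pixels; estimator noise ~ 1/sqrt(n) ",
            "will be large")
  nf <- nFrames(series)
  M <- matrix(0, npix, nf)
  for (f in seq_len(nf)) M[, f] <- series@I[, , f][ring@pixels]
  if (normalizeProfile) {
    # sub-shells at the q-pixel spacing of the map (corner |q| is
    # sqrt(2) * N/2 spacings from the centre)
    dqPix <- max(series@qmap) * sqrt(2) / nrow(series@qmap)
    shell <- round(series@qmap[ring@pixels] / dqPix)
    for (s in unique(shell)) {
      sel <- shell == s
      mns <- colMeans(M[sel, , drop = FALSE])
      ok <- mns > 0
      if (any(ok))
        M[sel, ok] <- sweep(M[sel, ok, drop = FALSE], 2, mns[ok], `/`)
    }
  }
  if (estimator == "pearson") {
    sds <- apply(M, 2, stats::sd)
    valid <- sds > 0
    G <- matrix(0, nf, nf)
    if (any(valid)) {
      G[valid, valid] <- stats::cor(M[, valid, drop = FALSE])
    }
    if (!all(valid))
      warning(sum(!valid), " frame(s) with zero ring variance masked to 0")
  } else {
    mns <- colMeans(M)
    valid <- mns > 0
    G <- crossprod(M) / npix / tcrossprod(ifelse(valid, mns, 1))
    G[!valid, ] <- 0; G[, !valid] <- 0
  }
  G <- (G + t(G)) / 2  # remove fp asymmetry
  new("TwoTimeCorrelation", G = G, times = series@times,
      qCenter = ring@qCenter, qHalfwidth = ring@qHalfwidth,
      ringSize = npix, validFrames = valid, estimator = estimator)
}

#' Contrast profile at a fixed off-diagonal offset
#'
#' `values[k] = G(k, k + offset)` indexed by the age time of the pair
#' midpoint, `t_age = (t_k + t_(k+offset))/2`.  The offset-1 profile is the
#' canonical "contrast one pixel away from the diagonal" whose oscillations
#' mark tail crossings.
#'
#' @param ttc a [TwoTimeCorrelation]
#' @param offset frame offset, `1 <= offset < nFrames`
#' @return a [ContrastProfile]
#' @export
contrastProfile <- function(ttc, offset = 1L) {
  stopifnot(is(ttc, "TwoTimeCorrelation"))
  n <- length(ttc@times)
  checkThat(offset >= 1L && offset < n, "offset",
            sprintf("must lie in [1, %d]", n - 1L))
  idx <- seq_len(n - offset)
  new("ContrastProfile",
      values = ttc@G[cbind(idx, idx + offset)],
      ageTimes = (ttc@times[idx] + ttc@times[idx + offset]) / 2,
      offset = as.integer(offset))
}

#' g2-like cut through a TTC at fixed age
#'
#' Row mode returns `G(t_age, t_age + tau)` for `tau >= 0`; diagonal-band
#' mode averages over a band of `bandWidth` ages centred on `t_age`
#' (truncated at the matrix edge with a warning).  The value at `tau = 0`
#' equals the diagonal value (1 for valid frames).
#'
#' @param ttc a [TwoTimeCorrelation]
#' @param tAge age time of the cut (snapped to the nearest frame)
#' @param mode `"row"` or `"diagonal_band"`
#' @param bandWidth band size in frames (diagonal_band mode)
#' @return a [G2Cut]
#' @export
g2Cut <- function(ttc, tAge, mode = c("row", "diagonal_band"),
                  bandWidth = 5L) {
  stopifnot(is(ttc, "TwoTimeCorrelation"))
  mode <- match.arg(mode)
  n <- length(ttc@times)
  checkThat(tAge >= min(ttc@times) && tAge <= max(ttc@times), "tAge",
            "outside the time range")
  i <- which.min(abs(ttc@times - tAge))
  if (mode == "row") {
    vals <- ttc@G[i, i:n]
    tau <- ttc@times[i:n] - ttc@times[i]
  } else {
    half <- (bandWidth - 1L) %/% 2L
    rows <- (i - half):(i + half)
    if (any(rows < 1L) || any(rows > n)) {
      warning("diagonal band truncated at the matrix edge")
      rows <- rows[rows >= 1L & rows <= n]
    }
    maxTau <- n - max(rows)
    tau <- (0:maxTau) * (ttc@times[2] - ttc@times[1])
    vals <- vapply(0:maxTau, function(k)
      mean(ttc@G[cbind(rows, rows + k)]), numeric(1))
  }
  new("G2Cut", values = vals, tau = tau, tAge = ttc@times[i], mode = mode)
}

#' Relaxation time of a correlation decay
#'
#' Threshold method: first delay where the correlation falls below `1/e`,
#' linearly interpolated between samples.  KWW method: least-squares fit of
#' the stretched-exponential intensity-correlation form
#' `G(tau) = exp(-2 (tau/tau_r)^gamma)` (the factor 2 reflects that an
#' amplitude decorrelation enters the intensity correlation squared),
#' returning the relaxation time and Kohlrausch exponent.  A cut that never
#' decays below threshold returns a no-decay signal (`noDecay = TRUE`),
#' distinct from a fit failure (error).
#'
#' @param cut a [G2Cut]
#' @param method `"threshold"` or `"kww"`
#' @return list with `tau`, `gamma` (KWW only), `noDecay`
#' @export
relaxationTime <- function(cut, method = c("threshold", "kww")) {
  stopifnot(is(cut, "G2Cut"))
  method <- match.arg(method)
  v <- cut@values; tau <- cut@tau
  thr <- exp(-1)
  below <- which(v < thr)
  if (!length(below))
    return(list(tau = NA_real_, gamma = NA_real_, noDecay = TRUE))
  i <- below[1]
  tThr <- if (i == 1L) tau[1]
  else tau[i - 1] + (thr - v[i - 1]) * (tau[i] - tau[i - 1]) /
    (v[i] - v[i - 1])
  if (method == "threshold")
    return(list(tau = tThr, gamma = NA_real_, noDecay = FALSE))
  # KWW: tau_r such that exp(-2 (tau/tau_r)^gamma) = 1/e at tau = tThr
  # gives the start value tau_r = tThr * 2^(1/gamma), gamma = 1
  df <- data.frame(tau = tau[tau > 0 | v < 1], v = v[tau > 0 | v < 1])
  fit <- minpack.lm::nlsLM(v ~ exp(-2 * (tau / tr)^g), data = df,
                           start = list(tr = 2 * tThr, g = 1),
                           lower = c(1e-10, 0.05), upper = c(Inf, 5),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  list(tau = unname(co["tr"]), gamma = unname(co["g"]), noDecay = FALSE)
}

#' Pearson correlation between two TTC matrices
#'
#' Overall similarity of two two-time correlation maps on the same frame
#' grid (vectorized over all entries); the binarization-invariance check
#' compares the TTC of a phase-field series with that of its binarized
#' counterpart this way.
#'
#' @param ttc1,ttc2 [TwoTimeCorrelation] objects on the same frames
#' @return Pearson r over matrix entries
#' @export
ttcSimilarity <- function(ttc1, ttc2) {
  stopifnot(is(ttc1, "TwoTimeCorrelation"), is(ttc2, "TwoTimeCorrelation"),
            all(dim(ttc1@G) == dim(ttc2@G)))
  stats::cor(as.vector(ttc1@G), as.vector(ttc2@G))
}

#' Mean off-diagonal value of a TTC
#'
#' The plateau statistic used for the Brownian limits: averages `G(t1, t2)`
#' over all pairs with `|t1 - t2|` at least `minLag` frames.
#'
#' @param ttc a [TwoTimeCorrelation]
#' @param minLag minimum frame separation (default 1 = all off-diagonal)
#' @return mean off-diagonal correlation
#' @export
meanOffDiagonal <- function(ttc, minLag = 1L) {
  n <- length(ttc@times)
  lag <- abs(outer(seq_len(n), seq_len(n), `-`))
  mean(ttc@G[lag >= minLag])
}
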