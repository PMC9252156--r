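# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# fftshift for matrices: move the zero-frequency element to the centre.
fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  m[c((s1 + 1):n1, 1:s1), c((s2 + 1):n2, 1:s2)]
}

# Signed integer FFT frequencies 0, 1, ..., n/2-1, -n/2, ..., -1.
fftFreqs <- function(n) {
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1)
  k[seq_len(n)]
}

# Centered moving average with window w (odd); edges use truncated windows.
movingAverage <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  half <- floor(w / 2)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

# Indices of interior local maxima of x with prominence >= prom.
# Prominence of a peak: height minus the higher of the two valley minima
# separating it from taller terrain (standard topographic definition;
# profiles here are short, so the O(n * peaks) scan is fine).
localMaxima <- function(x, prom = 0) {
  n <- length(x)
  if (n < 3L) return(integer())
  # plateaus count once, at their first index
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[cand > 1L & cand < n]
  if (!length(cand)) return(integer())
  keep <- vapply(cand, function(i) {
    h <- x[i]
    # walk left until terrain exceeds h (or edge); valley min on the way
    lv <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) { lv <- min(lv, x[j]); j <- j - 1L }
    if (j < 1L) lv <- min(lv, min(x[1:i]))
    rv <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) { rv <- min(rv, x[j]); j <- j + 1L }
    if (j > n) rv <- min(rv, min(x[i:n]))
    (h - max(lv, rv)) >= prom
  }, logical(1))
  cand[keep]
}

# Parameter-validation helper: stops with the offending field named.
checkThat <- function(ok, field, what) {
  if (!ok) stop(sprintf("invalid parameter '%s': %s", field, what),
                call. = FALSE)
  invisible(TRUE)
}

# Periodic wrap of coordinates into [0, n).
wrapPeriodic <- function(x, n) {
  y <- x %% n
  # guard against negative-zero artefacts of %% on exact negatives
  y[y == n] <- 0
  y
}
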