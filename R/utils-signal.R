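#' @importFrom stats sd median quantile fft rnorm runif rlnorm approx convolve
#'   prcomp cor lm pf coef fitted aggregate complete.cases runmed var setNames
#'   dist rbinom rexp
#' @importFrom rlang .data abort warn
NULL

#' z-score a numeric vector
#'
#' Centres and scales by the sample standard deviation. A zero-variance input
#' returns all zeros (so downstream peak detectors find nothing) rather than
#' erroring; this is the convention used by every detector in the package.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Zero-phase Butterworth filtering
#'
#' Forward-backward (`signal::filtfilt`) Butterworth filtering, so event times
#' are not shifted by filter group delay. `bandpass_zerophase` designs a
#' single band-pass section; `lowpass_zerophase`/`highpass_zerophase` design
#' one-sided filters.
#'
#' @param x numeric signal.
#' @param lo,hi passband edges in Hz.
#' @param fs sampling rate in Hz.
#' @param poles filter order (poles of the analogue prototype).
#' @return filtered numeric vector, same length as `x`.
#' @export
bandpass_zerophase <- function(x, lo, hi, fs, poles = 3) {
  nyq <- fs / 2
  if (!(lo > 0 && lo < hi && hi < nyq)) {
    abort(sprintf("infeasible band [%g, %g] Hz at fs = %g Hz", lo, hi, fs))
  }
  b <- signal::butter(poles, c(lo, hi) / nyq, type = "pass")
  as.numeric(signal::filtfilt(b, x))
}

#' @rdname bandpass_zerophase
#' @param cutoff cutoff frequency in Hz.
#' @export
lowpass_zerophase <- function(x, cutoff, fs, poles = 2) {
  nyq <- fs / 2
  if (!(cutoff > 0 && cutoff < nyq)) {
    abort(sprintf("infeasible cutoff %g Hz at fs = %g Hz", cutoff, fs))
  }
  b <- signal::butter(poles, cutoff / nyq, type = "low")
  as.numeric(signal::filtfilt(b, x))
}

#' @rdname bandpass_zerophase
#' @export
highpass_zerophase <- function(x, cutoff, fs, poles = 3) {
  nyq <- fs / 2
  if (!(cutoff > 0 && cutoff < nyq)) {
    abort(sprintf("infeasible cutoff %g Hz at fs = %g Hz", cutoff, fs))
  }
  b <- signal::butter(poles, cutoff / nyq, type = "high")
  as.numeric(signal::filtfilt(b, x))
}

# Local maxima of x with plateau handling: a run of equal values is a single
# candidate peak at its (floor) midpoint, kept when strictly higher than both
# neighbouring runs. Returns integer indices.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  r <- rle(x)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  v <- r$values
  is_pk <- c(FALSE, v[2:(k - 1)] > v[1:(k - 2)] & v[2:(k - 1)] > v[3:k], FALSE)
  idx <- which(is_pk)
  as.integer(floor((starts[idx] + ends[idx]) / 2))
}

# Topographic prominence: height above the higher of the two key saddles,
# where each side extends to the nearest strictly-higher sample (or the
# signal edge).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    i <- p - 1L
    lmin <- h
    while (i >= 1L && x[i] <= h) {
      if (x[i] < lmin) lmin <- x[i]
      i <- i - 1L
    }
    j <- p + 1L
    rmin <- h
    n <- length(x)
    while (j <= n && x[j] <= h) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Peak detection with height, prominence and separation constraints
#'
#' Finds local maxima of a signal, then filters by minimum height, minimum
#' topographic prominence (height above the higher of the two flanking
#' saddles) and minimum separation. When two surviving peaks are closer than
#' `min_separation`, the lower one is discarded.
#'
#' @param x numeric signal.
#' @param min_height minimum peak value, or `NULL` for no constraint.
#' @param min_prominence minimum prominence, or `NULL`.
#' @param min_separation minimum index separation between kept peaks.
#' @return integer vector of peak indices, ascending.
#' @export
find_peaks <- function(x, min_height = NULL, min_prominence = NULL,
                       min_separation = 0) {
  pk <- local_maxima(x)
  if (!is.null(min_height)) pk <- pk[x[pk] >= min_height]
  if (length(pk) && !is.null(min_prominence)) {
    pk <- pk[peak_prominence(x, pk) >= min_prominence]
  }
  if (length(pk) > 1L && min_separation > 0) {
    ord <- pk[order(x[pk], decreasing = TRUE)]
    kept <- integer(0)
    for (p in ord) {
      if (!length(kept) || all(abs(kept - p) >= min_separation)) {
        kept <- c(kept, p)
      }
    }
    pk <- sort(kept)
  }
  pk
}

# Longest run of TRUE; returns c(length, start_index) (0, NA if none).
longest_true_run <- function(mask) {
  r <- rle(mask)
  if (!any(r$values)) return(c(0L, NA_integer_))
  lens <- r$lengths
  lens[!r$values] <- 0L
  i <- which.max(lens)
  start <- if (i == 1L) 1L else sum(r$lengths[1:(i - 1L)]) + 1L
  c(r$lengths[i], start)
}

# Sliding k-point median across a vector (channel axis); shrunken windows at
# the edges so the output has the same length.
median_across <- function(v, k = 5) {
  n <- length(v)
  if (n <= 2 || k <= 1) return(v)
  half <- floor(k / 2)
  vapply(seq_len(n), function(i) {
    stats::median(v[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

# Deterministic evaluation under a seed without disturbing the caller's RNG.
with_sim_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# von Mises sampler (Best & Fisher rejection scheme); used for circular
# statistics power checks.
#' Draw from a von Mises distribution
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration; `0` gives the uniform circular distribution.
#' @return numeric vector of angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      theta <- mu + sign(u[3] - 0.5) * acos(f)
      out[i] <- theta %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

#' Polyphase rational-ratio resampling
#'
#' Resamples `x` by the rational factor `p/q` (upsample by zero-stuffing,
#' low-pass with a Blackman-windowed sinc anti-alias filter, downsample),
#' with the kernel centred so the output is delay-free. Passband gain is
#' flat to well under 0.1%.
#'
#' @param x numeric signal.
#' @param p,q integer up/down factors (coprime).
#' @param half_lobes half-width of the sinc kernel, in zero crossings.
#' @return resampled signal of length `ceiling(length(x) * p / q)`.
#' @export
resample_poly <- function(x, p, q, half_lobes = 16) {
  p <- as.integer(p); q <- as.integer(q)
  if (p == q) return(x)
  n <- length(x)
  up <- numeric(n * p)
  up[seq(1, n * p, by = p)] <- x
  m <- half_lobes * max(p, q)
  j <- seq(-m, m)
  fc <- 1 / max(p, q)                      # cutoff, fraction of Nyquist
  h <- fc * sinc_fn(fc * j) *
    (0.42 + 0.5 * cos(pi * j / m) + 0.08 * cos(2 * pi * j / m))
  h <- p * h / sum(h) * 1                  # unit DC gain after zero-stuffing
  xc <- stats::convolve(up, rev(h), type = "open")[(m + 1):(m + n * p)]
  xc[seq(1, n * p, by = q)]
}

sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
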