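#' Morlet wavelet spectrogram
#'
#' Continuous wavelet transform with a complex Morlet wavelet (bandwidth 1.5,
#' centre frequency 1.0) at 100 logarithmically spaced frequencies between 1
#' and 100 Hz, computed by FFT convolution with L1-normalized kernels (so a
#' pure tone excites every scale equally). The magnitude is normalized by its
#' maximum, giving values between 0 and 1.
#'
#' @param x numeric signal (>= 1 s).
#' @param fs sampling rate, Hz.
#' @param freqs_hz analysis frequencies; default 100 log-spaced in 1-100 Hz.
#' @param bandwidth Morlet bandwidth parameter.
#' @param center_freq Morlet centre frequency parameter.
#' @return object of class `cs_spectrogram`: list with `freq_hz`, `time_s`
#'   and `magnitude` (frequency x time, max 1).
#' @export
wavelet_spectrogram <- function(x, fs,
                                freqs_hz = 10^seq(0, 2, length.out = 100),
                                bandwidth = 1.5, center_freq = 1) {
  if (!length(x)) abort("empty signal")
  if (length(x) < fs) abort("signal must be at least 1 s long")
  n <- length(x)
  scales <- center_freq * fs / freqs_hz        # samples per wavelet time unit
  half_len <- ceiling(4 * sqrt(bandwidth / 2) * max(scales))
  nfft <- 2^ceiling(log2(n + 2 * half_len + 1))
  xf <- stats::fft(c(x, rep(0, nfft - n)))
  mag <- matrix(0, nrow = length(freqs_hz), ncol = n)
  for (i in seq_along(freqs_hz)) {
    a <- scales[i]
    hl <- ceiling(4 * sqrt(bandwidth / 2) * a)
    tt <- seq(-hl, hl) / a
    kern <- exp(-tt^2 / bandwidth) * exp(1i * 2 * pi * center_freq * tt)
    kern <- kern / sum(Mod(kern))
    kv <- complex(length.out = nfft)
    kv[1:(hl + 1)] <- kern[(hl + 1):(2 * hl + 1)]       # causal half
    kv[(nfft - hl + 1):nfft] <- kern[1:hl]              # anti-causal half
    y <- stats::fft(xf * stats::fft(kv), inverse = TRUE) / nfft
    mag[i, ] <- Mod(y[1:n])
  }
  mx <- max(mag)
  if (mx > 0) mag <- mag / mx
  structure(list(freq_hz = freqs_hz, time_s = (seq_len(n) - 1) / fs,
                 magnitude = mag),
            class = "cs_spectrogram")
}

#' @export
print.cs_spectrogram <- function(x, ...) {
  cat(sprintf("<cs_spectrogram> %d frequencies (%.3g-%.3g Hz) x %d samples\n",
              length(x$freq_hz), min(x$freq_hz), max(x$freq_hz),
              length(x$time_s)))
  invisible(x)
}

# DPSS (Slepian) tapers from the symmetric tridiagonal formulation;
# cached per (n, nw, k).
.dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw = 5, k = 9) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  w <- nw / n
  i <- seq_len(n) - 1
  dg <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  od <- (seq_len(n - 1) * (n - seq_len(n - 1))) / 2
  m <- diag(dg)
  m[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- od
  m[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- od
  eg <- eigen(m, symmetric = TRUE)
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  # normalize and fix sign convention (positive mean / initial lobe)
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    s <- sum(v[, j])
    if ((s != 0 && s < 0) || (s == 0 && v[2, j] < 0)) v[, j] <- -v[, j]
  }
  .dpss_cache[[key]] <- v
  v
}

#' Multitaper power spectrum
#'
#' Averaged multitaper (DPSS/Slepian) power spectral density over
#' non-overlapping 1-s chunks, with time-bandwidth product `nw = 5` and
#' `k = 9` tapers. The one-sided density is scaled so that its integral over
#' frequency equals the signal variance.
#'
#' @param x numeric signal (>= 1 s).
#' @param fs sampling rate, Hz.
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @param chunk_s chunk length, seconds.
#' @return tibble with columns `freq_hz`, `power` (uV^2/Hz for uV input) and
#'   attribute `n_chunks`.
#' @export
multitaper_spectrum <- function(x, fs, nw = 5, k = 9, chunk_s = 1) {
  n_chunk_len <- round(fs * chunk_s)
  n_chunks <- floor(length(x) / n_chunk_len)
  if (n_chunks < 1) abort("signal must be at least one chunk long")
  v <- dpss_tapers(n_chunk_len, nw, k)
  nf <- floor(n_chunk_len / 2) + 1
  acc <- numeric(nf)
  for (c in seq_len(n_chunks)) {
    seg <- x[((c - 1) * n_chunk_len + 1):(c * n_chunk_len)]
    p <- numeric(nf)
    for (j in seq_len(k)) {
      sp <- Mod(stats::fft(seg * v[, j]))^2 / fs
      p <- p + sp[seq_len(nf)]
    }
    acc <- acc + p / k
  }
  s <- acc / n_chunks
  # one-sided: double everything except DC (and Nyquist when present)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (n_chunk_len %% 2 == 0) dbl[nf] <- 1
  s <- s * dbl
  out <- tibble::tibble(freq_hz = (seq_len(nf) - 1) * fs / n_chunk_len,
                        power = s)
  attr(out, "n_chunks") <- n_chunks
  out
}
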