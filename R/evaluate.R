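#' Score detected event times against ground truth
#'
#' Greedy one-to-one matching of detected to true event times within a
#' tolerance, reporting true/false positives, misses, recall and precision.
#' Used to validate detectors against the synthetic generators' truth logs.
#'
#' @param detected detected event times, seconds.
#' @param truth true event times, seconds.
#' @param tol_s matching tolerance, seconds.
#' @return one-row tibble: `tp`, `fp`, `fn`, `recall`, `precision`.
#' @export
match_event_times <- function(detected, truth, tol_s = 2) {
  used <- rep(FALSE, length(truth))
  tp <- 0L
  for (t in detected) {
    d <- abs(truth - t)
    d[used] <- Inf
    if (length(d) && min(d) <= tol_s) {
      tp <- tp + 1L
      used[which.min(d)] <- TRUE
    }
  }
  tibble::tibble(
    tp = tp, fp = length(detected) - tp, fn = length(truth) - tp,
    recall = if (length(truth)) tp / length(truth) else NA_real_,
    precision = if (length(detected)) tp / length(detected) else NA_real_)
}

#' Restrict detected events to QS intervals of a schedule
#'
#' Flash detection operates on QS data (AS and wake periods are annotated
#' separately), so detections falling inside AS or wake intervals are
#' discarded before scoring.
#'
#' @param times_s event times, seconds.
#' @param schedule a [state_schedule()].
#' @return the subset of `times_s` lying inside a `QS` interval.
#' @export
restrict_to_qs <- function(times_s, schedule) {
  qs <- schedule[schedule$label == "QS", ]
  keep <- vapply(times_s, function(t) {
    any(t >= qs$start_s & t <= qs$end_s)
  }, logical(1))
  times_s[keep]
}

#' Dominant frequency of an oscillatory event
#'
#' Estimates the dominant frequency of a short oscillatory segment from the
#' zero-padded periodogram peak with quadratic interpolation.
#'
#' @param x numeric segment containing the event.
#' @param fs sampling rate, Hz.
#' @param band search band, Hz.
#' @return frequency in Hz.
#' @export
dominant_frequency <- function(x, fs, band = c(4, 40)) {
  x <- x - mean(x)
  n <- length(x)
  nfft <- 2^ceiling(log2(n * 8))
  p <- Mod(stats::fft(c(x * 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1))),
                        rep(0, nfft - n))))^2
  fr <- (seq_len(nfft) - 1) * fs / nfft
  sel <- which(fr >= band[1] & fr <= band[2])
  i <- sel[which.max(p[sel])]
  # quadratic interpolation around the peak bin
  if (i > 1 && i < nfft) {
    a <- p[i - 1]; b <- p[i]; c <- p[i + 1]
    delta <- 0.5 * (a - c) / (a - 2 * b + c)
    if (is.finite(delta) && abs(delta) <= 0.5) {
      return((i - 1 + delta) * fs / nfft)
    }
  }
  fr[i]
}
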