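gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Preprocess a raw LFP recording
#'
#' Standard preprocessing chain: polyphase resampling to `resample_to_hz`
#' (default 1 kHz from the 2.5 kHz acquisition rate), zero-phase band-pass
#' filtering 0.1-150 Hz (three-pole Butterworth), then common-mode removal by
#' subtracting, at every sample, the median of the out-of-brain channels from
#' every channel. Because the reference channels pass through the identical
#' resampling and filtering, any signal common to all channels is removed
#' exactly.
#'
#' @param rec an [lfp_recording()]; must contain out-of-brain channels.
#' @param resample_to_hz target rate, Hz.
#' @param band passband edges, Hz.
#' @param poles Butterworth order.
#' @return a new [lfp_recording()] at `resample_to_hz`.
#' @export
preprocess_lfp <- function(rec, resample_to_hz = 1000, band = c(0.1, 150),
                           poles = 3) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (rec$fs_hz < 300) abort("sampling rate below 300 Hz; not LFP-band data")
  ob <- which(!rec$channels$in_brain)
  if (!length(ob)) abort("no out-of-brain channels available for re-referencing")
  g <- gcd2(resample_to_hz, rec$fs_hz)
  p <- resample_to_hz / g; q <- rec$fs_hz / g
  resampled <- t(apply(rec$data, 1, function(x) resample_poly(x, p, q)))
  filtered <- t(apply(resampled, 1, function(x) {
    bandpass_zerophase(x, band[1], band[2], resample_to_hz, poles)
  }))
  ref <- apply(filtered[ob, , drop = FALSE], 2, stats::median)
  out <- sweep(filtered, 2, ref, `-`)
  lfp_recording(out, resample_to_hz, rec$channels)
}

#' Extract state-labelled LFP segments
#'
#' Builds the analysis segments used for state comparisons: 60 s of data from
#' each AS or wake onset, the 60 s immediately preceding each AS onset as QS,
#' and 0.7-s windows centred on flash times. QS segments overlapping a wake
#' interval are removed; segments exceeding the record bounds are dropped
#' with a warning.
#'
#' @param rec a (preprocessed) [lfp_recording()].
#' @param schedule a [state_schedule()] with `AS` (and optionally `wake`)
#'   intervals.
#' @param flash_times_s optional flash times for `flash` segments.
#' @param state_window_s AS/QS/wake segment length, seconds.
#' @param flash_window_s flash segment length, seconds.
#' @return tibble with columns `label`, `start_s`, `end_s` and list-column
#'   `data` (channels x samples matrices).
#' @export
extract_state_segments <- function(rec, schedule, flash_times_s = numeric(0),
                                   state_window_s = 60, flash_window_s = 0.7) {
  stopifnot(inherits(rec, "lfp_recording"))
  dur <- ncol(rec$data) / rec$fs_hz
  wake_iv <- schedule[schedule$label == "wake", ]
  rows <- list()
  dropped <- 0L
  add_seg <- function(label, a, b) {
    if (a < 0 || b > dur + 1e-9) { dropped <<- dropped + 1L; return() }
    if (label == "QS" && nrow(wake_iv) &&
        any(wake_iv$start_s < b & wake_iv$end_s > a)) return()
    i0 <- floor(a * rec$fs_hz) + 1
    i1 <- min(ncol(rec$data), floor(b * rec$fs_hz))
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      label = label, start_s = a, end_s = b,
      data = list(rec$data[, i0:i1, drop = FALSE]))
  }
  for (i in which(schedule$label == "AS")) {
    on <- schedule$start_s[i]
    add_seg("QS", on - state_window_s, on)
    add_seg("AS", on, on + state_window_s)
  }
  for (i in which(schedule$label == "wake")) {
    add_seg("wake", schedule$start_s[i],
            schedule$start_s[i] + state_window_s)
  }
  for (ft in flash_times_s) {
    add_seg("flash", ft - flash_window_s / 2, ft + flash_window_s / 2)
  }
  if (dropped) warn(sprintf("%d segment(s) exceeded record bounds and were dropped",
                            dropped))
  if (!length(rows)) {
    return(tibble::tibble(label = character(0), start_s = numeric(0),
                          end_s = numeric(0), data = list()))
  }
  dplyr::bind_rows(rows)
}
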