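#' QS oscillatory-event detection parameters
#'
#' Defaults follow the published settings: 4-40 Hz band-pass, peaks on the
#' z-scored filtered signal with minimum height 2, minimum prominence 2 and
#' minimum separation 1 s; 1200-s QS windows; a 5-channel median filter on
#' the per-channel rates.
#'
#' @param band_hz detection passband, Hz.
#' @param min_height_z,min_prominence_z peak constraints, z-units.
#' @param min_separation_s minimum event separation, seconds.
#' @param qs_window_s QS window loaded before each AS bout, seconds.
#' @param flash_window_s flash-proximity window (see
#'   [fraction_near_flashes()]), seconds.
#' @param median_channels sliding-median width across channels.
#' @return list of class `osc_event_params`.
#' @export
osc_event_params <- function(band_hz = c(4, 40), min_height_z = 2,
                             min_prominence_z = 2, min_separation_s = 1,
                             qs_window_s = 1200, flash_window_s = 0.7,
                             median_channels = 5) {
  stopifnot(band_hz[1] > 0, band_hz[1] < band_hz[2], min_separation_s > 0)
  structure(as.list(environment()), class = "osc_event_params")
}

#' Extract long QS windows preceding AS bouts
#'
#' Loads up to `window_s` of data immediately preceding each AS onset and
#' removes any wake intervals by splitting the window into wake-free
#' sub-segments. These are the segments scanned for spindle-like oscillatory
#' events.
#'
#' @param rec a (preprocessed) [lfp_recording()].
#' @param schedule a [state_schedule()].
#' @param window_s window length before each AS onset, seconds.
#' @param min_len_s sub-segments shorter than this are discarded.
#' @return segment tibble as in [extract_state_segments()].
#' @export
extract_qs_chunks <- function(rec, schedule, window_s = 1200, min_len_s = 5) {
  stopifnot(inherits(rec, "lfp_recording"))
  wake_iv <- schedule[schedule$label == "wake", ]
  as_on <- schedule$start_s[schedule$label == "AS"]
  as_iv <- schedule[schedule$label == "AS", ]
  rows <- list()
  for (on in as_on) {
    a <- max(0, on - window_s); b <- on
    # subtract wake and other AS bouts from [a, b]
    cuts <- rbind(as.matrix(wake_iv[, c("start_s", "end_s")]),
                  as.matrix(as_iv[as_iv$start_s < on, c("start_s", "end_s")]))
    segs <- list(c(a, b))
    if (nrow(cuts)) for (i in seq_len(nrow(cuts))) {
      segs <- unlist(lapply(segs, function(s) {
        if (cuts[i, 1] >= s[2] || cuts[i, 2] <= s[1]) return(list(s))
        out <- list()
        if (cuts[i, 1] > s[1]) out <- c(out, list(c(s[1], cuts[i, 1])))
        if (cuts[i, 2] < s[2]) out <- c(out, list(c(cuts[i, 2], s[2])))
        out
      }), recursive = FALSE)
    }
    for (s in segs) {
      s <- as.numeric(s)
      if (s[2] - s[1] < min_len_s) next
      i0 <- floor(s[1] * rec$fs_hz) + 1
      i1 <- min(ncol(rec$data), floor(s[2] * rec$fs_hz))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        label = "QS", start_s = s[1], end_s = s[2],
        data = list(rec$data[, i0:i1, drop = FALSE]))
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(label = character(0), start_s = numeric(0),
                          end_s = numeric(0), data = list()))
  }
  dplyr::bind_rows(rows)
}

#' Detect spindle-like oscillatory events in QS segments
#'
#' Per channel and QS segment: zero-phase band-pass filter (4-40 Hz),
#' per-segment z-scoring, then peak detection with the configured height,
#' prominence and separation constraints. Event rates are computed per
#' segment (events per second, equal weighting across segments), averaged,
#' and smoothed with a 5-channel sliding median across the channel axis.
#' Zero-variance segments contribute no events.
#'
#' @param qs_segments segment tibble (e.g. from [extract_qs_chunks()]).
#' @param fs sampling rate of the segment data, Hz.
#' @param params an [osc_event_params()].
#' @return list with `events` (tibble `channel`, `time_s`, `height_z`) and
#'   `rates` (tibble `channel`, `rate_hz` raw, `rate_hz_med` median-filtered).
#' @export
detect_osc_events <- function(qs_segments, fs, params = osc_event_params()) {
  data_list <- qs_segments$data
  if (!length(data_list)) abort("no QS segments supplied")
  n_ch <- nrow(data_list[[1]])
  sep <- round(params$min_separation_s * fs)
  ev_rows <- list()
  rate_mat <- matrix(0, nrow = n_ch, ncol = length(data_list))
  for (s in seq_along(data_list)) {
    m <- data_list[[s]]
    dur <- ncol(m) / fs
    for (ch in seq_len(n_ch)) {
      if (stats::sd(m[ch, ]) == 0) next
      xf <- bandpass_zerophase(m[ch, ], params$band_hz[1], params$band_hz[2],
                               fs, 3)
      z <- zscore(xf)
      pk <- find_peaks(z, min_height = params$min_height_z,
                       min_prominence = params$min_prominence_z,
                       min_separation = sep)
      if (length(pk)) {
        ev_rows[[length(ev_rows) + 1L]] <- tibble::tibble(
          channel = ch,
          time_s = qs_segments$start_s[s] + (pk - 1) / fs,
          height_z = z[pk])
      }
      rate_mat[ch, s] <- length(pk) / dur
    }
  }
  events <- if (length(ev_rows)) dplyr::bind_rows(ev_rows) else
    tibble::tibble(channel = integer(0), time_s = numeric(0),
                   height_z = numeric(0))
  raw <- rowMeans(rate_mat)
  list(events = dplyr::arrange(events, .data$channel, .data$time_s),
       rates = tibble::tibble(channel = seq_len(n_ch), rate_hz = raw,
                              rate_hz_med = median_across(raw,
                                                          params$median_channels)))
}

#' Fraction of events occurring near flashes
#'
#' Fraction of oscillatory events whose time lies within `window_s` seconds
#' (two-sided) of any QS colour flash.
#'
#' @param event_times sorted event times, seconds.
#' @param flash_times sorted flash times, seconds.
#' @param window_s proximity window, seconds.
#' @return scalar fraction between 0 and 1.
#' @export
fraction_near_flashes <- function(event_times, flash_times, window_s = 10) {
  if (!length(event_times)) abort("no events supplied")
  if (!length(flash_times)) return(0)
  fl <- sort(flash_times)
  idx <- findInterval(event_times, fl)
  d_lo <- ifelse(idx >= 1, event_times - fl[pmax(idx, 1)], Inf)
  d_hi <- ifelse(idx < length(fl), fl[pmin(idx + 1, length(fl))] - event_times,
                 Inf)
  mean(pmin(d_lo, d_hi) <= window_s)
}
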