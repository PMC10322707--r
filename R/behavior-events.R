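#' Flash detection parameters
#'
#' Defaults follow the published detection settings: band-pass 0.005-2 Hz
#' with a three-pole Butterworth filter, then peaks on the negated z-scored
#' signal with minimum height 2, minimum prominence 0.5 and minimum
#' separation 10 s.
#'
#' @param band_hz length-2 passband (Hz).
#' @param filter_poles Butterworth order.
#' @param min_height_z,min_prominence_z peak constraints in z-units.
#' @param min_separation_s minimum peak separation, seconds.
#' @return list of class `flash_detect_params`.
#' @export
flash_detect_params <- function(band_hz = c(0.005, 2), filter_poles = 3,
                                min_height_z = 2, min_prominence_z = 0.5,
                                min_separation_s = 10) {
  stopifnot(length(band_hz) == 2, band_hz[1] > 0, band_hz[1] < band_hz[2])
  structure(as.list(environment()), class = "flash_detect_params")
}

#' Detect QS colour flashes in a brightness trace
#'
#' Band-pass filters the mean-skin-brightness trace (zero-phase), negates and
#' z-scores it (flashes are brightness decreases), and returns the times of
#' peaks satisfying the height, prominence and separation constraints.
#' A zero-variance trace yields no detections.
#'
#' @param trace a [brightness_trace()] (any data frame with `time_s`,
#'   `value`).
#' @param params a [flash_detect_params()].
#' @return tibble with columns `time_s` and `height_z`, ascending in time.
#' @export
detect_flashes <- function(trace, params = flash_detect_params()) {
  check_trace(trace)
  fps <- trace_fps(trace)
  if (params$band_hz[2] >= fps / 2) {
    abort(sprintf("band upper edge %g Hz infeasible at fps %g",
                  params$band_hz[2], fps))
  }
  if (nrow(trace) < 2 / params$band_hz[1] * fps / 100) {
    abort("trace too short for the requested low band edge")
  }
  if (stats::sd(trace$value) == 0) {
    return(tibble::tibble(time_s = numeric(0), height_z = numeric(0)))
  }
  # demean first: filtfilt startup transients on the raw 8-bit offset would
  # otherwise dominate the variance
  filt <- bandpass_zerophase(trace$value - mean(trace$value),
                             params$band_hz[1], params$band_hz[2],
                             fps, params$filter_poles)
  z <- zscore(-filt)
  pk <- find_peaks(z, min_height = params$min_height_z,
                   min_prominence = params$min_prominence_z,
                   min_separation = round(params$min_separation_s * fps))
  tibble::tibble(time_s = trace$time_s[pk], height_z = z[pk])
}

#' Detect colour flashes within the QS intervals of a schedule
#'
#' The published procedure detects flashes on the brightness trace during
#' QS: AS bouts and wake are annotated separately, and each QS interval is
#' filtered, z-scored and scanned on its own. This avoids the filter-ringing
#' false positives that deep AS excursions would otherwise inject near bout
#' edges. QS intervals shorter than twice the low-band period are skipped.
#'
#' @param trace a brightness trace.
#' @param schedule a [state_schedule()] with `QS` intervals (manual labels).
#' @param params a [flash_detect_params()].
#' @return tibble with columns `time_s` (in original trace time) and
#'   `height_z`.
#' @export
detect_flashes_qs <- function(trace, schedule, params = flash_detect_params()) {
  check_trace(trace)
  fps <- trace_fps(trace)
  qs <- schedule[schedule$label == "QS", ]
  min_len <- 2 / params$band_hz[1]
  out <- list()
  for (i in seq_len(nrow(qs))) {
    if (qs$end_s[i] - qs$start_s[i] < min_len) next
    i0 <- max(1, floor((qs$start_s[i] - trace$time_s[1]) * fps) + 1)
    i1 <- min(nrow(trace), floor((qs$end_s[i] - trace$time_s[1]) * fps))
    sub <- trace[i0:i1, ]
    attr(sub, "fps") <- fps
    det <- detect_flashes(sub, params)
    if (nrow(det)) out[[length(out) + 1L]] <- det
  }
  if (!length(out)) {
    return(tibble::tibble(time_s = numeric(0), height_z = numeric(0)))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$time_s)
}

#' Colour flash duration from threshold crossings
#'
#' Takes a window from 500 frames before the flash peak to 1000 frames after
#' (21 s / 42 s at 24 fps), z-scores the negated window, and returns the time
#' between the last crossing of the 2z threshold before the peak and the
#' first after it. A side with no crossing is clamped to the window edge and
#' flagged.
#'
#' @param trace a brightness trace.
#' @param peak_s flash peak time(s), seconds.
#' @param pre_frames,post_frames window extent in frames.
#' @param threshold_z crossing threshold, z-units.
#' @return tibble with columns `peak_s`, `duration_s`, `clamped`.
#' @export
flash_duration <- function(trace, peak_s, pre_frames = 500,
                           post_frames = 1000, threshold_z = 2) {
  check_trace(trace)
  fps <- trace_fps(trace)
  purrr::map_dfr(peak_s, function(pk) {
    c0 <- round((pk - trace$time_s[1]) * fps) + 1
    i0 <- c0 - pre_frames
    i1 <- c0 + post_frames
    if (i0 < 1 || i1 > nrow(trace)) {
      abort(sprintf("flash window around t=%g s does not fit in trace", pk))
    }
    w <- zscore(-trace$value[i0:i1])
    p <- pre_frames + 1   # peak position within window
    above <- w >= threshold_z
    clamped <- FALSE
    lo <- which(!above[seq_len(p)])
    if (length(lo)) {
      start <- max(lo) + 1
    } else {
      start <- 1; clamped <- TRUE
    }
    hi <- which(!above[p:length(w)])
    if (length(hi)) {
      end <- p + min(hi) - 2
    } else {
      end <- length(w); clamped <- TRUE
    }
    if (!above[p]) {          # sub-threshold event: full-window fallback
      start <- 1; end <- length(w); clamped <- TRUE
    }
    tibble::tibble(peak_s = pk, duration_s = (end - start + 1) / fps,
                   clamped = clamped)
  })
}

#' Bout-duration estimation parameters
#'
#' Defaults follow the published procedure: a window from 10 s before to
#' 100 s after the AS start, z-scored, low-pass filtered at 0.1 Hz with a
#' two-pole Butterworth filter, and thresholded at 0.2 z (a subjective match
#' to video-confirmed bout ends).
#'
#' @param pre_s,post_s window extent, seconds.
#' @param lowpass_hz low-pass cutoff, Hz.
#' @param lowpass_poles filter order.
#' @param threshold_z darkening threshold, z-units.
#' @return list of class `bout_duration_params`.
#' @export
bout_duration_params <- function(pre_s = 10, post_s = 100, lowpass_hz = 0.1,
                                 lowpass_poles = 2, threshold_z = 0.2) {
  stopifnot(pre_s > 0, post_s > 0, threshold_z > 0)
  structure(as.list(environment()), class = "bout_duration_params")
}

#' Estimate AS bout duration from a brightness trace
#'
#' For each AS start time, z-scores the surrounding window, low-pass filters
#' it and returns the length of the longest contiguous run below
#' `-threshold_z` (bouts are darkenings, i.e. negative excursions). When no
#' sample falls below threshold the duration is 0 and the row is flagged.
#'
#' @param trace a brightness trace.
#' @param start_s AS bout start time(s), seconds.
#' @param params a [bout_duration_params()].
#' @return tibble with columns `start_s`, `duration_s`, `flagged` (no sample
#'   below threshold) and `truncated` (the excursion reaches the window
#'   edge, so the bout outlasts the analysis window and the duration is a
#'   lower bound).
#' @export
estimate_bout_duration <- function(trace, start_s,
                                   params = bout_duration_params()) {
  check_trace(trace)
  fps <- trace_fps(trace)
  purrr::map_dfr(start_s, function(st) {
    i0 <- round((st - params$pre_s - trace$time_s[1]) * fps) + 1
    i1 <- round((st + params$post_s - trace$time_s[1]) * fps) + 1
    if (i0 < 1 || i1 > nrow(trace)) {
      abort(sprintf("bout window around t=%g s does not fit in trace", st))
    }
    w <- zscore(trace$value[i0:i1])
    wf <- lowpass_zerophase(w, params$lowpass_hz, fps, params$lowpass_poles)
    run <- longest_true_run(wf < -params$threshold_z)
    # the zero-phase low-pass relaxes to 0 at the window edges, so a bout
    # outlasting the window ends within about a filter time constant of it
    margin <- round(0.5 / params$lowpass_hz * fps)
    trunc <- run[1] > 0 &&
      (run[2] <= margin || run[2] + run[1] - 1L >= length(wf) - margin)
    tibble::tibble(start_s = st, duration_s = run[1] / fps,
                   flagged = run[1] == 0, truncated = trunc)
  })
}

#' Automatic AS bout-start detection (convenience)
#'
#' Bout starts were identified manually in the original protocol (brightness
#' trace plus video confirmation); this convenience detector thresholds the
#' low-pass-filtered, negated, z-scored trace and reports the onsets of
#' contiguous supra-threshold runs of at least `min_duration_s`. Runs closer
#' than `min_separation_s` are merged.
#'
#' @param trace a brightness trace.
#' @param lowpass_hz low-pass cutoff, Hz.
#' @param threshold_z onset threshold on the negated z-scored signal.
#' @param min_duration_s minimum excursion length, seconds.
#' @param min_separation_s merge window between runs, seconds.
#' @return tibble with columns `start_s`, `end_s`.
#' @export
detect_bout_starts <- function(trace, lowpass_hz = 0.1, threshold_z = 3.5,
                               min_duration_s = 20, min_separation_s = 30) {
  check_trace(trace)
  fps <- trace_fps(trace)
  z <- zscore(-lowpass_zerophase(trace$value, lowpass_hz, fps, 2))
  r <- rle(z > threshold_z)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(tibble::tibble(start_s = numeric(0),
                                           end_s = numeric(0)))
  iv <- cbind(starts[keep], ends[keep])
  # merge runs separated by less than min_separation_s
  merged <- list(iv[1, ])
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    last <- merged[[length(merged)]]
    if (iv[i, 1] - last[2] < min_separation_s * fps) {
      merged[[length(merged)]] <- c(last[1], iv[i, 2])
    } else merged[[length(merged) + 1]] <- iv[i, ]
  }
  iv <- do.call(rbind, merged)
  len_ok <- (iv[, 2] - iv[, 1] + 1) >= min_duration_s * fps
  iv <- iv[len_ok, , drop = FALSE]
  tibble::tibble(start_s = trace$time_s[iv[, 1]],
                 end_s = trace$time_s[iv[, 2]])
}

#' Flash rate across the normalized inter-bout interval
#'
#' Rescales every complete inter-bout interval to `[0, 1]`, bins the flashes
#' falling in it, converts counts to events/min using each interval's own
#' duration, and averages the per-interval rate profiles. Intervals
#' containing wake are not "complete" and are skipped when the schedule
#' carries wake labels.
#'
#' @param flash_times numeric flash times, seconds.
#' @param bout_schedule schedule tibble with `AS` intervals (and optionally
#'   `wake`), or a tibble with `start_s`/`end_s` of AS bouts.
#' @param n_bins number of bins across the normalized interval.
#' @return tibble with columns `bin_mid` (normalized time) and
#'   `rate_per_min`.
#' @export
flash_rate_profile <- function(flash_times, bout_schedule, n_bins = 10) {
  sched <- bout_schedule
  if ("label" %in% names(sched)) {
    as_iv <- sched[sched$label == "AS", ]
    wake_iv <- sched[sched$label == "wake", ]
  } else {
    as_iv <- sched
    wake_iv <- sched[0, ]
  }
  as_iv <- dplyr::arrange(as_iv, .data$start_s)
  if (nrow(as_iv) < 2) abort("need at least one complete inter-bout interval")
  profiles <- list()
  for (i in seq_len(nrow(as_iv) - 1)) {
    a <- as_iv$end_s[i]; b <- as_iv$start_s[i + 1]
    if (b <= a) next
    if (nrow(wake_iv) && any(wake_iv$start_s < b & wake_iv$end_s > a)) next
    u <- (flash_times[flash_times >= a & flash_times < b] - a) / (b - a)
    cnt <- tabulate(pmin(n_bins, floor(u * n_bins) + 1L), nbins = n_bins)
    bin_min <- (b - a) / n_bins / 60
    profiles[[length(profiles) + 1]] <- cnt / bin_min
  }
  if (!length(profiles)) abort("no complete inter-bout interval")
  rate <- Reduce(`+`, profiles) / length(profiles)
  tibble::tibble(bin_mid = (seq_len(n_bins) - 0.5) / n_bins,
                 rate_per_min = rate)
}
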