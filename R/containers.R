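#' Brightness and movement traces
#'
#' A trace is an ordinary tibble with columns `time_s` and `value`, carrying
#' the frame rate as an `fps` attribute. All detectors accept any data frame
#' with those two columns; the frame rate is taken from the attribute when
#' present and otherwise inferred from the median time step, so traces survive
#' round-trips through dplyr verbs and CSV files.
#'
#' `brightness_trace()` values are mean skin brightness in 8-bit units
#' (0-255); `movement_trace()` values are non-negative optic-flow movement
#' magnitudes.
#'
#' @param values numeric vector, one sample per frame.
#' @param fps frames per second (> 0).
#' @param t0 time of the first frame, seconds.
#' @return a tibble with columns `time_s`, `value` and attribute `fps`.
#' @export
brightness_trace <- function(values, fps, t0 = 0) {
  stopifnot(is.numeric(values), length(values) >= 2, fps > 0,
            all(is.finite(values)))
  out <- tibble::tibble(time_s = t0 + (seq_along(values) - 1) / fps,
                        value = as.numeric(values))
  attr(out, "fps") <- fps
  out
}

#' @rdname brightness_trace
#' @export
movement_trace <- function(values, fps, t0 = 0) {
  stopifnot(all(values >= 0))
  brightness_trace(values, fps, t0)
}

#' Frame rate of a trace
#'
#' Returns the `fps` attribute if present, otherwise the reciprocal of the
#' median time step.
#'
#' @param trace data frame with columns `time_s`, `value`.
#' @return frames per second.
#' @export
trace_fps <- function(trace) {
  fps <- attr(trace, "fps")
  if (!is.null(fps)) return(fps)
  dt <- stats::median(diff(trace$time_s))
  if (!is.finite(dt) || dt <= 0) abort("cannot infer fps from time_s column")
  1 / dt
}

check_trace <- function(trace) {
  if (!all(c("time_s", "value") %in% names(trace))) {
    abort("trace must have columns `time_s` and `value`")
  }
  if (nrow(trace) < 2) abort("trace must have at least 2 samples")
  if (!all(is.finite(trace$value))) abort("trace values must be finite")
  invisible(trace)
}

#' Labelled state schedules
#'
#' A state schedule is a tibble of labelled, non-overlapping-within-label
#' intervals in seconds: columns `label` (e.g. `"AS"`, `"QS"`, `"wake"`),
#' `start_s`, `end_s`.
#'
#' @param label character vector of state labels.
#' @param start_s,end_s interval bounds in seconds, `end_s > start_s`.
#' @return a tibble sorted by `start_s`.
#' @export
state_schedule <- function(label, start_s, end_s) {
  stopifnot(length(label) == length(start_s), length(start_s) == length(end_s))
  out <- tibble::tibble(label = as.character(label),
                        start_s = as.numeric(start_s),
                        end_s = as.numeric(end_s))
  if (nrow(out) && any(out$end_s <= out$start_s)) {
    abort("state_schedule intervals must have end_s > start_s")
  }
  out <- dplyr::arrange(out, .data$start_s)
  for (lb in unique(out$label)) {
    iv <- out[out$label == lb, ]
    if (nrow(iv) > 1 && any(iv$start_s[-1] < iv$end_s[-nrow(iv)] - 1e-9)) {
      abort(sprintf("overlapping `%s` intervals in schedule", lb))
    }
  }
  out
}

#' Multi-channel LFP recordings
#'
#' Container for a channels-by-samples local field potential array with its
#' sampling rate and a per-channel table of atlas coordinates, region labels,
#' probe identity and an in-brain flag. Out-of-brain channels supply the
#' common-mode reference used by [preprocess_lfp()].
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param fs_hz sampling rate, Hz.
#' @param channels tibble with one row per channel: columns `channel`,
#'   `x_um`, `y_um`, `z_um`, `region`, `probe`, `in_brain`.
#' @return an object of class `lfp_recording`.
#' @export
lfp_recording <- function(data, fs_hz, channels) {
  stopifnot(is.matrix(data), fs_hz > 0, nrow(data) == nrow(channels))
  need <- c("channel", "x_um", "y_um", "z_um", "region", "probe", "in_brain")
  if (!all(need %in% names(channels))) {
    abort(paste("channel table needs columns:", paste(need, collapse = ", ")))
  }
  if (!all(is.finite(data))) abort("LFP data must be finite")
  structure(list(data = data, fs_hz = fs_hz,
                 channels = tibble::as_tibble(channels)),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channels x %d samples at %g Hz (%.1f s), %d out-of-brain\n",
              nrow(x$data), ncol(x$data), x$fs_hz, ncol(x$data) / x$fs_hz,
              sum(!x$channels$in_brain)))
  invisible(x)
}

#' Skin-pattern feature trajectories
#'
#' One active-sleep bout's skin-pattern dynamics: a frames-by-dimensions
#' matrix of per-frame feature vectors with frame rate and animal/bout
#' identity.
#'
#' @param features numeric matrix, T frames x D feature dimensions.
#' @param fps frames per second.
#' @param animal_id,bout_id identity labels.
#' @return an object of class `pattern_trajectory`.
#' @export
pattern_trajectory <- function(features, fps = 30, animal_id = "a1",
                               bout_id = "b1") {
  stopifnot(is.matrix(features), nrow(features) >= 2, fps > 0,
            all(is.finite(features)))
  structure(list(features = features, fps = fps,
                 animal_id = animal_id, bout_id = bout_id),
            class = "pattern_trajectory")
}

#' @export
print.pattern_trajectory <- function(x, ...) {
  cat(sprintf("<pattern_trajectory> %s/%s: %d frames x %d dims at %g fps\n",
              x$animal_id, x$bout_id, nrow(x$features), ncol(x$features),
              x$fps))
  invisible(x)
}

traj_features <- function(x) {
  if (inherits(x, "pattern_trajectory")) x$features
  else if (is.matrix(x)) x
  else abort("expected a pattern_trajectory or a frames x dims matrix")
}
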