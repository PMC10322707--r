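#' Linear model of inter-bout interval on water temperature
#'
#' Ordinary least squares of inter-bout interval (minutes) on temperature
#' (degC) with an intercept, reported as slope, intercept, R-squared, the
#' F statistic against the intercept-only model and its p value from
#' F(1, n-2). Matches the reporting tuple used for the published temperature
#' dependence of bout timing (slope about -5 min/degC on the original data).
#'
#' @param intervals_min inter-bout intervals, minutes.
#' @param temps_C water temperature for each interval, degC.
#' @return object of class `temperature_model` (wraps the underlying `lm`).
#' @export
fit_temperature_model <- function(intervals_min, temps_C) {
  stopifnot(length(intervals_min) == length(temps_C))
  ok <- is.finite(intervals_min) & is.finite(temps_C)
  intervals_min <- intervals_min[ok]; temps_C <- temps_C[ok]
  n <- length(intervals_min)
  if (n < 3) abort("need at least 3 observations")
  if (length(unique(temps_C)) < 2) abort("need at least 2 distinct temperatures")
  fit <- stats::lm(interval ~ temp,
                   data = data.frame(interval = intervals_min, temp = temps_C))
  # a noiseless line is a legitimate input; the perfect-fit case is handled
  # explicitly below, so lm's advisory warning is muffled
  sm <- suppressWarnings(summary(fit))
  fstat <- unname(sm$fstatistic)
  p <- if (sm$sigma == 0) .Machine$double.xmin else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 slope_se = sm$coefficients[2, 2],
                 r2 = sm$r.squared,
                 f_stat = fstat[1],
                 p_value = max(p, .Machine$double.xmin),
                 n = n, fit = fit),
            class = "temperature_model")
}

#' @export
print.temperature_model <- function(x, ...) {
  cat(sprintf("Interval ~ temperature: slope %.3f min/degC (SE %.3f), intercept %.2f min\n",
              x$slope, x$slope_se, x$intercept))
  cat(sprintf("R^2 = %.3f, F(1, %d) = %.1f, p = %.3g, n = %d\n",
              x$r2, x$n - 2L, x$f_stat, x$p_value, x$n))
  invisible(x)
}

#' @export
tidy.temperature_model <- function(x, ...) {
  tb <- tibble::as_tibble(suppressWarnings(summary(x$fit))$coefficients,
                          rownames = "term")
  names(tb) <- c("term", "estimate", "std.error", "statistic", "p.value")
  tb$term <- c("(Intercept)", "temperature_C")
  tb
}

#' @export
glance.temperature_model <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, statistic = x$f_stat,
                 p.value = x$p_value, df = 1L, df.residual = x$n - 2L,
                 nobs = x$n)
}

#' Arousal reaction magnitude around a stimulation
#'
#' Mean movement magnitude over the 1 s following each stimulation minus the
#' mean over the 1 s preceding it (25 frames each way at 25 fps).
#'
#' @param move a [movement_trace()].
#' @param stim_s stimulation time(s), seconds.
#' @param window_s baseline/response window, seconds.
#' @return tibble with columns `stim_s`, `magnitude`.
#' @export
reaction_magnitude <- function(move, stim_s, window_s = 1) {
  check_trace(move)
  fps <- trace_fps(move)
  w <- round(window_s * fps)
  purrr::map_dfr(stim_s, function(st) {
    c0 <- round((st - move$time_s[1]) * fps) + 1
    if (c0 - w < 1 || c0 + w - 1 > nrow(move)) {
      abort(sprintf("stimulation at t=%g s too close to trace edge", st))
    }
    post <- mean(move$value[c0:(c0 + w - 1)])
    pre <- mean(move$value[(c0 - w):(c0 - 1)])
    tibble::tibble(stim_s = st, magnitude = post - pre)
  })
}

#' Breathing rate and variability from a residual movement trace
#'
#' Smooths the anterior-mantle residual movement trace with a 10-frame moving
#' average, z-scores it, detects inhalation peaks (prominence 0.05 on the z
#' scale), converts inter-peak intervals to instantaneous breaths/min and
#' linearly interpolates the rate to the video frame rate. The coefficient of
#' variation is SD/mean of the inter-peak intervals.
#'
#' @param residual a [movement_trace()] of residual movements.
#' @param smooth_frames moving-average window, frames.
#' @param min_prominence_z peak prominence threshold, z-units.
#' @return list with `rate` (tibble `time_s`, `bpm`), `mean_bpm`, `cv` and
#'   `peak_times_s`.
#' @export
breathing_metrics <- function(residual, smooth_frames = 10,
                              min_prominence_z = 0.05) {
  check_trace(residual)
  fps <- trace_fps(residual)
  if (nrow(residual) < 10 * fps) abort("trace must be at least 10 s long")
  # centred moving average (half-weight ends for even window lengths)
  kern <- if (smooth_frames %% 2 == 0) {
    c(0.5, rep(1, smooth_frames - 1), 0.5) / smooth_frames
  } else {
    rep(1 / smooth_frames, smooth_frames)
  }
  sm <- stats::filter(residual$value, kern, sides = 2)
  sm[is.na(sm)] <- mean(residual$value)
  z <- zscore(as.numeric(sm))
  pk <- find_peaks(z, min_prominence = min_prominence_z)
  if (length(pk) < 2) abort("fewer than 2 breathing peaks detected")
  pk_t <- residual$time_s[pk]
  ipi <- diff(pk_t)
  inst_bpm <- 60 / ipi
  mids <- pk_t[-length(pk_t)] + ipi / 2
  bpm <- stats::approx(mids, inst_bpm, xout = residual$time_s, rule = 2)$y
  list(rate = tibble::tibble(time_s = residual$time_s, bpm = bpm),
       mean_bpm = 60 / mean(ipi),
       cv = stats::sd(ipi) / mean(ipi),
       peak_times_s = pk_t)
}
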