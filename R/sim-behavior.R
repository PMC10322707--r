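#' Configuration for the behavioural trace generator
#'
#' Parameters of [gen_brightness_trace()]. Defaults reproduce the descriptive
#' statistics of octopus two-stage sleep at the 22 degC reference temperature:
#' active-sleep (AS) bouts of 75 +/- 28 s roughly every 60 min of daytime
#' sleep, inter-bout interval shortening by 5 min per degC of warming, and
#' brief (7.1 s) colour flashes during the quiet sleep (QS) separating bouts,
#' at a rate decaying across the inter-bout interval. The resting pattern is
#' uniformly white, so bouts and flashes are modelled as brightness decreases.
#'
#' The animal is nocturnal: bouts are generated by a renewal process running
#' in an "operational time" that advances at rate 1 during subjective day and
#' `1/circadian_day_gain` at night (30-min cosine taper at the light
#' transitions), so realized day intervals have mean `base_interval_min` while
#' night sleep is suppressed; night is labelled `wake` in the truth schedule.
#'
#' @param duration_h recording length, hours.
#' @param fps frames per second.
#' @param temperature_C water temperature, degC (reference 22).
#' @param base_interval_min mean bout start-to-start interval at 22 degC,
#'   minutes; `Inf` disables bouts.
#' @param interval_slope_min_per_C interval change per degC, minutes.
#' @param interval_sd_min interval standard deviation, minutes.
#' @param bout_duration_mean_s,bout_duration_sd_s AS bout duration moments,
#'   seconds (truncated below at 10 s).
#' @param circadian_day_gain ratio of day to night bout rate (at least 1).
#' @param day_start_h,day_length_h subjective day window, hours of day.
#' @param taper_min light-transition cosine taper, minutes.
#' @param bout_ramp_s onset/offset transition length of a bout, seconds.
#' @param flash_duration_s full duration of a colour flash, seconds.
#' @param flash_rate_start,flash_rate_end flash rate at the start/end of each
#'   inter-bout interval, events/min (decaying linearly).
#' @param flash_depth_z,bout_depth_z event amplitudes, units of the white
#'   per-frame noise SD. Real mean-brightness traces average ~1e5 pixels, so
#'   frame noise sits orders of magnitude below event depth; the defaults
#'   (14x flashes, 30x bouts) keep flashes subtle relative to bouts while
#'   leaving the trace variance event-dominated even in flash-poor QS
#'   stretches -- the regime the published fixed z thresholds presuppose.
#' @param noise_sd frame-to-frame (white) brightness noise SD, 8-bit units.
#' @param slow_sd SD of the slow in-band background fluctuation (posture and
#'   breathing-related brightness drift), 8-bit units; 0 disables it.
#' @param slow_band_hz passband of the slow fluctuation, Hz.
#' @param baseline resting brightness, 8-bit units.
#' @param seed RNG seed.
#' @return a list of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(duration_h = 24, fps = 24, temperature_C = 22,
                                base_interval_min = 60,
                                interval_slope_min_per_C = -5,
                                interval_sd_min = 16.4,
                                bout_duration_mean_s = 75,
                                bout_duration_sd_s = 28,
                                bout_ramp_s = 2,
                                circadian_day_gain = 8,
                                day_start_h = 6, day_length_h = 12,
                                taper_min = 30,
                                flash_duration_s = 7.1,
                                flash_rate_start = 0.4,
                                flash_rate_end = 0.1,
                                flash_depth_z = 14, bout_depth_z = 30,
                                noise_sd = 2, slow_sd = 1,
                                slow_band_hz = c(0.01, 0.05),
                                baseline = 200, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$fps > 0, cfg$noise_sd > 0, cfg$duration_h > 0,
            cfg$circadian_day_gain >= 1,
            cfg$flash_rate_start >= cfg$flash_rate_end,
            cfg$flash_rate_end >= 0,
            cfg$flash_duration_s > 0,
            cfg$flash_duration_s < cfg$base_interval_min * 60)
  class(cfg) <- "behavior_sim_config"
  cfg
}

# Day/night rate multiplier profile in [1/gain, 1], cosine-tapered at the
# light transitions; t_s in seconds from midnight of day 0.
day_speed <- function(t_s, cfg) {
  h <- (t_s / 3600) %% 24
  d0 <- cfg$day_start_h
  d1 <- cfg$day_start_h + cfg$day_length_h
  tap <- cfg$taper_min / 60
  lo <- 1 / cfg$circadian_day_gain
  ramp_up <- pmin(1, pmax(0, (h - (d0 - tap / 2)) / tap))
  ramp_dn <- pmin(1, pmax(0, (h - (d1 - tap / 2)) / tap))
  day_frac <- 0.5 * (1 - cos(pi * ramp_up)) * (1 - 0.5 * (1 - cos(pi * ramp_dn)))
  lo + (1 - lo) * day_frac
}

# Intervals of subjective day within [0, dur_s], using taper midpoints as
# boundaries.
day_intervals <- function(dur_s, cfg) {
  res <- list()
  k <- -1
  repeat {
    a <- (k * 24 + cfg$day_start_h) * 3600
    b <- (k * 24 + cfg$day_start_h + cfg$day_length_h) * 3600
    if (a > dur_s) break
    if (b > 0) res[[length(res) + 1]] <- c(max(0, a), min(dur_s, b))
    k <- k + 1
  }
  res <- Filter(function(iv) iv[2] > iv[1], res)
  res
}

trunc_norm <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  guard <- 0L
  while (length(bad) && guard < 1000L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower)
    guard <- guard + 1L
  }
  x[x < lower] <- lower
  x
}

raised_cosine_pulse <- function(n) {
  # Hann window: smooth unit-depth pulse over n samples
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' Generate a synthetic skin-brightness trace with ground truth
#'
#' Simulates the mean-skin-brightness recording of a sleeping octopus:
#' Gaussian baseline noise, sustained negative excursions for AS bouts,
#' brief negative Hann-shaped deflections for QS colour flashes (rate decaying
#' linearly across each inter-bout interval), day/night modulation of bout
#' rate and temperature-dependent bout intervals. Events are kept disjoint by
#' rejection. The returned truth logs every event and the full state
#' schedule (`AS`/`QS`/`wake`).
#'
#' @param cfg a [behavior_sim_config()].
#' @return a list with elements `trace` (a [brightness_trace()] tibble) and
#'   `truth` (list: `bout_starts_s`, `bout_durations_s`, `flash_times_s`,
#'   `schedule`, `params`).
#' @export
gen_brightness_trace <- function(cfg = behavior_sim_config()) {
  stopifnot(inherits(cfg, "behavior_sim_config"))
  dur_s <- cfg$duration_h * 3600
  n <- round(dur_s * cfg$fps)
  with_sim_seed(cfg$seed, {
    ## --- bout times: renewal process in operational time -------------------
    mu_min <- cfg$base_interval_min +
      cfg$interval_slope_min_per_C * (cfg$temperature_C - 22)
    starts <- numeric(0)
    durs <- numeric(0)
    if (is.finite(mu_min)) {
      grid <- seq(0, dur_s, by = 1)
      speed <- day_speed(grid, cfg)
      op <- c(0, cumsum((speed[-1] + speed[-length(speed)]) / 2))
      t_cur <- 0
      first <- TRUE
      repeat {
        d <- trunc_norm(1, cfg$bout_duration_mean_s, cfg$bout_duration_sd_s, 10)
        guard <- 0L
        repeat {
          u <- trunc_norm(1, mu_min, cfg$interval_sd_min, 5) * 60
          if (first || u > d + 20) break   # keep events disjoint
          guard <- guard + 1L
          if (guard > 200L) break
        }
        if (first) u <- u * runif(1)  # random phase for the first bout
        op_target <- op[min(length(op), floor(t_cur) + 1)] + u
        idx <- findInterval(op_target, op)
        if (idx >= length(grid)) break
        frac <- (op_target - op[idx]) / max(op[idx + 1] - op[idx], 1e-12)
        t_new <- grid[idx] + frac
        if (t_new + d > dur_s) break
        starts <- c(starts, t_new)
        durs <- c(durs, d)
        t_cur <- t_new
        first <- FALSE
      }
    }
    if (!length(starts) && is.finite(mu_min)) {
      warn("duration too short to contain one bout; truth is empty")
    }

    ## --- flashes: thinned inhomogeneous Poisson in every day-QS stretch ----
    flash_times <- numeric(0)
    if (cfg$flash_rate_start > 0) {
      pad <- cfg$flash_duration_s / 2 + 2
      # maximal QS stretches: day intervals minus bouts
      qs_gaps <- list()
      for (iv in day_intervals(dur_s, cfg)) {
        cuts <- c(iv[1], as.vector(rbind(starts, starts + durs)), iv[2])
        cuts <- sort(pmin(pmax(cuts, iv[1]), iv[2]))
        for (k in seq(1, length(cuts) - 1, by = 1)) {
          a0 <- cuts[k]; b0 <- cuts[k + 1]
          mid <- (a0 + b0) / 2
          in_bout <- length(starts) && any(mid >= starts & mid < starts + durs)
          if (!in_bout && b0 - a0 > 2 * pad) {
            qs_gaps[[length(qs_gaps) + 1L]] <- c(a0, b0)
          }
        }
      }
      for (gap in qs_gaps) {
        a <- gap[1] + pad
        b <- gap[2] - pad
        if (b - a < 2 * cfg$flash_duration_s) next
        len <- b - a
        lam_max <- cfg$flash_rate_start / 60
        n_cand <- stats::rpois(1, lam_max * len)
        if (!n_cand) next
        tt <- sort(runif(n_cand, a, b))
        u <- (tt - a) / len
        lam <- (cfg$flash_rate_start +
                  (cfg$flash_rate_end - cfg$flash_rate_start) * u) / 60
        tt <- tt[runif(n_cand) < lam / lam_max]
        # enforce 10-s separation greedily
        keep <- numeric(0)
        for (t in tt) if (!length(keep) || t - keep[length(keep)] >= 10) {
          keep <- c(keep, t)
        }
        flash_times <- c(flash_times, keep)
      }
    }

    ## --- assemble trace ----------------------------------------------------
    values <- cfg$baseline + rnorm(n, 0, cfg$noise_sd)
    if (cfg$slow_sd > 0) {
      slow <- bandpass_zerophase(rnorm(n), cfg$slow_band_hz[1],
                                 cfg$slow_band_hz[2], cfg$fps, 3)
      values <- values + slow / stats::sd(slow) * cfg$slow_sd
    }
    ramp <- round(cfg$bout_ramp_s * cfg$fps)
    for (i in seq_along(starts)) {
      i0 <- floor(starts[i] * cfg$fps) + 1
      i1 <- min(n, floor((starts[i] + durs[i]) * cfg$fps))
      len <- i1 - i0 + 1
      shape <- rep(1, len)
      r <- min(ramp, floor(len / 2))
      if (r > 1) {
        edge <- 0.5 * (1 - cos(pi * (seq_len(r) - 1) / (r - 1)))
        shape[seq_len(r)] <- edge
        shape[len - seq_len(r) + 1] <- edge
      }
      values[i0:i1] <- values[i0:i1] - cfg$bout_depth_z * cfg$noise_sd * shape
    }
    half <- round(cfg$flash_duration_s * cfg$fps / 2)
    for (t in flash_times) {
      c0 <- round(t * cfg$fps) + 1
      i0 <- max(1, c0 - half); i1 <- min(n, c0 + half)
      pulse <- raised_cosine_pulse(2 * half + 1)
      values[i0:i1] <- values[i0:i1] -
        cfg$flash_depth_z * cfg$noise_sd * pulse[(i0 - (c0 - half) + 1):(i1 - (c0 - half) + 1)]
    }

    ## --- state schedule ----------------------------------------------------
    days <- day_intervals(dur_s, cfg)
    lab <- character(0); s0 <- numeric(0); s1 <- numeric(0)
    add <- function(l, a, b) {
      if (b - a > 1e-6) { lab <<- c(lab, l); s0 <<- c(s0, a); s1 <<- c(s1, b) }
    }
    bnd <- sort(unique(c(0, dur_s, unlist(days),
                         starts, starts + durs)))
    for (i in seq_len(length(bnd) - 1)) {
      a <- bnd[i]; b <- bnd[i + 1]; mid <- (a + b) / 2
      in_bout <- length(starts) &&
        any(mid >= starts & mid < starts + durs)
      in_day <- any(vapply(days, function(iv) mid >= iv[1] && mid < iv[2],
                           logical(1)))
      add(if (in_bout) "AS" else if (in_day) "QS" else "wake", a, b)
    }
    sched <- state_schedule(lab, s0, s1)
    # merge touching intervals of the same label
    sched <- dplyr::mutate(sched,
      grp = cumsum(c(TRUE, label[-1] != label[-dplyr::n()] |
                       abs(start_s[-1] - end_s[-dplyr::n()]) > 1e-6)))
    sched <- dplyr::summarise(dplyr::group_by(sched, .data$grp),
      label = dplyr::first(.data$label),
      start_s = min(.data$start_s), end_s = max(.data$end_s),
      .groups = "drop")
    sched <- dplyr::arrange(dplyr::select(sched, -"grp"), .data$start_s)

    truth <- list(bout_starts_s = starts, bout_durations_s = durs,
                  flash_times_s = sort(flash_times), schedule = sched,
                  params = cfg)
    list(trace = brightness_trace(values, cfg$fps), truth = truth)
  })
}

#' Configuration for the movement-trace generator
#'
#' Parameters of [gen_movement_trace()], which emulates the mean optic-flow
#' movement-magnitude trace: a breathing oscillation, state-gated body
#' movement bursts, and boxcar impulse responses at stimulation times.
#'
#' @param duration_s trace length, seconds.
#' @param fps frames per second.
#' @param baseline constant magnitude offset (keeps the trace positive).
#' @param breathing_rate_bpm breaths per minute.
#' @param breathing_amplitude oscillation amplitude (0 disables breathing).
#' @param burst_rate_per_min,burst_amplitude named per-state (`QS`, `AS`,
#'   `wake`) Poisson burst rates and amplitudes.
#' @param burst_duration_s duration of one movement burst, seconds.
#' @param stim_times_s stimulation times, seconds.
#' @param stim_response response amplitude per stimulation (recycled).
#' @param stim_response_duration_s response duration, seconds.
#' @param noise_sd additive Gaussian noise SD.
#' @param schedule optional state schedule tibble; default labels the whole
#'   trace `QS`.
#' @param seed RNG seed.
#' @return a list of class `movement_sim_config`.
#' @export
movement_sim_config <- function(duration_s = 120, fps = 25, baseline = 0.5,
                                breathing_rate_bpm = 20,
                                breathing_amplitude = 0.3,
                                burst_rate_per_min = c(QS = 0.5, AS = 6, wake = 3),
                                burst_amplitude = c(QS = 0.2, AS = 2, wake = 1.5),
                                burst_duration_s = 1,
                                stim_times_s = numeric(0),
                                stim_response = numeric(0),
                                stim_response_duration_s = 1,
                                noise_sd = 0.02, schedule = NULL, seed = 1) {
  cfg <- as.list(environment())
  if (any(c(cfg$breathing_amplitude, cfg$burst_amplitude,
            cfg$stim_response, cfg$noise_sd, cfg$baseline) < 0)) {
    abort("amplitudes must be non-negative")
  }
  stopifnot(cfg$fps > 0, cfg$duration_s > 0)
  class(cfg) <- "movement_sim_config"
  cfg
}

#' Generate a synthetic movement-magnitude trace with ground truth
#'
#' @param cfg a [movement_sim_config()].
#' @return list with `trace` (a [movement_trace()] tibble) and `truth`
#'   (list: `breath_peak_times_s`, `burst_times_s`, `stim` tibble, `params`).
#' @export
gen_movement_trace <- function(cfg = movement_sim_config()) {
  stopifnot(inherits(cfg, "movement_sim_config"))
  n <- round(cfg$duration_s * cfg$fps)
  t <- (seq_len(n) - 1) / cfg$fps
  sched <- cfg$schedule
  if (is.null(sched)) sched <- state_schedule("QS", 0, cfg$duration_s)
  with_sim_seed(cfg$seed, {
    values <- rep(cfg$baseline, n)
    breath_peaks <- numeric(0)
    if (cfg$breathing_amplitude > 0 && cfg$breathing_rate_bpm > 0) {
      f <- cfg$breathing_rate_bpm / 60
      values <- values + cfg$breathing_amplitude * 0.5 * (1 - cos(2 * pi * f * t))
      breath_peaks <- seq((1 / (2 * f)), cfg$duration_s - 1e-9, by = 1 / f)
    }
    burst_times <- numeric(0)
    for (i in seq_len(nrow(sched))) {
      st <- sched$label[i]
      rate <- cfg$burst_rate_per_min[[st]] %||% 0
      amp <- cfg$burst_amplitude[[st]] %||% 0
      if (rate <= 0 || amp <= 0) next
      len <- sched$end_s[i] - sched$start_s[i]
      k <- stats::rpois(1, rate * len / 60)
      if (!k) next
      bt <- sort(runif(k, sched$start_s[i], max(sched$start_s[i],
                                                sched$end_s[i] - cfg$burst_duration_s)))
      for (b in bt) {
        i0 <- floor(b * cfg$fps) + 1
        i1 <- min(n, i0 + round(cfg$burst_duration_s * cfg$fps) - 1)
        m <- i1 - i0 + 1
        values[i0:i1] <- values[i0:i1] + amp * sin(pi * (seq_len(m) - 0.5) / m)
      }
      burst_times <- c(burst_times, bt)
    }
    stim <- tibble::tibble(time_s = cfg$stim_times_s,
                           amplitude = rep_len(if (length(cfg$stim_response))
                             cfg$stim_response else 0,
                             length(cfg$stim_times_s)))
    for (i in seq_len(nrow(stim))) {
      i0 <- floor(stim$time_s[i] * cfg$fps) + 1
      i1 <- min(n, i0 + round(cfg$stim_response_duration_s * cfg$fps) - 1)
      if (i0 <= n) values[i0:i1] <- values[i0:i1] + stim$amplitude[i]
    }
    if (cfg$noise_sd > 0) values <- values + rnorm(n, 0, cfg$noise_sd)
    values <- pmax(values, 0)
    truth <- list(breath_peak_times_s = breath_peaks,
                  burst_times_s = sort(burst_times), stim = stim, params = cfg)
    list(trace = movement_trace(values, cfg$fps), truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
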