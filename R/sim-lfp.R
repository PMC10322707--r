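#' Configuration for the LFP generator
#'
#' Parameters of [gen_lfp()]. Channels carry band-limited noise whose
#' low-band (0.1-10 Hz) and high-band (20-150 Hz) standard deviations depend
#' on behavioural state (AS strongest, wake intermediate, QS quietest, as in
#' the recorded data). During QS, spindle-like oscillatory events --
#' Hann-windowed sinusoids at 12-18 Hz lasting 0.3-1 s, up to ~700 uV -- are
#' injected on a designated channel subset with heavy-tailed (log-normal)
#' inter-event intervals. A common-mode artifact is added identically to all
#' channels, including the out-of-brain channels used for re-referencing.
#'
#' @param n_channels channel count.
#' @param fs_hz sampling rate, Hz.
#' @param n_probes probe count for the synthetic channel table.
#' @param out_of_brain_channels indices of reference channels outside the
#'   brain.
#' @param regions region labels cycled over the in-brain channels (the first
#'   region receives `spindle_channels`).
#' @param state_band_power named list state -> c(low, high) band SDs, uV.
#' @param spindle_freq_hz spindle frequency range, Hz.
#' @param spindle_duration_s spindle duration range, seconds (<= 1 s).
#' @param spindle_amplitude_uV spindle peak amplitude range, uV.
#' @param spindle_iei_meanlog,spindle_iei_sdlog log-normal inter-event
#'   interval parameters (seconds).
#' @param spindle_channels channels receiving spindles (disjoint from
#'   `out_of_brain_channels`).
#' @param common_artifact_sd SD of the shared common-mode artifact, uV.
#' @param ob_noise_sd independent instrument noise on out-of-brain channels,
#'   uV.
#' @param seed RNG seed.
#' @return list of class `lfp_sim_config`.
#' @export
lfp_sim_config <- function(n_channels = 64, fs_hz = 2500, n_probes = 4,
                           out_of_brain_channels = 1:10,
                           regions = c("sFL", "VL", "Subv", "Subfr", "Buc"),
                           state_band_power = list(
                             QS = c(low = 5, high = 2),
                             AS = c(low = 40, high = 15),
                             wake = c(low = 20, high = 8)),
                           spindle_freq_hz = c(12, 18),
                           spindle_duration_s = c(0.3, 1),
                           spindle_amplitude_uV = c(200, 700),
                           spindle_iei_meanlog = log(8),
                           spindle_iei_sdlog = 0.8,
                           spindle_channels = 11:20,
                           common_artifact_sd = 20,
                           ob_noise_sd = 0.5, seed = 1) {
  cfg <- as.list(environment())
  if (length(intersect(cfg$out_of_brain_channels, cfg$spindle_channels))) {
    abort("out_of_brain_channels must be disjoint from spindle_channels")
  }
  stopifnot(max(cfg$spindle_duration_s) <= 1,
            max(c(cfg$out_of_brain_channels, cfg$spindle_channels)) <=
              cfg$n_channels,
            cfg$fs_hz > 300)
  class(cfg) <- "lfp_sim_config"
  cfg
}

# Synthetic channel table: out-of-brain channels first, then region blocks
# whose channels cycle over probes so every region is sampled by several
# probes. y_um is the anterior-posterior coordinate.
synth_channel_table <- function(cfg) {
  n <- cfg$n_channels
  ob <- cfg$out_of_brain_channels
  in_brain <- setdiff(seq_len(n), ob)
  nreg <- length(cfg$regions)
  per <- ceiling(length(in_brain) / nreg)
  reg_idx <- rep(seq_len(nreg), each = per)[seq_along(in_brain)]
  region <- character(n); probe <- integer(n)
  region[ob] <- "outside"
  probe[ob] <- 1L
  region[in_brain] <- cfg$regions[reg_idx]
  probe[in_brain] <- ((seq_along(in_brain) - 1L) %% cfg$n_probes) + 1L
  within <- stats::ave(seq_along(in_brain), reg_idx, FUN = seq_along)
  y <- numeric(n)
  y[in_brain] <- reg_idx * 1000 + within * 450 / per
  tibble::tibble(channel = seq_len(n),
                 x_um = probe * 400,
                 y_um = y,
                 z_um = 0,
                 region = region,
                 probe = probe,
                 in_brain = !(seq_len(n) %in% ob))
}

check_schedule_cover <- function(schedule, dur_s) {
  s <- dplyr::arrange(schedule, .data$start_s)
  cur <- 0
  for (i in seq_len(nrow(s))) {
    if (s$start_s[i] > cur + 1e-6) {
      abort(sprintf("schedule gap: [%g, %g] s uncovered", cur, s$start_s[i]))
    }
    cur <- max(cur, s$end_s[i])
  }
  if (cur < dur_s - 1e-6) {
    abort(sprintf("schedule gap: [%g, %g] s uncovered", cur, dur_s))
  }
  invisible(s)
}

unit_band_noise <- function(n, lo, hi, fs) {
  x <- bandpass_zerophase(rnorm(n), lo, hi, fs, poles = 3)
  x / stats::sd(x)
}

#' Generate a synthetic multi-channel LFP recording with ground truth
#'
#' @param cfg an [lfp_sim_config()].
#' @param schedule a [state_schedule()] covering the full recording (its
#'   maximum `end_s` sets the duration); labels must appear in
#'   `cfg$state_band_power` (plus optional `wake`).
#' @return list with `rec` (an [lfp_recording()]) and `truth` (list:
#'   `spindles` tibble with `time_s`, `freq_hz`, `duration_s`,
#'   `amplitude_uV`; `params`).
#' @export
gen_lfp <- function(cfg = lfp_sim_config(), schedule) {
  stopifnot(inherits(cfg, "lfp_sim_config"))
  dur_s <- max(schedule$end_s)
  check_schedule_cover(schedule, dur_s)
  n <- round(dur_s * cfg$fs_hz)
  bad <- setdiff(unique(schedule$label), names(cfg$state_band_power))
  if (length(bad)) {
    abort(paste("no state_band_power entry for state:", paste(bad, collapse = ", ")))
  }
  with_sim_seed(cfg$seed, {
    # per-sample band SDs from the schedule
    low_sd <- numeric(n); high_sd <- numeric(n)
    for (i in seq_len(nrow(schedule))) {
      i0 <- max(1, floor(schedule$start_s[i] * cfg$fs_hz) + 1)
      i1 <- min(n, ceiling(schedule$end_s[i] * cfg$fs_hz))
      bp <- cfg$state_band_power[[schedule$label[i]]]
      low_sd[i0:i1] <- bp[["low"]]
      high_sd[i0:i1] <- bp[["high"]]
    }
    data <- matrix(0, nrow = cfg$n_channels, ncol = n)
    ob <- cfg$out_of_brain_channels
    for (ch in seq_len(cfg$n_channels)) {
      if (ch %in% ob) {
        if (cfg$ob_noise_sd > 0) data[ch, ] <- rnorm(n, 0, cfg$ob_noise_sd)
      } else {
        lo <- unit_band_noise(n, 0.1, 10, cfg$fs_hz)
        hi <- unit_band_noise(n, 20, 150, cfg$fs_hz)
        data[ch, ] <- lo * low_sd + hi * high_sd
      }
    }
    # spindle-like events during QS on the designated channels
    sp_t <- numeric(0); sp_f <- numeric(0); sp_d <- numeric(0); sp_a <- numeric(0)
    qs <- schedule[schedule$label == "QS", ]
    for (i in seq_len(nrow(qs))) {
      t <- qs$start_s[i]
      repeat {
        t <- t + rlnorm(1, cfg$spindle_iei_meanlog, cfg$spindle_iei_sdlog)
        d <- runif(1, cfg$spindle_duration_s[1], cfg$spindle_duration_s[2])
        if (t + d > qs$end_s[i]) break
        f <- runif(1, cfg$spindle_freq_hz[1], cfg$spindle_freq_hz[2])
        a <- runif(1, min(cfg$spindle_amplitude_uV), max(cfg$spindle_amplitude_uV))
        i0 <- floor(t * cfg$fs_hz) + 1
        len <- round(d * cfg$fs_hz)
        if (i0 + len - 1 > n) break
        tt <- (seq_len(len) - 1) / cfg$fs_hz
        wave <- a * raised_cosine_pulse(len) * sin(2 * pi * f * tt)
        data[cfg$spindle_channels, i0:(i0 + len - 1)] <-
          data[cfg$spindle_channels, i0:(i0 + len - 1), drop = FALSE] +
          matrix(wave, nrow = length(cfg$spindle_channels), ncol = len,
                 byrow = TRUE)
        sp_t <- c(sp_t, t + d / 2); sp_f <- c(sp_f, f)
        sp_d <- c(sp_d, d); sp_a <- c(sp_a, a)
      }
    }
    if (cfg$common_artifact_sd > 0) {
      art <- rnorm(n, 0, cfg$common_artifact_sd)
      data <- sweep(data, 2, art, `+`)
    }
    rec <- lfp_recording(data, cfg$fs_hz, synth_channel_table(cfg))
    truth <- list(spindles = tibble::tibble(time_s = sp_t, freq_hz = sp_f,
                                            duration_s = sp_d,
                                            amplitude_uV = sp_a),
                  params = cfg)
    list(rec = rec, truth = truth)
  })
}
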