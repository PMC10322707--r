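#' Plot a brightness or movement trace with optional event overlays
#'
#' @param trace a trace tibble (`time_s`, `value`).
#' @param events optional tibble with a `time_s` column (e.g. detected
#'   flashes) drawn as vertical marks.
#' @param bouts optional tibble with `start_s`, `end_s` shaded intervals.
#' @return a ggplot object.
#' @export
plot_trace <- function(trace, events = NULL, bouts = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_s / 3600,
                                           y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (h)", y = "value")
  if (!is.null(bouts) && nrow(bouts)) {
    p <- p + ggplot2::geom_rect(
      data = bouts,
      ggplot2::aes(xmin = .data$start_s / 3600, xmax = .data$end_s / 3600,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.2)
  }
  if (!is.null(events) && nrow(events)) {
    p <- p + ggplot2::geom_vline(
      data = events, ggplot2::aes(xintercept = .data$time_s / 3600),
      colour = "firebrick", alpha = 0.5, linetype = 2)
  }
  p
}

#' Plot circadian bout-rate estimates
#'
#' @param circ result of [circadian_rate()].
#' @return a ggplot object (histogram bars plus smoothed rate).
#' @export
plot_circadian <- function(circ) {
  ggplot2::ggplot() +
    ggplot2::geom_col(data = circ$hist,
                      ggplot2::aes(x = .data$bin_mid_h, y = .data$count),
                      fill = "grey70") +
    ggplot2::geom_line(data = circ$rate,
                       ggplot2::aes(x = .data$time_h,
                                    y = .data$rate_per_h *
                                      attr(circ, "hist_bin_h") %||% 2),
                       colour = "firebrick") +
    ggplot2::labs(x = "time (h)", y = "bouts per bin")
}

#' Plot a wavelet spectrogram
#'
#' @param spg a `cs_spectrogram` from [wavelet_spectrogram()].
#' @param max_points downsample the time axis to roughly this many columns.
#' @return a ggplot object.
#' @export
plot_spectrogram <- function(spg, max_points = 2000) {
  step <- max(1, floor(length(spg$time_s) / max_points))
  idx <- seq(1, length(spg$time_s), by = step)
  df <- tidyr::expand_grid(freq_hz = spg$freq_hz, time_s = spg$time_s[idx])
  df$mag <- as.vector(spg$magnitude[, idx])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                                   fill = .data$mag)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "norm. mag.") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)")
}

#' @export
autoplot.cs_spectrogram <- function(object, ...) plot_spectrogram(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the trajectory distance distributions
#'
#' Histograms of intra-trajectory, nearest-point and zero-lag
#' inter-trajectory distances (the three distributions characterizing AS
#' pattern dynamics).
#'
#' @param trajectories list of [pattern_trajectory()] objects.
#' @param max_pairs cap on trajectory pairs.
#' @return a ggplot object.
#' @export
plot_distance_distributions <- function(trajectories, max_pairs = 50) {
  intra <- unlist(lapply(trajectories, function(tr) {
    attr(intra_distance(tr), "steps")
  }))
  pr <- utils::combn(length(trajectories), 2)
  if (ncol(pr) > max_pairs) pr <- pr[, seq_len(max_pairs), drop = FALSE]
  near <- unlist(lapply(seq_len(ncol(pr)), function(k) {
    nearest_distances(trajectories[[pr[1, k]]], trajectories[[pr[2, k]]])
  }))
  inter <- unlist(lapply(seq_len(ncol(pr)), function(k) {
    attr(inter_distance(trajectories[[pr[1, k]]], trajectories[[pr[2, k]]]),
         "per_frame")
  }))
  df <- dplyr::bind_rows(
    tibble::tibble(kind = "intra (consecutive)", d = intra),
    tibble::tibble(kind = "nearest between", d = near),
    tibble::tibble(kind = "inter at zero lag", d = inter))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, fill = .data$kind)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, alpha = 0.5, position = "identity") +
    ggplot2::labs(x = "pattern distance", y = "density", fill = NULL)
}

#' Plot per-region summaries
#'
#' @param region_summary tibble from [region_aggregate()].
#' @return a ggplot object.
#' @export
plot_region_summary <- function(region_summary) {
  rs <- region_summary
  if ("half" %in% names(rs)) {
    ggplot2::ggplot(rs, ggplot2::aes(x = .data$region, y = .data$mean,
                                     fill = .data$half)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = NULL, y = "mean value", fill = NULL)
  } else {
    ggplot2::ggplot(rs, ggplot2::aes(x = .data$region, y = .data$mean)) +
      ggplot2::geom_col(fill = "grey40") +
      ggplot2::labs(x = NULL, y = "mean value")
  }
}
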