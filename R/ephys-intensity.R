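#' Frequency band specification
#'
#' @param name band label.
#' @param lo_hz,hi_hz passband edges, Hz.
#' @return list of class `band_spec`.
#' @export
band_spec <- function(name, lo_hz, hi_hz) {
  stopifnot(lo_hz > 0, lo_hz < hi_hz)
  structure(list(name = name, lo_hz = lo_hz, hi_hz = hi_hz),
            class = "band_spec")
}

#' Canonical low/high analysis bands
#'
#' The two bands used for state comparisons: low 0.1-10 Hz and high
#' 20-150 Hz.
#' @return list of two [band_spec()] objects.
#' @export
default_bands <- function() {
  list(low = band_spec("low", 0.1, 10), high = band_spec("high", 20, 150))
}

# Odd-length (type III) FIR Hilbert transformer, Hamming-windowed ideal
# response. A literal even 150-tap design is not type III; 151 taps is the
# nearest odd length.
fir_hilbert <- function(taps = 151) {
  stopifnot(taps %% 2 == 1)
  m <- (taps - 1) / 2
  j <- seq(-m, m)
  h <- ifelse(j %% 2 != 0, 2 / (pi * j), 0)
  h[m + 1] <- 0
  w <- 0.54 + 0.46 * cos(pi * j / m)   # Hamming
  h * w
}

# Analytic-signal envelope via the FIR Hilbert transformer; the centred
# convolution leaves (taps-1)/2 edge samples invalid on each side.
fir_envelope <- function(x, taps = 151) {
  h <- fir_hilbert(taps)
  m <- (taps - 1) / 2
  n <- length(x)
  xi <- stats::convolve(x, rev(h), type = "open")[(m + 1):(m + n)]
  env <- sqrt(x^2 + xi^2)
  valid <- rep(TRUE, n)
  valid[seq_len(min(m, n))] <- FALSE
  valid[seq.int(max(1, n - m + 1), n)] <- FALSE
  list(envelope = env, valid = valid)
}

#' Per-channel band intensity of LFP segments
#'
#' For every segment and channel: zero-phase band-pass filter, analytic
#' envelope via a 151-tap FIR Hilbert transformer, mean envelope over the
#' filter-valid samples. The per-channel vector is then smoothed with a
#' 5-channel sliding median along the channel axis (suppressing single noisy
#' channels) and finally averaged over segments. Segments shorter than twice
#' the transformer length are dropped.
#'
#' @param segments segment tibble from [extract_state_segments()] (or any
#'   tibble with a `data` list-column of channels x samples matrices),
#'   typically pre-filtered to one state label.
#' @param band a [band_spec()].
#' @param fs sampling rate of the segment data, Hz.
#' @param taps Hilbert transformer length (odd).
#' @param median_channels sliding-median width across channels.
#' @param filter_poles Butterworth order.
#' @return tibble with columns `channel`, `intensity` (uV).
#' @export
band_intensity <- function(segments, band, fs, taps = 151,
                           median_channels = 5, filter_poles = 3) {
  data_list <- if (is.data.frame(segments)) segments$data else segments
  data_list <- Filter(function(m) ncol(m) >= 2 * taps, data_list)
  if (!length(data_list)) abort("no segment long enough for the envelope filter")
  n_ch <- nrow(data_list[[1]])
  per_seg <- lapply(data_list, function(m) {
    v <- vapply(seq_len(n_ch), function(ch) {
      if (stats::sd(m[ch, ]) == 0) return(0)
      xf <- bandpass_zerophase(m[ch, ], band$lo_hz, band$hi_hz, fs,
                               filter_poles)
      e <- fir_envelope(xf, taps)
      mean(e$envelope[e$valid])
    }, numeric(1))
    median_across(v, median_channels)
  })
  intensity <- Reduce(`+`, per_seg) / length(per_seg)
  tibble::tibble(channel = seq_len(n_ch), intensity = intensity)
}

#' Aggregate per-channel values over brain regions
#'
#' Averages a per-channel measure (band intensity, event rate) over all
#' in-brain channels of each atlas region, excluding regions sampled by
#' fewer than `min_probes` probes. Optionally sub-splits each region
#' anterior/posterior at the midpoint `(min + max)/2` of its
#' anterior-posterior coordinate span.
#'
#' @param values tibble with columns `channel`, `value` (or a numeric vector
#'   indexed by channel).
#' @param channels channel table (as in [lfp_recording()]).
#' @param min_probes minimum probes per region.
#' @param ap_split split regions anterior/posterior.
#' @param ap_coord name of the anterior-posterior coordinate column.
#' @param anterior_low if `TRUE`, lower coordinate values are anterior.
#' @return tibble with columns `region` (and `half` when splitting), `mean`,
#'   `n_channels`, `n_probes`.
#' @export
region_aggregate <- function(values, channels, min_probes = 2,
                             ap_split = FALSE, ap_coord = "y_um",
                             anterior_low = TRUE) {
  if (!is.data.frame(values)) {
    values <- tibble::tibble(channel = seq_along(values),
                             value = as.numeric(values))
  }
  tb <- dplyr::inner_join(values, channels, by = "channel")
  tb <- tb[tb$in_brain, ]
  if (any(is.na(tb$region) | tb$region == "")) {
    abort("unknown region label on an in-brain channel")
  }
  probe_counts <- dplyr::summarise(dplyr::group_by(tb, .data$region),
                                   n_probes = dplyr::n_distinct(.data$probe),
                                   .groups = "drop")
  keep <- probe_counts$region[probe_counts$n_probes >= min_probes]
  tb <- tb[tb$region %in% keep, ]
  if (ap_split) {
    tb <- dplyr::group_by(tb, .data$region)
    tb <- dplyr::mutate(tb,
      mid = (min(.data[[ap_coord]]) + max(.data[[ap_coord]])) / 2,
      half = ifelse((.data[[ap_coord]] < .data$mid) == anterior_low,
                    "anterior", "posterior"))
    tb <- dplyr::group_by(tb, .data$region, .data$half)
  } else {
    tb <- dplyr::group_by(tb, .data$region)
  }
  dplyr::summarise(tb, mean = mean(.data$value),
                   n_channels = dplyr::n(),
                   n_probes = dplyr::n_distinct(.data$probe),
                   .groups = "drop")
}

#' Pearson correlation between two per-channel intensity maps
#'
#' Correlates two per-channel measures (e.g. wake vs AS band intensity) over
#' the channels belonging to regions that meet the probe minimum.
#'
#' @param map_a,map_b tibbles with columns `channel`, `value`, over the same
#'   channel set.
#' @param channels optional channel table; when supplied, only channels from
#'   regions with at least `min_probes` probes enter the correlation.
#' @param min_probes minimum probes per region.
#' @return Pearson correlation coefficient.
#' @export
intensity_correlation <- function(map_a, map_b, channels = NULL,
                                  min_probes = 2) {
  tb <- dplyr::inner_join(map_a, map_b, by = "channel",
                          suffix = c("_a", "_b"))
  if (!is.null(channels)) {
    ch <- dplyr::inner_join(tb["channel"], channels, by = "channel")
    counts <- dplyr::summarise(
      dplyr::group_by(ch[ch$in_brain, ], .data$region),
      n_probes = dplyr::n_distinct(.data$probe), .groups = "drop")
    keep_reg <- counts$region[counts$n_probes >= min_probes]
    keep_ch <- ch$channel[ch$in_brain & ch$region %in% keep_reg]
    tb <- tb[tb$channel %in% keep_ch, ]
  }
  if (nrow(tb) < 3) abort("need at least 3 channels")
  if (stats::sd(tb$value_a) == 0 || stats::sd(tb$value_b) == 0) {
    abort("zero variance in an intensity map")
  }
  stats::cor(tb$value_a, tb$value_b)
}
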