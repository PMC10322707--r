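#' Circadian binning/smoothing parameters
#'
#' Defaults follow the published analysis: 2-h histogram bins, a continuous
#' rate estimate from a 0.1-h binning smoothed with a Gaussian kernel of SD
#' 40 bins (4 h), and a kernel density estimate on 5-min binned times.
#'
#' @param hist_bin_h histogram bin width, hours.
#' @param rate_bin_h fine binning for the smoothed rate, hours.
#' @param smooth_sd_bins Gaussian smoothing SD, in `rate_bin_h` bins.
#' @param kde_bin_min KDE pre-binning, minutes.
#' @return list of class `circadian_params`.
#' @export
circadian_params <- function(hist_bin_h = 2, rate_bin_h = 0.1,
                             smooth_sd_bins = 40, kde_bin_min = 5) {
  stopifnot(hist_bin_h > 0, rate_bin_h > 0, smooth_sd_bins > 0,
            kde_bin_min > 0)
  structure(as.list(environment()), class = "circadian_params")
}

gaussian_smooth_reflect <- function(x, sd_bins) {
  k <- ceiling(4 * sd_bins)
  kern <- stats::dnorm(seq(-k, k), sd = sd_bins)
  kern <- kern / sum(kern)
  n <- length(x)
  # symmetric reflection, clamped for signals shorter than the kernel arm
  pad_l <- rev(x[pmin(n, seq_len(k))])
  pad_r <- x[pmax(1, seq.int(n, n - k + 1))]
  xp <- c(pad_l, x, pad_r)
  out <- stats::filter(xp, kern, sides = 2)
  as.numeric(out[(k + 1):(k + n)])
}

#' Histogram, smoothed rate and KDE of event times
#'
#' Computes (1) a coarse histogram of event times, (2) a continuous rate
#' estimate obtained by convolving a fine binning with a Gaussian kernel
#' (reflective edges, so total event mass is conserved), and (3) a kernel
#' density estimate of the pre-binned times (Silverman bandwidth).
#'
#' @param event_times_s event times, seconds from recording start.
#' @param duration_s recording duration, seconds.
#' @param params a [circadian_params()].
#' @return list with tibbles `hist` (`bin_mid_h`, `count`), `rate`
#'   (`time_h`, `rate_per_h`) and `kde` (`time_h`, `density`).
#' @export
circadian_rate <- function(event_times_s, duration_s,
                           params = circadian_params()) {
  if (length(event_times_s) &&
      (min(event_times_s) < 0 || max(event_times_s) > duration_s)) {
    abort("event times must lie within [0, duration_s]")
  }
  t_h <- event_times_s / 3600
  dur_h <- duration_s / 3600
  brks_hist <- seq(0, dur_h + params$hist_bin_h, by = params$hist_bin_h)
  brks_rate <- seq(0, dur_h + params$rate_bin_h, by = params$rate_bin_h)
  hist_cnt <- if (length(t_h)) {
    tabulate(findInterval(t_h, brks_hist, rightmost.closed = TRUE),
             nbins = length(brks_hist) - 1)
  } else rep(0L, length(brks_hist) - 1)
  rate_cnt <- if (length(t_h)) {
    tabulate(findInterval(t_h, brks_rate, rightmost.closed = TRUE),
             nbins = length(brks_rate) - 1)
  } else rep(0L, length(brks_rate) - 1)
  smoothed <- gaussian_smooth_reflect(as.numeric(rate_cnt),
                                      params$smooth_sd_bins)
  rate <- tibble::tibble(
    time_h = brks_rate[-length(brks_rate)] + params$rate_bin_h / 2,
    rate_per_h = smoothed / params$rate_bin_h)
  hist_tb <- tibble::tibble(
    bin_mid_h = brks_hist[-length(brks_hist)] + params$hist_bin_h / 2,
    count = hist_cnt)
  kde <- if (length(t_h) >= 2) {
    bin_h <- params$kde_bin_min / 60
    binned <- (floor(t_h / bin_h) + 0.5) * bin_h
    d <- stats::density(binned, bw = "nrd0", from = 0, to = dur_h, n = 512)
    tibble::tibble(time_h = d$x, density = d$y)
  } else {
    tibble::tibble(time_h = seq(0, dur_h, length.out = 512),
                   density = rep(0, 512))
  }
  list(hist = hist_tb, rate = rate, kde = kde)
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether event times are uniformly distributed in phase over a cycle
#' (default 24 h). Phases are `2*pi*(t mod period)/period`; the statistic is
#' the mean resultant length `R_bar`, with `Z = n*R_bar^2` and the standard
#' finite-n corrected approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - n*Z)) - (1 + 2n))`.
#'
#' @param event_times_s event times, seconds (or any unit matching
#'   `period_h * 3600`).
#' @param period_h cycle length, hours.
#' @return object of class `rayleigh_test` with fields `r_bar`, `z`,
#'   `p_value`, `n`, `period_h`.
#' @export
rayleigh_test <- function(event_times_s, period_h = 24) {
  n <- length(event_times_s)
  if (n < 2) abort("rayleigh_test needs at least 2 events")
  period_s <- period_h * 3600
  ph <- 2 * pi * (event_times_s %% period_s) / period_s
  r_bar <- Mod(mean(exp(1i * ph)))
  z <- n * r_bar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - n * z)) - (1 + 2 * n))
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(r_bar = r_bar, z = z, p_value = p, n = n,
                 period_h = period_h),
            class = "rayleigh_test")
}

#' @export
print.rayleigh_test <- function(x, ...) {
  cat(sprintf("Rayleigh test (period %g h): R_bar = %.4f, Z = %.3f, p = %.3g, n = %d\n",
              x$period_h, x$r_bar, x$z, x$p_value, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.rayleigh_test <- function(x, ...) {
  tibble::tibble(r_bar = x$r_bar, statistic = x$z, p.value = x$p_value,
                 n = x$n, period_h = x$period_h)
}

#' Paired / unpaired rank comparisons between states
#'
#' Thin convenience wrapper around [stats::wilcox.test()] (sign-rank when
#' `paired = TRUE`, rank-sum otherwise), returning a one-row tibble. Used for
#' routine state comparisons (QS vs AS movement, pre/post deprivation rates).
#'
#' @param x,y numeric samples.
#' @param paired use the signed-rank test.
#' @return tibble with `statistic`, `p.value`, `method`, `n_x`, `n_y`.
#' @export
compare_groups <- function(x, y, paired = FALSE) {
  ht <- stats::wilcox.test(x, y, paired = paired, exact = FALSE)
  tibble::tibble(statistic = unname(ht$statistic), p.value = ht$p.value,
                 method = ht$method, n_x = length(x), n_y = length(y))
}
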