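test_that("constant and zero-variance traces give no flash detections", {
  tr <- brightness_trace(rep(150, 24 * 120), fps = 24)
  expect_equal(nrow(detect_flashes(tr)), 0)
})

test_that("flash detection recovers injected dips within one second", {
  hits <- 0L; total <- 0L
  for (s in 1:6) {
    times <- c(120, 180, 240)
    tr <- make_dip_trace(times, depth_sd = 5, duration_s = 600, seed = s)
    det <- detect_flashes(tr)
    m <- match_events(det$time_s, times, tol_s = 1)
    hits <- hits + m["tp"]; total <- total + 3L
    expect_lte(m["fp"], 1)
  }
  expect_gte(hits / total, 0.9)
})

test_that("minimum separation keeps only the stronger of two close dips", {
  tr <- make_dip_trace(c(300, 305), depth_sd = c(5), dip_dur_s = 4,
                       duration_s = 600, seed = 2)
  det <- detect_flashes(tr)
  near <- det$time_s[det$time_s > 290 & det$time_s < 315]
  expect_length(near, 1)
  # cross-check the separation rule against a brute-force scan
  fps <- 24
  filt <- bandpass_zerophase(tr$value, 0.005, 2, fps, 3)
  z <- zscore(-filt)
  bf <- brute_force_peaks(z, min_height = 2, min_separation = 10 * fps)
  pk <- find_peaks(z, min_height = 2, min_separation = 10 * fps)
  expect_true(all(pk %in% bf))
})

test_that("detection times are invariant to affine brightness rescaling", {
  tr <- make_dip_trace(c(150, 300, 450), duration_s = 600, seed = 5)
  t0 <- detect_flashes(tr)$time_s
  for (ab in list(c(3.7, 10), c(0.2, -40))) {
    tr2 <- tr
    tr2$value <- ab[1] * tr$value + ab[2]
    expect_equal(detect_flashes(tr2)$time_s, t0)
  }
})

test_that("flash duration is read from 2z crossings around the peak", {
  # constructed rectangular pulse oracle (noise-free): crossings sit exactly
  # at the pulse edges
  fps <- 24
  v <- rep(200, 120 * fps)
  i0 <- 60 * fps
  v[i0:(i0 + 7 * fps - 1)] <- 200 - 5
  tr <- brightness_trace(v, fps)
  fd <- flash_duration(tr, 60 + 3.5)
  expect_lte(abs(fd$duration_s - 7), 2 / fps)
  expect_false(fd$clamped)
  # default window arithmetic: 500 frames before, 1000 after
  expect_error(flash_duration(tr, 10), "does not fit")
})

test_that("sub-threshold flashes fall back to the full window and flag", {
  fps <- 24
  withr::with_seed(8, {
    v <- 200 + rnorm(120 * fps, 0, 1)
    i0 <- 60 * fps
    v[i0:(i0 + 7 * fps)] <- v[i0:(i0 + 7 * fps)] - 1   # 1 SD only
    tr <- brightness_trace(v, fps)
  })
  fd <- flash_duration(tr, 60 + 3.5)
  expect_true(fd$clamped)
  expect_equal(fd$duration_s, 1501 / fps, tolerance = 0.01)
})

test_that("bout duration matches constructed pulses and takes longest run", {
  fps <- 24
  pulse_trace <- function(durs, starts, depth = 5) {
    n <- 400 * fps
    v <- rep(0, n)
    for (k in seq_along(durs)) {
      i0 <- round(starts[k] * fps); i1 <- i0 + round(durs[k] * fps)
      v[i0:i1] <- v[i0:i1] - depth
    }
    brightness_trace(200 + v, fps)
  }
  est <- estimate_bout_duration(pulse_trace(75, 100), 100)
  expect_lte(abs(est$duration_s - 75), 3)
  expect_false(est$flagged)
  # two separated dips in one window: the longest run wins
  est2 <- estimate_bout_duration(pulse_trace(c(20, 40), c(100, 130)), 100)
  expect_equal(est2$duration_s, 40, tolerance = 4 / 40)
  # flat window: zero with flag
  flat <- brightness_trace(rep(200, 400 * 24), 24)
  est3 <- estimate_bout_duration(flat, 100)
  expect_equal(est3$duration_s, 0)
  expect_true(est3$flagged)
  # monotone non-decreasing in true excursion length
  durs <- c(20, 35, 50, 65, 80, 95)
  ests <- vapply(durs, function(d) {
    estimate_bout_duration(pulse_trace(d, 100), 100)$duration_s
  }, numeric(1))
  expect_true(all(diff(ests) >= 0))
  # a bout outlasting the window is flagged as truncated
  est4 <- estimate_bout_duration(pulse_trace(130, 100), 100)
  expect_true(est4$truncated)
})

test_that("flash rate profile recovers uniform and one-sided placements", {
  sched <- state_schedule(rep("AS", 5), (0:4) * 1000, (0:4) * 1000 + 60)
  withr::with_seed(3, {
    fl <- sort(runif(400, 0, 5000))
    fl <- fl[vapply(fl, function(t) {
      any(t > (0:3) * 1000 + 60 & t < (1:4) * 1000)
    }, logical(1))]
  })
  prof <- flash_rate_profile(fl, sched, n_bins = 5)
  expect_lt(max(abs(prof$rate_per_min - mean(prof$rate_per_min))),
            3 * sd(prof$rate_per_min) + 0.05)
  # all flashes in first half of each interval -> second half exactly zero
  fl2 <- c(100, 200, 1100, 1300, 2100)
  prof2 <- flash_rate_profile(fl2, sched, n_bins = 4)
  expect_equal(prof2$rate_per_min[3:4], c(0, 0))
  expect_error(flash_rate_profile(fl, sched[1, ]), "complete")
})

test_that("wake-spanning inter-bout gaps are excluded from the profile", {
  sched <- state_schedule(c("AS", "wake", "AS", "AS"),
                          c(0, 100, 300, 600), c(60, 200, 360, 660))
  prof <- flash_rate_profile(c(450, 500), sched, n_bins = 2)
  # only the 360-600 gap is complete; both flashes fall in it
  expect_equal(sum(prof$rate_per_min) * (600 - 360) / 2 / 60, 2,
               tolerance = 1e-9)
})
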