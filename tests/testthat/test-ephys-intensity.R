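make_tone_segments <- function(f, amp = 40, n_ch = 5, fs = 1000,
                               dur_s = 10) {
  t <- (0:(dur_s * fs - 1)) / fs
  tone <- amp * sin(2 * pi * f * t)
  tibble::tibble(label = "x", start_s = 0, end_s = dur_s,
                 data = list(matrix(rep(tone, n_ch), n_ch, byrow = TRUE)))
}

test_that("band intensity is zero for silent input and tracks tone amplitude", {
  fs <- 1000
  zero <- tibble::tibble(label = "x", start_s = 0, end_s = 5,
                         data = list(matrix(0, 4, 5 * fs)))
  bz <- band_intensity(zero, band_spec("high", 20, 150), fs)
  expect_true(all(bz$intensity == 0))
  # in-band tones where the Hilbert transformer is valid: within 5%
  for (f in c(30, 80)) {
    b <- band_intensity(make_tone_segments(f), band_spec("high", 20, 150), fs)
    expect_equal(b$intensity, rep(40, 5), tolerance = 0.05)
  }
  # out-of-band leakage <= 5% of amplitude
  b5 <- make_tone_segments(5)
  leak <- band_intensity(b5, band_spec("high", 20, 150), fs)
  expect_lt(max(leak$intensity), 0.05 * 40)
  # low-band envelope of a 5 Hz tone: known transformer-length bias
  # (151 taps at 1 kHz span under one period; frozen regression value)
  lo <- band_intensity(b5, band_spec("low", 0.1, 10), fs)
  expect_equal(lo$intensity[1], 0.846 * 40, tolerance = 0.01)
})

test_that("an outlier channel is suppressed by the 5-channel median", {
  fs <- 1000
  segs <- make_tone_segments(30, n_ch = 7)
  segs$data[[1]][4, ] <- segs$data[[1]][4, ] * 100
  b <- band_intensity(segs, band_spec("high", 20, 150), fs)
  expect_lt(b$intensity[4], 2 * 40)
})

test_that("short segments are dropped from the intensity estimate", {
  fs <- 1000
  segs <- dplyr::bind_rows(make_tone_segments(30),
                           tibble::tibble(label = "x", start_s = 0,
                                          end_s = 0.2,
                                          data = list(matrix(1, 5, 200))))
  b <- band_intensity(segs, band_spec("high", 20, 150), fs)
  expect_equal(b$intensity, rep(40, 5), tolerance = 0.05)
  short_only <- segs[2, ]
  expect_error(band_intensity(short_only, band_spec("high", 20, 150), fs),
               "long enough")
})

test_that("region aggregation averages, excludes single-probe regions, and
           splits anterior/posterior", {
  ch <- tibble::tibble(
    channel = 1:8, x_um = 0,
    y_um = c(0, 10, 15, 25, 0, 0, 0, 0),
    z_um = 0,
    region = c("sFL", "sFL", "sFL", "sFL", "VL", "VL", "Subv", "outside"),
    probe = c(1L, 2L, 1L, 2L, 1L, 1L, 2L, 1L),
    in_brain = c(rep(TRUE, 7), FALSE))
  vals <- tibble::tibble(channel = 1:8, value = 3)
  rs <- region_aggregate(vals, ch)
  expect_setequal(rs$region, "sFL")       # VL single-probe, Subv single-probe
  expect_equal(rs$mean, 3)
  # constant input: every retained region mean equals the constant
  vals2 <- tibble::tibble(channel = 1:8, value = c(1, 2, 3, 4, 9, 9, 9, 9))
  rs2 <- region_aggregate(vals2, ch, ap_split = TRUE)
  # sFL spans y 0-25, midpoint 12.5: channels 1,2,3 anterior (y<12.5 for 0,10
  # and 15 posterior), 4 posterior
  ant <- rs2$mean[rs2$half == "anterior"]
  pos <- rs2$mean[rs2$half == "posterior"]
  expect_equal(ant, mean(c(1, 2)))
  expect_equal(pos, mean(c(3, 4)))
  # unknown region label errors
  ch_bad <- ch
  ch_bad$region[2] <- NA
  expect_error(region_aggregate(vals, ch_bad), "unknown region")
})

test_that("intensity correlation is affine-invariant and sign-correct", {
  a <- tibble::tibble(channel = 1:50, value = rnorm(50))
  b <- a; b$value <- 2 * a$value + 1
  expect_equal(intensity_correlation(a, b), 1)
  b2 <- a; b2$value <- -a$value
  expect_equal(intensity_correlation(a, b2), -1)
  const <- a; const$value <- 5
  expect_error(intensity_correlation(a, const), "zero variance")
  expect_error(intensity_correlation(a[1:2, ], b[1:2, ]), "at least 3")
  # independent maps: mean correlation near zero
  withr::with_seed(6, {
    rs <- replicate(100, {
      x <- tibble::tibble(channel = 1:200, value = rnorm(200))
      y <- tibble::tibble(channel = 1:200, value = rnorm(200))
      intensity_correlation(x, y)
    })
  })
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("state-dependent band power ordering survives the full chain", {
  # AS > wake > QS in the generator must reproduce in region summaries
  fs <- 2500
  cfg <- lfp_sim_config(n_channels = 10, fs_hz = fs,
                        out_of_brain_channels = 1:2, spindle_channels = 3:4,
                        n_probes = 2, regions = c("sFL", "VL"),
                        spindle_amplitude_uV = c(0, 0),
                        common_artifact_sd = 5, seed = 3)
  sched <- state_schedule(c("QS", "AS", "QS", "AS", "wake"),
                          c(0, 70, 130, 200, 270), c(70, 130, 200, 270, 340))
  g <- gen_lfp(cfg, sched)
  pp <- preprocess_lfp(g$rec)
  segs <- extract_state_segments(pp, sched)
  lowb <- band_spec("low", 0.1, 10)
  means <- vapply(c("QS", "AS", "wake"), function(st) {
    bi <- band_intensity(segs[segs$label == st, ], lowb, 1000)
    mean(bi$intensity[3:10])
  }, numeric(1))
  expect_true(means[["QS"]] < means[["wake"]])
  expect_true(means[["wake"]] < means[["AS"]])
})
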