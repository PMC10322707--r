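test_that("event-free configuration reproduces baseline noise statistics", {
  cfg <- behavior_sim_config(duration_h = 10 / 60, base_interval_min = Inf,
                             flash_rate_start = 0, flash_rate_end = 0,
                             noise_sd = 1, slow_sd = 0, baseline = 200,
                             seed = 4)
  g <- gen_brightness_trace(cfg)
  expect_equal(nrow(g$trace), 10 / 60 * 3600 * 24)
  expect_equal(mean(g$trace$value), 200, tolerance = 0.05)
  expect_equal(sd(g$trace$value), 1, tolerance = 0.05)
  expect_length(g$truth$bout_starts_s, 0)
  expect_length(g$truth$flash_times_s, 0)
})

test_that("generation is bit-identical under the same seed", {
  cfg <- behavior_sim_config(duration_h = 2, seed = 11)
  g1 <- gen_brightness_trace(cfg)
  g2 <- gen_brightness_trace(cfg)
  expect_identical(g1$trace$value, g2$trace$value)
  expect_identical(g1$truth$flash_times_s, g2$truth$flash_times_s)
  g3 <- gen_brightness_trace(behavior_sim_config(duration_h = 2, seed = 12))
  expect_false(identical(g1$trace$value, g3$trace$value))
})

test_that("realized day intervals and bout durations match configuration", {
  ivs <- c(); durs <- c(); counts <- c()
  for (s in 1:8) {
    g <- gen_brightness_trace(behavior_sim_config(seed = s))
    tr <- g$truth
    sched <- tr$schedule
    wake <- sched[sched$label == "wake", ]
    st <- tr$bout_starts_s
    if (length(st) >= 2) {
      for (i in seq_len(length(st) - 1)) {
        crosses_wake <- any(wake$start_s < st[i + 1] & wake$end_s > st[i])
        if (!crosses_wake) ivs <- c(ivs, (st[i + 1] - st[i]) / 60)
      }
    }
    durs <- c(durs, tr$bout_durations_s)
    counts <- c(counts, length(st))
  }
  expect_lt(abs(mean(ivs) - 60), 2 * sd(ivs) / sqrt(length(ivs)))
  expect_lt(abs(mean(durs) - 75), 2 * sd(durs) / sqrt(length(durs)))
  expect_lt(abs(sd(durs) - 28), 2 * sd(durs) / sqrt(length(durs)))
  # daily bout count in the descriptive range (10 +/- 3.5 per 24 h)
  expect_gt(mean(counts), 10 - 3.5)
  expect_lt(mean(counts), 10 + 2 * 3.5)
})

test_that("flashes lie inside QS and their rate decays across the interval", {
  slopes <- c()
  for (s in 1:6) {
    g <- gen_brightness_trace(behavior_sim_config(seed = s))
    qs <- g$truth$schedule[g$truth$schedule$label == "QS", ]
    in_qs <- vapply(g$truth$flash_times_s, function(t) {
      any(t >= qs$start_s & t <= qs$end_s)
    }, logical(1))
    expect_true(all(in_qs))
    prof <- flash_rate_profile(g$truth$flash_times_s, g$truth$schedule,
                               n_bins = 5)
    slopes <- c(slopes, coef(lm(rate_per_min ~ bin_mid, prof))[2])
  }
  expect_gte(sum(slopes < 0), 5)   # decaying profile in nearly every seed
})

test_that("temperature shifts the mean interval by the configured slope", {
  iv_at <- function(temp, seeds = 1:6) {
    out <- c()
    for (s in seeds) {
      g <- gen_brightness_trace(behavior_sim_config(
        temperature_C = temp, seed = s))
      st <- g$truth$bout_starts_s
      wake <- g$truth$schedule[g$truth$schedule$label == "wake", ]
      if (length(st) >= 2) for (i in seq_len(length(st) - 1)) {
        if (!any(wake$start_s < st[i + 1] & wake$end_s > st[i])) {
          out <- c(out, (st[i + 1] - st[i]) / 60)
        }
      }
    }
    out
  }
  cold <- iv_at(19); warm <- iv_at(26)
  # configured: 75 min at 19 C, 40 min at 26 C
  expect_lt(abs(mean(cold) - 75), 3 * sd(cold) / sqrt(length(cold)))
  expect_lt(abs(mean(warm) - 40), 3 * sd(warm) / sqrt(length(warm)))
})

test_that("too-short recordings warn and return empty truth", {
  expect_warning(
    g <- gen_brightness_trace(behavior_sim_config(duration_h = 0.02,
                                                  seed = 1)),
    "too short")
  expect_length(g$truth$bout_starts_s, 0)
})

test_that("truth events are recoverable from the trace by matched filtering", {
  g <- gen_brightness_trace(behavior_sim_config(seed = 9))
  fps <- 24
  tmpl_len <- round(7.1 * fps)
  tmpl <- 0.5 * (1 - cos(2 * pi * (seq_len(tmpl_len) - 1) / (tmpl_len - 1)))
  tmpl <- tmpl - mean(tmpl)
  v <- -(g$trace$value - mean(g$trace$value))
  for (t in sample(g$truth$flash_times_s, 10)) {
    c0 <- round(t * fps) + 1
    idx <- (c0 - tmpl_len %/% 2):(c0 + tmpl_len %/% 2 - 1 +
                                    tmpl_len %% 2)
    score <- sum(v[idx] * tmpl) / sum(tmpl^2)
    # matched-filter amplitude close to configured depth (14 x noise SD = 28)
    expect_equal(score, 28, tolerance = 0.25)
  }
})
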