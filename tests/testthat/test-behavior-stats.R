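test_that("circadian rate conserves event mass and tracks a flat rate", {
  circ <- circadian_rate(3600 * 5, 86400)
  expect_equal(sum(circ$rate$rate_per_h) * 0.1, 1, tolerance = 0.01)
  # Poisson events at constant rate: smoothed rate stays near the true rate
  withr::with_seed(21, {
    lambda <- 2  # per hour
    times <- cumsum(rexp(500, lambda / 3600))
    times <- times[times < 72 * 3600]
  })
  circ2 <- circadian_rate(times, 72 * 3600)
  inner <- circ2$rate$time_h > 6 & circ2$rate$time_h < 66
  se <- sqrt(lambda / (sqrt(2 * pi) * 4))  # effective kernel width 4 h
  expect_lt(max(abs(circ2$rate$rate_per_h[inner] - lambda)), 3 * se)
  # KDE integrates to ~1 (boundary mass outside the recording is lost)
  kde <- circ2$kde
  mass <- sum(kde$density) * diff(kde$time_h[1:2])
  expect_gt(mass, 0.9)
  expect_lte(mass, 1)
  # empty input: zero curves
  circ0 <- circadian_rate(numeric(0), 86400)
  expect_true(all(circ0$rate$rate_per_h == 0))
  expect_true(all(circ0$hist$count == 0))
})

test_that("rayleigh test handles concentrated and balanced phases", {
  r1 <- rayleigh_test(rep(7 * 3600, 50))
  expect_equal(r1$r_bar, 1)
  expect_lt(r1$p_value, 1e-10)
  r2 <- rayleigh_test(c(0, 6, 12, 18) * 3600)
  expect_equal(r2$r_bar, 0, tolerance = 1e-12)
  expect_equal(r2$p_value, 1, tolerance = 1e-6)
  expect_error(rayleigh_test(1), "at least 2")
  td <- tidy(r1)
  expect_equal(td$n, 50)
})

test_that("rayleigh type-I error is near nominal and power is high", {
  withr::with_seed(31, {
    rej <- mean(replicate(600, {
      rayleigh_test(runif(50, 0, 86400))$p_value < 0.05
    }))
  })
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.075)
  withr::with_seed(32, {
    pow <- mean(replicate(300, {
      ph <- rvonmises(50, mu = pi, kappa = 1)
      rayleigh_test(ph / (2 * pi) * 86400)$p_value < 0.05
    }))
  })
  expect_gte(pow, 0.9)
})

test_that("temperature model recovers a noiseless line exactly", {
  temps <- rep(c(19, 22, 24, 26, 28), each = 10)
  iv <- 300 - 5 * (temps - 22)
  fit <- fit_temperature_model(iv, temps)
  expect_equal(fit$slope, -5, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$intercept, 300 + 5 * 22, tolerance = 1e-6)
  g <- glance(fit)
  expect_equal(g$nobs, 50)
  td <- tidy(fit)
  expect_equal(td$estimate[2], -5, tolerance = 1e-9)
})

test_that("temperature model recovers a noisy slope within its own SE", {
  withr::with_seed(41, {
    temps <- runif(243, 19, 28)
    iv <- 300 - 5 * (temps - 22) + rnorm(243, 0, 20)
  })
  fit <- fit_temperature_model(iv, temps)
  expect_lt(abs(fit$slope + 5), 2 * fit$slope_se)
  expect_error(fit_temperature_model(iv, rep(22, 243)), "distinct")
  expect_error(fit_temperature_model(iv[1:2], temps[1:2]), "at least 3")
})

test_that("reaction magnitude is the post-minus-pre mean difference", {
  fps <- 25
  flat <- movement_trace(rep(0.4, 20 * fps), fps)
  expect_equal(reaction_magnitude(flat, 10)$magnitude, 0)
  v <- rep(0.4, 20 * fps)
  v[(10 * fps + 1):(20 * fps)] <- 0.4 + 1.5   # step of +m at stim
  expect_equal(reaction_magnitude(movement_trace(v, fps), 10)$magnitude, 1.5)
  expect_error(reaction_magnitude(flat, 0.2), "edge")
  # configured impulse response recovered within the noise SEM bound
  errs <- vapply(1:6, function(s) {
    g <- gen_movement_trace(movement_sim_config(
      duration_s = 30, breathing_amplitude = 0, stim_times_s = 15,
      stim_response = 2, noise_sd = 0.1,
      burst_rate_per_min = c(QS = 0), burst_amplitude = c(QS = 0), seed = s))
    reaction_magnitude(g$trace, 15)$magnitude - 2
  }, numeric(1))
  expect_true(all(abs(errs) <= 3 * 0.1 * sqrt(2 / 25)))
  # weak stimulation during QS (zero configured response) -> ~0
  g0 <- gen_movement_trace(movement_sim_config(
    duration_s = 30, breathing_amplitude = 0, stim_times_s = 15,
    stim_response = 0, noise_sd = 0.05,
    burst_rate_per_min = c(QS = 0), burst_amplitude = c(QS = 0), seed = 3))
  expect_lt(abs(reaction_magnitude(g0$trace, 15)$magnitude),
            3 * 0.05 * sqrt(2 / 25))
})

test_that("breathing metrics recover rate and variability", {
  g <- gen_movement_trace(movement_sim_config(
    duration_s = 60, breathing_rate_bpm = 30, noise_sd = 0,
    burst_rate_per_min = c(QS = 0), burst_amplitude = c(QS = 0)))
  expect_length(g$truth$breath_peak_times_s, 30)
  bm <- breathing_metrics(g$trace)
  expect_equal(bm$mean_bpm, 30, tolerance = 0.01)
  expect_lt(bm$cv, 0.01)
  # flat trace: no peaks
  expect_error(breathing_metrics(movement_trace(rep(1, 25 * 20), 25)),
               "peaks")
  # alternating 1 s / 3 s intervals: mean 2 s, CV exactly 0.5 (hand-computed)
  fps <- 25
  pk_t <- cumsum(rep(c(1, 3), 15))
  v <- rep(0, 65 * fps)
  for (p in pk_t) v[round(p * fps) + 1] <- 1
  v <- as.numeric(stats::filter(v, rep(1, 9) / 9, sides = 2))
  v[is.na(v)] <- 0
  bm2 <- breathing_metrics(movement_trace(v + 1e-3, fps), smooth_frames = 1)
  expect_equal(60 / bm2$mean_bpm, 2, tolerance = 0.02)
  expect_equal(bm2$cv, 0.5, tolerance = 0.01)
})

test_that("group comparison wrapper reports a rank test", {
  withr::with_seed(5, {
    out <- compare_groups(rnorm(20), rnorm(20) + 2)
  })
  expect_lt(out$p.value, 0.001)
  expect_match(out$method, "Wilcoxon")
})
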