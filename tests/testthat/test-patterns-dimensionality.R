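test_that("parallel analysis recovers a known low rank and rejects noise", {
  withr::with_seed(21, {
    ests <- vapply(1:3, function(s) {
      n <- 2000; d <- 50; r <- 5
      z <- matrix(rnorm(n * r), n)
      b <- qr.Q(qr(matrix(rnorm(d * r), d)))
      x <- z %*% t(b) + matrix(rnorm(n * d, sd = 0.1), n)
      parallel_analysis(x, n_sample = 2000, seed = s)
    }, integer(1))
  })
  expect_true(all(abs(ests - 5) <= 1))
  # pure iid noise: at most 1 spurious dimension in most seeds
  withr::with_seed(22, {
    noise_ests <- vapply(1:6, function(s) {
      parallel_analysis(matrix(rnorm(1500 * 40), 1500), seed = s)
    }, integer(1))
  })
  expect_gte(sum(noise_ests <= 1), 5)
  expect_error(parallel_analysis(matrix(1, 5, 1)), "2 dimensions")
})

test_that("parallel analysis is seed-stable", {
  withr::with_seed(23, {
    n <- 1500; d <- 60; r <- 8
    x <- matrix(rnorm(n * r), n) %*%
      t(qr.Q(qr(matrix(rnorm(d * r), d)))) +
      matrix(rnorm(n * d, sd = 0.1), n)
  })
  ests <- vapply(1:6, function(s) {
    parallel_analysis(x, n_sample = 1000, seed = s)
  }, integer(1))
  expect_lte(sd(ests) / mean(ests), 0.05)
})

test_that("silhouette separates clusters and reports overlap near zero", {
  withr::with_seed(24, {
    far <- rbind(matrix(rnorm(150 * 8), 150),
                 matrix(rnorm(150 * 8, mean = 30), 150))
    lab <- rep(c("a", "b"), each = 150)
  })
  expect_gt(silhouette_by_animal(far, lab), 0.9)
  withr::with_seed(25, {
    same <- matrix(rnorm(800 * 8), 800)
    lab2 <- rep(c("a", "b"), each = 400)
  })
  expect_lt(abs(silhouette_by_animal(same, lab2)), 0.02)
  expect_error(silhouette_by_animal(same, rep("a", 800)), "2 animals")
})

test_that("PCA projection preserves planar data and orders components", {
  withr::with_seed(26, {
    plane <- cbind(rnorm(120), rnorm(120, sd = 0.5))
    b <- qr.Q(qr(matrix(rnorm(20 * 2), 20)))
    x <- plane %*% t(b)
  })
  tr <- pattern_trajectory(x, animal_id = "a1", bout_id = "b1")
  proj <- pca_project(list(tr))
  d_orig <- dist(x)
  d_proj <- dist(cbind(proj$pc1, proj$pc2))
  expect_equal(as.vector(d_proj), as.vector(d_orig), tolerance = 1e-6)
  fit <- attr(proj, "fit")
  expect_gte(fit$sdev[1], fit$sdev[2])
  expect_equal(mean(proj$pc1), 0, tolerance = 1e-9)
  expect_equal(mean(proj$pc2), 0, tolerance = 1e-9)
})

test_that("wake vectors drawn from the library fall within AS space", {
  # enough bouts that nearly every library pattern is visited at least once
  cfg <- pattern_sim_config(n_animals = 2, n_bouts_per_animal = 5, seed = 6)
  g <- gen_pattern_trajectories(cfg)
  wake <- gen_wake_patterns(cfg, g$library, n = 30, seed = 7)
  rep <- wake_in_as_test(wake, g$trajectories)
  expect_gte(rep$fraction_within, 0.9)
  expect_true(rep$within_space)
  # a vector copied from an AS frame has nearest distance zero
  copied <- g$trajectories[[1]]$features[10, , drop = FALSE]
  rep2 <- wake_in_as_test(copied, g$trajectories)
  expect_equal(rep2$per_vector$nearest, 0)
  # a far outlier is flagged outside
  outlier <- matrix(100 * max(abs(g$trajectories[[1]]$features)), 1, 512)
  rep3 <- wake_in_as_test(outlier, g$trajectories)
  expect_false(rep3$per_vector$within)
  expect_error(wake_in_as_test(wake[0, , drop = FALSE], g$trajectories),
               "empty")
})

test_that("trajectory endpoints are exactly the white pattern", {
  g <- gen_pattern_trajectories(pattern_sim_config(
    n_animals = 1, n_bouts_per_animal = 3, seed = 9))
  white <- g$library$ambient[g$library$white_index, ]
  for (tr in g$trajectories) {
    expect_equal(tr$features[1, ], white, tolerance = 1e-12)
    expect_equal(tr$features[nrow(tr$features), ], white, tolerance = 1e-12)
  }
})

test_that("degenerate pattern dynamics give a constant trajectory", {
  cfg <- pattern_sim_config(n_animals = 1, n_bouts_per_animal = 1,
                            patterns_per_bout = 0, step_sd = 0,
                            transit_frames = 0, animal_offset_sd = 0,
                            ambient_noise_sd = 0, seed = 2)
  g <- gen_pattern_trajectories(cfg)
  x <- g$trajectories[[1]]$features
  expect_equal(as.numeric(intra_distance(x)), 0)
  expect_error(gen_pattern_trajectories(pattern_sim_config(library_size = 1)),
               "library_size")
})

test_that("featurizer is deterministic, blind to uniform images, separable", {
  u <- matrix(128, 48, 48)
  f <- default_featurizer(u)
  expect_length(f, 512)
  expect_lt(max(abs(f)), 1e-8)
  g <- gen_pattern_image_pair(image_sim_config(seed = 4))
  f1 <- default_featurizer(g$image_a)
  f2 <- default_featurizer(g$image_a)
  expect_identical(f1, f2)
  bad <- g$image_a; bad[5, 5] <- NA
  expect_error(default_featurizer(bad), "finite")
  # two different textures are far apart relative to re-noised copies
  withr::with_seed(27, {
    inter <- c(); within <- c()
    for (s in 1:5) {
      ga <- gen_pattern_image_pair(image_sim_config(seed = s))
      gb <- gen_pattern_image_pair(image_sim_config(seed = s + 50))
      fa <- default_featurizer(ga$image_a)
      fb <- default_featurizer(gb$image_a)
      renoised <- pmin(pmax(ga$image_a +
                              matrix(rnorm(length(ga$image_a), 0, 6),
                                     nrow(ga$image_a)), 0), 255)
      fa2 <- default_featurizer(renoised)
      inter <- c(inter, sqrt(sum((fa - fb)^2)))
      within <- c(within, sqrt(sum((fa - fa2)^2)))
    }
  })
  expect_gt(mean(inter) / mean(within), 5)
  fz <- filter_bank_featurizer()
  expect_equal(fz$dim, 512)
  expect_identical(fz$transform(u), f)
})
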