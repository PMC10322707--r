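test_that("identity and translation warps are exact in the interior", {
  g <- gen_pattern_image_pair(image_sim_config(seed = 1))
  cps0 <- g$control_points
  cps0$x_dst <- cps0$x_src; cps0$y_dst <- cps0$y_src
  expect_identical(mls_warp(g$image_a, cps0), g$image_a)
  cpt <- tibble::tibble(x_src = c(30, 130, 30, 130),
                        y_src = c(30, 30, 130, 130))
  cpt$x_dst <- cpt$x_src + 10; cpt$y_dst <- cpt$y_src
  wt <- mls_warp(g$image_a, cpt)
  expect_lt(max(abs(wt[40:120, 40:120] - g$image_a[40:120, 30:110])), 1e-9)
})

test_that("MLS interpolates control points and reduces to a similarity", {
  g <- gen_pattern_image_pair(image_sim_config(seed = 2))
  src <- as.matrix(g$control_points[, c("x_src", "y_src")])
  dst <- as.matrix(g$control_points[, c("x_dst", "y_dst")])
  mapped <- mls_map(src, src, dst)
  expect_lt(max(abs(mapped - dst)), 0.5)
  # all pairs related by one similarity: MLS equals the closed form
  th <- 0.4; sc <- 1.3; tr <- c(5, -3)
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  dst_sim <- sc * src %*% t(rot) + matrix(tr, nrow(src), 2, byrow = TRUE)
  withr::with_seed(3, q <- matrix(runif(40, 10, 150), ncol = 2))
  expect_equal(mls_map(q, src, dst_sim),
               sc * q %*% t(rot) + matrix(tr, nrow(q), 2, byrow = TRUE),
               tolerance = 1e-8)
  # degenerate control sets are rejected
  line <- tibble::tibble(x_src = 1:4, y_src = 2 * (1:4),
                         x_dst = 1:4, y_dst = 2 * (1:4) + 1)
  expect_error(mls_warp(g$image_a, line), "collinear")
  expect_error(mls_warp(g$image_a, g$control_points[1:2, ]), "3 control")
})

test_that("threshold match scores identity, disjoint and remapped inputs", {
  g <- gen_pattern_image_pair(image_sim_config(seed = 5))
  tm <- threshold_match(g$image_a, g$image_a)
  expect_equal(tm$iou, 1)
  expect_true(all(tm$threshold >= 180 & tm$threshold <= 230))
  # disjoint dark regions
  a <- matrix(255, 60, 60); a[10:20, 10:20] <- 0
  b <- matrix(255, 60, 60); b[40:50, 40:50] <- 0
  expect_equal(threshold_match(a, b, thresh = 200)$iou, 0)
  # symmetric
  tm2 <- threshold_match(g$image_a, g$image_b)
  tm3 <- threshold_match(g$image_b, g$image_a)
  expect_equal(tm2$iou, tm3$iou)
  # empty masks error
  flat <- matrix(255, 30, 30)
  expect_error(threshold_match(flat, flat, thresh = 250), "empty")
})

test_that("true-warp alignment separates matched from unmatched patterns", {
  iou_w <- c(); iou_u <- c()
  for (s in 1:6) {
    g <- gen_pattern_image_pair(image_sim_config(seed = s))
    aligned <- mls_warp(g$image_a, g$control_points)
    iou_w <- c(iou_w, threshold_match(aligned, g$image_b)$iou)
    iou_u <- c(iou_u, threshold_match(g$image_a, g$image_b)$iou)
  }
  expect_gte(min(iou_w), 0.8)
  expect_lte(mean(iou_u), 0.4)
})

test_that("warp-free pairs are identical and fold-over is rejected", {
  g0 <- gen_pattern_image_pair(image_sim_config(warp_mag_px = 0, seed = 3))
  expect_identical(g0$image_a, g0$image_b)
  expect_error(gen_pattern_image_pair(image_sim_config(warp_mag_px = 60,
                                                       seed = 3)),
               "fold-over")
})

test_that("warping approximately conserves the interior histogram", {
  tv <- vapply(1:6, function(s) {
    g <- gen_pattern_image_pair(image_sim_config(seed = s))
    crop <- 25:136
    ha <- hist(g$image_a[crop, crop], breaks = seq(0, 256, 16),
               plot = FALSE)$counts
    hb <- hist(g$image_b[crop, crop], breaks = seq(0, 256, 16),
               plot = FALSE)$counts
    sum(abs(ha / sum(ha) - hb / sum(hb))) / 2
  }, numeric(1))
  expect_lt(mean(tv), 0.05)
})

test_that("mantle alignment recovers a known similarity transform", {
  mkmask <- function(n, cx, cy, a, b, th) {
    rr <- matrix(seq_len(n), n, n); cc <- t(rr)
    u <- (cc - cx) * cos(th) + (rr - cy) * sin(th)
    v <- -(cc - cx) * sin(th) + (rr - cy) * cos(th)
    (u / a)^2 + (v / b)^2 <= 1
  }
  n <- 300
  m1 <- mkmask(n, 150, 150, 60, 30, 0.2)
  img1 <- matrix(200, n, n); img1[m1] <- 100
  mi <- mantle_image(img1, m1)
  m2 <- mkmask(n, 160, 140, 90, 45, 0.2 + pi / 6)
  img2 <- matrix(200, n, n); img2[m2] <- 100
  ref <- mantle_image(img2, m2)
  tr <- attr(align_mantle(mi, ref), "transform")
  expect_equal(tr$rotation_rad, pi / 6, tolerance = 0.01)
  expect_equal(tr$scale, 1.5, tolerance = 0.01)
  # identity on self-alignment
  tr0 <- attr(align_mantle(mi, mi), "transform")
  expect_lt(abs(tr0$rotation_rad), 1e-6)
  expect_equal(tr0$scale, 1, tolerance = 1e-6)
  # anterior flag flips by pi
  trf <- attr(align_mantle(mi, mi, flip_anterior = TRUE), "transform")
  expect_equal(abs(trf$rotation_rad), pi, tolerance = 1e-6)
  # degenerate mask
  tiny <- matrix(FALSE, 50, 50); tiny[25, 25] <- TRUE
  expect_error(mantle_image(matrix(0, 50, 50), tiny) |>
                 align_mantle(ref), "degenerate")
})
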