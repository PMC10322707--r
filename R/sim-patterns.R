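#' Configuration for the skin-pattern trajectory generator
#'
#' Parameters of [gen_pattern_trajectories()]. The generator emulates the
#' statistical structure of active-sleep pattern dynamics: a library of
#' macroscopic skin patterns shared across animals, living in a
#' `latent_rank`-dimensional subspace embedded in `dims`-dimensional feature
#' space (the published estimate of pattern-space dimensionality is ~60, with
#' 512-dimensional feature vectors). Each bout is a random itinerary through
#' a random subset of library patterns -- no stereotyped sequence -- starting
#' and ending at the designated "white" resting pattern, with
#' Ornstein-Uhlenbeck jitter around the itinerary and a small per-animal
#' offset (animals largely overlap in pattern space).
#'
#' The library latent coordinates are whitened so the pattern cloud is
#' exactly isotropic in the latent subspace (requires
#' `library_size > latent_rank`), which makes the latent dimensionality a
#' well-defined recovery target.
#'
#' @param n_animals animals.
#' @param n_bouts_per_animal AS bouts per animal.
#' @param dims ambient feature dimensionality.
#' @param library_size number of shared macroscopic patterns.
#' @param latent_rank true dimensionality of pattern space.
#' @param patterns_per_bout patterns visited per bout (excluding white).
#' @param dwell_frames mean frames spent at a visited pattern.
#' @param transit_frames frames of linear transit between patterns.
#' @param step_sd per-frame, per-latent-dimension jitter innovation SD.
#' @param jitter_rho AR(1) coefficient of the jitter process.
#' @param animal_offset_sd per-animal latent offset SD.
#' @param ambient_noise_sd isotropic ambient feature noise SD.
#' @param fps frames per second.
#' @param seed RNG seed.
#' @return list of class `pattern_sim_config`.
#' @export
pattern_sim_config <- function(n_animals = 3, n_bouts_per_animal = 8,
                               dims = 512, library_size = 70,
                               latent_rank = 60, patterns_per_bout = 20,
                               dwell_frames = 100, transit_frames = 25,
                               step_sd = 0.22, jitter_rho = 0.5,
                               animal_offset_sd = 0.1,
                               ambient_noise_sd = 0.02,
                               fps = 30, seed = 1) {
  cfg <- as.list(environment())
  if (cfg$library_size < 2) abort("library_size must be at least 2")
  stopifnot(cfg$latent_rank <= cfg$dims, cfg$fps > 0,
            cfg$patterns_per_bout >= 0, cfg$step_sd >= 0,
            abs(cfg$jitter_rho) < 1)
  class(cfg) <- "pattern_sim_config"
  cfg
}

# Whitened latent library: library_size points whose sample covariance is
# exactly isotropic with unit per-dimension variance (when library_size >
# latent_rank; otherwise raw centred Gaussian draws).
make_pattern_library <- function(cfg) {
  p <- matrix(rnorm(cfg$library_size * cfg$latent_rank),
              nrow = cfg$library_size)
  p <- sweep(p, 2, colMeans(p))
  if (cfg$library_size > cfg$latent_rank) {
    sv <- svd(p)
    p <- sqrt(cfg$library_size - 1) * sv$u %*% t(sv$v)
  }
  basis <- qr.Q(qr(matrix(rnorm(cfg$dims * cfg$latent_rank),
                          nrow = cfg$dims)))
  list(latent = p, basis = basis, white_index = 1L)
}

#' Generate synthetic skin-pattern trajectories with ground truth
#'
#' @param cfg a [pattern_sim_config()].
#' @return list with `trajectories` (list of [pattern_trajectory()]),
#'   `library` (list: `latent` library_size x latent_rank, `basis`
#'   dims x latent_rank, `white_index`, `ambient` library_size x dims) and
#'   `truth` (list: `visited` tibble of the per-bout pattern sequences,
#'   `animal_offsets`, `params`).
#' @export
gen_pattern_trajectories <- function(cfg = pattern_sim_config()) {
  stopifnot(inherits(cfg, "pattern_sim_config"))
  with_sim_seed(cfg$seed, {
    lib <- make_pattern_library(cfg)
    offsets <- matrix(rnorm(cfg$n_animals * cfg$latent_rank,
                            sd = cfg$animal_offset_sd),
                      nrow = cfg$n_animals)
    trajs <- list()
    visited_rows <- list()
    for (a in seq_len(cfg$n_animals)) {
      for (b in seq_len(cfg$n_bouts_per_animal)) {
        k <- min(cfg$patterns_per_bout, cfg$library_size - 1)
        others <- setdiff(seq_len(cfg$library_size), lib$white_index)
        seq_idx <- c(lib$white_index,
                     if (k > 0) sample(others, k) else integer(0),
                     lib$white_index)
        # dwell lengths (>=1 frame), linear transits between patterns
        dwells <- pmax(1L, stats::rpois(length(seq_idx), cfg$dwell_frames))
        legs <- list()
        for (i in seq_along(seq_idx)) {
          pt <- lib$latent[seq_idx[i], ]
          legs[[length(legs) + 1L]] <-
            matrix(pt, nrow = dwells[i], ncol = cfg$latent_rank, byrow = TRUE)
          if (i < length(seq_idx) && cfg$transit_frames > 0) {
            nxt <- lib$latent[seq_idx[i + 1], ]
            al <- seq_len(cfg$transit_frames) / (cfg$transit_frames + 1)
            legs[[length(legs) + 1L]] <-
              outer(1 - al, pt) + outer(al, nxt)
          }
        }
        z <- do.call(rbind, legs)
        tt <- nrow(z)
        if (cfg$step_sd > 0) {
          jit <- matrix(0, nrow = tt, ncol = cfg$latent_rank)
          innov <- matrix(rnorm(tt * cfg$latent_rank, sd = cfg$step_sd),
                          nrow = tt)
          for (t in 2:tt) {
            jit[t, ] <- cfg$jitter_rho * jit[t - 1, ] + innov[t, ]
          }
          jit[tt, ] <- 0                       # end exactly at white
          z <- z + jit
        }
        z <- sweep(z, 2, offsets[a, ], `+`)
        z[1, ] <- lib$latent[lib$white_index, ]  # exact white endpoints
        z[tt, ] <- lib$latent[lib$white_index, ]
        x <- z %*% t(lib$basis)
        if (cfg$ambient_noise_sd > 0) {
          no <- matrix(rnorm(tt * cfg$dims, sd = cfg$ambient_noise_sd),
                       nrow = tt)
          no[c(1, tt), ] <- 0
          x <- x + no
        }
        trajs[[length(trajs) + 1L]] <- pattern_trajectory(
          x, fps = cfg$fps, animal_id = paste0("a", a),
          bout_id = paste0("b", b))
        visited_rows[[length(visited_rows) + 1L]] <- tibble::tibble(
          animal_id = paste0("a", a), bout_id = paste0("b", b),
          order = seq_along(seq_idx), pattern = seq_idx)
      }
    }
    lib$ambient <- lib$latent %*% t(lib$basis)
    list(trajectories = trajs, library = lib,
         truth = list(visited = dplyr::bind_rows(visited_rows),
                      animal_offsets = offsets, params = cfg))
  })
}

#' Sample waking pattern vectors from the shared library
#'
#' Waking octopuses occasionally display library patterns in full; this
#' draws feature vectors at randomly chosen library patterns (patterns are
#' held stably while awake, so only ambient feature noise -- and optional
#' latent jitter -- is added), for use with [wake_in_as_test()].
#'
#' @param cfg the [pattern_sim_config()] used for the trajectories.
#' @param library the library returned by [gen_pattern_trajectories()].
#' @param n number of wake vectors.
#' @param jitter_sd latent jitter SD per dimension (default 0: the pattern
#'   is displayed in full).
#' @param seed RNG seed.
#' @return matrix n x dims.
#' @export
gen_wake_patterns <- function(cfg, library, n = 20, jitter_sd = 0, seed = 1) {
  with_sim_seed(seed, {
    idx <- sample(nrow(library$latent), n, replace = TRUE)
    z <- library$latent[idx, , drop = FALSE] +
      matrix(rnorm(n * cfg$latent_rank, sd = jitter_sd), nrow = n)
    z %*% t(library$basis) +
      matrix(rnorm(n * cfg$dims, sd = cfg$ambient_noise_sd), nrow = n)
  })
}

#' Configuration for the mantle image-pair generator
#'
#' Parameters of [gen_pattern_image_pair()]: a synthetic mottled mantle
#' texture (dark elliptical blobs plus band-limited noise on a bright
#' background) and a smoothly warped copy defined by control-point
#' displacements.
#'
#' @param size image size, pixels (rows, cols).
#' @param n_blobs dark blob count.
#' @param blob_radius_px blob radius range, pixels.
#' @param blob_depth blob darkness range, 8-bit units.
#' @param background background brightness, 8-bit units.
#' @param noise_sd band-limited texture noise SD, 8-bit units.
#' @param warp_mag_px typical control-point displacement magnitude, pixels
#'   (drawn uniform in 0.8-1.2 times this, random direction).
#' @param grid_n control-point grid (grid_n x grid_n).
#' @param seed RNG seed.
#' @return list of class `image_sim_config`.
#' @export
image_sim_config <- function(size = c(160, 160), n_blobs = 25,
                             blob_radius_px = c(4, 12),
                             blob_depth = c(80, 140), background = 220,
                             noise_sd = 6, warp_mag_px = 12, grid_n = 4,
                             seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$grid_n >= 2, cfg$warp_mag_px >= 0, all(cfg$size >= 32))
  class(cfg) <- "image_sim_config"
  cfg
}

# Smooth blurred-noise field via separable box smoothing passes.
smooth_noise_field <- function(nr, nc, sd, passes = 3, width = 9) {
  x <- matrix(rnorm(nr * nc), nr, nc)
  kern <- rep(1 / width, width)
  for (i in seq_len(passes)) {
    x <- apply(x, 2, function(col) {
      y <- stats::filter(col, kern, sides = 2, circular = TRUE)
      as.numeric(y)
    })
    x <- t(apply(x, 1, function(row) {
      as.numeric(stats::filter(row, kern, sides = 2, circular = TRUE))
    }))
  }
  x / stats::sd(x) * sd
}

#' Generate a synthetic mantle image pair related by a known smooth warp
#'
#' `image_a` is a mottled texture; `image_b` is `image_a` deformed by a
#' moving-least-squares warp whose control-point displacements are drawn from
#' the configuration. The exact control points are returned, so warping
#' `image_a` with them reproduces `image_b`. Displacement fields that would
#' fold the image over (non-positive Jacobian) raise an error.
#'
#' @param cfg an [image_sim_config()].
#' @return list with `image_a`, `image_b` (matrices, 8-bit scale) and
#'   `control_points` (tibble `x_src`, `y_src`, `x_dst`, `y_dst`).
#' @export
gen_pattern_image_pair <- function(cfg = image_sim_config()) {
  stopifnot(inherits(cfg, "image_sim_config"))
  with_sim_seed(cfg$seed, {
    nr <- cfg$size[1]; nc <- cfg$size[2]
    img <- matrix(cfg$background, nr, nc)
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (i in seq_len(cfg$n_blobs)) {
      cy <- runif(1, 0.1 * nr, 0.9 * nr); cx <- runif(1, 0.1 * nc, 0.9 * nc)
      r1 <- runif(1, cfg$blob_radius_px[1], cfg$blob_radius_px[2])
      r2 <- r1 * runif(1, 0.6, 1.4)
      th <- runif(1, 0, pi)
      dep <- runif(1, cfg$blob_depth[1], cfg$blob_depth[2])
      u <- (rr - cy) * cos(th) + (cc - cx) * sin(th)
      v <- -(rr - cy) * sin(th) + (cc - cx) * cos(th)
      img <- img - dep * exp(-((u / r1)^2 + (v / r2)^2))
    }
    if (cfg$noise_sd > 0) img <- img + smooth_noise_field(nr, nc, cfg$noise_sd)
    img <- pmin(pmax(img, 0), 255)

    gx <- seq(1, nc, length.out = cfg$grid_n)
    gy <- seq(1, nr, length.out = cfg$grid_n)
    src <- as.matrix(expand.grid(x = gx, y = gy))
    ang <- runif(nrow(src), 0, 2 * pi)
    mag <- cfg$warp_mag_px * runif(nrow(src), 0.8, 1.2)
    dst <- src + cbind(mag * cos(ang), mag * sin(ang))
    cps <- tibble::tibble(x_src = src[, 1], y_src = src[, 2],
                          x_dst = dst[, 1], y_dst = dst[, 2])
    check_warp_foldover(cps, nr, nc)
    image_b <- mls_warp(img, cps, background = cfg$background)
    list(image_a = img, image_b = image_b, control_points = cps)
  })
}

# Numerical Jacobian of the MLS forward map on a coarse grid; error on
# fold-over.
check_warp_foldover <- function(cps, nr, nc, n_grid = 15) {
  if (all(cps$x_src == cps$x_dst & cps$y_src == cps$y_dst)) return(invisible())
  gx <- seq(2, nc - 1, length.out = n_grid)
  gy <- seq(2, nr - 1, length.out = n_grid)
  pts <- as.matrix(expand.grid(x = gx, y = gy))
  h <- 0.5
  fwd <- function(p) mls_map(p, cbind(cps$x_src, cps$y_src),
                             cbind(cps$x_dst, cps$y_dst))
  f0x <- fwd(pts + cbind(rep(h, nrow(pts)), 0))
  f1x <- fwd(pts - cbind(rep(h, nrow(pts)), 0))
  f0y <- fwd(pts + cbind(0, rep(h, nrow(pts))))
  f1y <- fwd(pts - cbind(0, rep(h, nrow(pts))))
  jxx <- (f0x[, 1] - f1x[, 1]) / (2 * h); jyx <- (f0x[, 2] - f1x[, 2]) / (2 * h)
  jxy <- (f0y[, 1] - f1y[, 1]) / (2 * h); jyy <- (f0y[, 2] - f1y[, 2]) / (2 * h)
  detj <- jxx * jyy - jxy * jyx
  if (any(detj <= 0)) {
    abort("warp magnitude causes fold-over (non-positive Jacobian)")
  }
  invisible()
}
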