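# Shared oracles and small utilities for the test suite.

# Greedy one-to-one matching of detected to true event times.
match_events <- function(detected, truth, tol_s = 2) {
  used <- rep(FALSE, length(truth))
  tp <- 0L
  for (t in detected) {
    d <- abs(truth - t)
    d[used] <- Inf
    if (length(d) && min(d) <= tol_s) {
      tp <- tp + 1L
      used[which.min(d)] <- TRUE
    }
  }
  c(tp = tp, fp = length(detected) - tp, fn = length(truth) - tp)
}

# Histogram overlap coefficient of two samples on common breaks.
overlap_coefficient <- function(a, b, n_bins = 40) {
  br <- seq(min(a, b), max(a, b), length.out = n_bins + 1)
  pa <- hist(a, breaks = br, plot = FALSE)$counts / length(a)
  pb <- hist(b, breaks = br, plot = FALSE)$counts / length(b)
  sum(pmin(pa, pb))
}

# Exhaustive DTW: minimum total cost over all monotone warping paths from
# (1,1) to (na,nb) with diagonal/horizontal/vertical steps.
brute_force_dtw <- function(a, b) {
  cost <- as.matrix(stats::dist(rbind(a, b)))[seq_len(nrow(a)),
                                              nrow(a) + seq_len(nrow(b)),
                                              drop = FALSE]
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + cost[i, j]
    if (acc >= best) return()
    if (i == nrow(a) && j == nrow(b)) {
      best <<- acc
      return()
    }
    if (i < nrow(a) && j < nrow(b)) recurse(i + 1, j + 1, acc)
    if (i < nrow(a)) recurse(i + 1, j, acc)
    if (j < nrow(b)) recurse(i, j + 1, acc)
  }
  recurse(1L, 1L, 0)
  best
}

# Brute-force peak scan honouring height and separation (keep higher of two
# conflicting peaks), for cross-checking find_peaks on small signals.
brute_force_peaks <- function(x, min_height, min_separation) {
  cand <- which(diff(sign(diff(x))) == -2) + 1L
  cand <- cand[x[cand] >= min_height]
  keep <- integer(0)
  for (p in cand[order(x[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - p) >= min_separation)) {
      keep <- c(keep, p)
    }
  }
  sort(keep)
}

# Noise trace with injected negative Hann dips for detector recovery tests.
make_dip_trace <- function(dip_times_s, depth_sd = 5, dip_dur_s = 7,
                           duration_s = 600, fps = 24, noise_sd = 1,
                           baseline = 200, seed = 1) {
  withr::with_seed(seed, {
    n <- duration_s * fps
    v <- baseline + rnorm(n, 0, noise_sd)
    half <- round(dip_dur_s * fps / 2)
    for (t in dip_times_s) {
      c0 <- round(t * fps) + 1
      idx <- (c0 - half):(c0 + half)
      pulse <- 0.5 * (1 - cos(2 * pi * (seq_along(idx) - 1) / (length(idx) - 1)))
      v[idx] <- v[idx] - depth_sd * noise_sd * pulse
    }
    brightness_trace(v, fps)
  })
}

# Small LFP recording with the given number of channels; first `n_ob`
# channels are out-of-brain.
make_test_recording <- function(data, fs, n_ob = 2,
                                regions = NULL, probes = NULL) {
  n_ch <- nrow(data)
  if (is.null(regions)) {
    regions <- c(rep("outside", n_ob), rep("sFL", n_ch - n_ob))
  }
  if (is.null(probes)) probes <- rep(1L, n_ch)
  lfp_recording(data, fs, tibble::tibble(
    channel = seq_len(n_ch), x_um = 0, y_um = seq_len(n_ch) * 10, z_um = 0,
    region = regions, probe = probes,
    in_brain = seq_len(n_ch) > n_ob))
}
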