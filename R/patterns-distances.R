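# Euclidean cross-distance matrix between row sets (Ta x D, Tb x D).
cross_dist <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(a, b)
  # clamp catastrophic-cancellation dust so identical rows give exactly 0
  tol <- 1e-12 * (max(an, bn) + 1)
  d2[d2 < tol] <- 0
  sqrt(d2)
}

#' Start-align a pattern trajectory
#'
#' Finds the frame at which pattern dynamics begin: the first principal
#' component of the trajectory's feature-by-frame matrix is computed (per
#' trajectory), and the start is the first frame where the absolute
#' difference between neighbouring PC1 scores exceeds `threshold`. Returns
#' `NA` (a "no start" signal, distinct from frame 1) when the threshold is
#' never exceeded.
#'
#' @param traj a [pattern_trajectory()] or frames x dims matrix.
#' @param threshold derivative threshold on the PC1 score.
#' @return integer frame index, or `NA_integer_`.
#' @export
align_start <- function(traj, threshold = 0.1) {
  x <- traj_features(traj)
  if (nrow(x) < 3) abort("need at least 3 frames")
  if (all(apply(x, 2, stats::sd) == 0)) return(NA_integer_)
  pc1 <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 1)$x[, 1]
  d <- abs(diff(pc1))
  hit <- which(d > threshold)
  if (!length(hit)) return(NA_integer_)
  as.integer(hit[1])
}

#' Intra-trajectory distance
#'
#' Mean Euclidean distance between neighbouring points in time along a
#' trajectory.
#'
#' @param traj a [pattern_trajectory()] or frames x dims matrix.
#' @return scalar mean step distance; the per-step distances are attached as
#'   attribute `steps`.
#' @export
intra_distance <- function(traj) {
  x <- traj_features(traj)
  steps <- sqrt(rowSums((x[-1, , drop = FALSE] -
                           x[-nrow(x), , drop = FALSE])^2))
  out <- mean(steps)
  attr(out, "steps") <- steps
  out
}

#' Zero-lag inter-trajectory distance
#'
#' Mean element-wise Euclidean distance between two start-aligned
#' trajectories, from start to the end of the shorter trajectory.
#'
#' @param a,b trajectories or matrices.
#' @return scalar mean distance; per-frame distances attached as attribute
#'   `per_frame`.
#' @export
inter_distance <- function(a, b) {
  xa <- traj_features(a); xb <- traj_features(b)
  t_min <- min(nrow(xa), nrow(xb))
  d <- sqrt(rowSums((xa[seq_len(t_min), , drop = FALSE] -
                       xb[seq_len(t_min), , drop = FALSE])^2))
  out <- mean(d)
  attr(out, "per_frame") <- d
  out
}

#' Nearest-point distances between trajectories
#'
#' For each frame of `a`, the minimum Euclidean distance to any frame of
#' `b`, irrespective of time.
#'
#' @param a,b trajectories or matrices.
#' @return numeric vector, one minimum per frame of `a`.
#' @export
nearest_distances <- function(a, b) {
  xa <- traj_features(a); xb <- traj_features(b)
  d <- cross_dist(xa, xb)
  apply(d, 1, min)
}

#' Dynamic time warping between multivariate trajectories
#'
#' Full dynamic-programming DTW with Euclidean local cost, symmetric step
#' pattern (diagonal/horizontal/vertical moves, unit weights) and no window
#' constraint. Returns the minimum accumulated cost, the optimal warping
#' path, and the mean cost per path cell.
#'
#' @param a,b trajectories or matrices (frames x dims), at least 2 frames.
#' @return list with `total_cost`, `mean_cost`, `path` (tibble `ia`, `ib`).
#' @export
dtw_align <- function(a, b) {
  xa <- traj_features(a); xb <- traj_features(b)
  if (nrow(xa) < 2 || nrow(xb) < 2) abort("DTW needs at least 2 frames each")
  cost <- cross_dist(xa, xb)
  na <- nrow(cost); nb <- ncol(cost)
  acc <- matrix(Inf, na, nb)
  acc[1, 1] <- cost[1, 1]
  for (j in 2:nb) acc[1, j] <- acc[1, j - 1] + cost[1, j]
  for (i in 2:na) {
    acc[i, 1] <- acc[i - 1, 1] + cost[i, 1]
    prev <- acc[i - 1, ]
    row <- acc[i, ]
    for (j in 2:nb) {
      row[j] <- cost[i, j] + min(prev[j - 1], prev[j], row[j - 1])
    }
    acc[i, ] <- row
  }
  # traceback
  ia <- na; ib <- nb
  path <- list(c(na, nb))
  while (ia > 1 || ib > 1) {
    if (ia == 1) { ib <- ib - 1 }
    else if (ib == 1) { ia <- ia - 1 }
    else {
      opts <- c(acc[ia - 1, ib - 1], acc[ia - 1, ib], acc[ia, ib - 1])
      k <- which.min(opts)
      if (k == 1) { ia <- ia - 1; ib <- ib - 1 }
      else if (k == 2) { ia <- ia - 1 }
      else { ib <- ib - 1 }
    }
    path[[length(path) + 1L]] <- c(ia, ib)
  }
  path <- do.call(rbind, rev(path))
  list(total_cost = acc[na, nb],
       mean_cost = acc[na, nb] / nrow(path),
       path = tibble::tibble(ia = path[, 1], ib = path[, 2]))
}

#' DTW-to-zero-lag distance ratio
#'
#' The mean DTW alignment cost divided by the zero-lag inter-trajectory
#' distance (so values well below 1 mean temporal warping recovers a match
#' that the zero-lag comparison misses). The divisor can alternatively be
#' the mean cumulative path length of the two trajectories.
#'
#' @param a,b start-aligned trajectories or matrices.
#' @param divisor `"inter"` (zero-lag inter distance, default) or
#'   `"path_length"` (mean cumulative intra-trajectory path length).
#' @return scalar ratio (0 when the DTW cost is 0).
#' @export
dtw_ratio <- function(a, b, divisor = c("inter", "path_length")) {
  divisor <- match.arg(divisor)
  al <- dtw_align(a, b)
  if (al$total_cost == 0) return(0)
  den <- if (divisor == "inter") {
    as.numeric(inter_distance(a, b))
  } else {
    steps_a <- sum(attr(intra_distance(a), "steps"))
    steps_b <- sum(attr(intra_distance(b), "steps"))
    (steps_a + steps_b) / 2
  }
  if (den == 0) return(Inf)
  al$mean_cost / den
}

#' Trajectory distance summary across bouts
#'
#' Computes the three distance distributions used to characterize
#' active-sleep pattern dynamics -- consecutive-frame (intra) distances per
#' trajectory, nearest-point distances between trajectory pairs, and
#' zero-lag inter-trajectory distances -- averaged over bout pairs, plus the
#' DTW/zero-lag ratio per pair.
#'
#' @param trajectories list of [pattern_trajectory()] objects.
#' @param max_pairs optional cap on the number of trajectory pairs (pairs
#'   are taken in order).
#' @param dtw also compute the DTW ratio per pair (slower).
#' @param frame_stride subsample every `frame_stride`-th frame for the
#'   pairwise (nearest/inter/DTW) computations; intra distances always use
#'   consecutive original frames.
#' @return list with tibbles `intra` (`animal_id`, `bout_id`, `mean_intra`),
#'   `pairs` (`i`, `j`, `mean_nearest`, `mean_inter`, and `dtw_ratio` when
#'   requested) and a one-row `summary`.
#' @export
distance_summary <- function(trajectories, max_pairs = Inf, dtw = FALSE,
                             frame_stride = 1) {
  stopifnot(length(trajectories) >= 2)
  intra <- purrr::map_dfr(trajectories, function(tr) {
    tibble::tibble(animal_id = tr$animal_id, bout_id = tr$bout_id,
                   mean_intra = as.numeric(intra_distance(tr)))
  })
  pr <- utils::combn(length(trajectories), 2)
  if (ncol(pr) > max_pairs) pr <- pr[, seq_len(max_pairs), drop = FALSE]
  thin <- function(tr) {
    if (frame_stride <= 1) return(tr$features)
    tr$features[seq(1, nrow(tr$features), by = frame_stride), , drop = FALSE]
  }
  pairs <- purrr::map_dfr(seq_len(ncol(pr)), function(k) {
    i <- pr[1, k]; j <- pr[2, k]
    a <- thin(trajectories[[i]]); b <- thin(trajectories[[j]])
    row <- tibble::tibble(
      i = i, j = j,
      mean_nearest = mean(c(nearest_distances(a, b),
                            nearest_distances(b, a))),
      mean_inter = as.numeric(inter_distance(a, b)))
    if (dtw) row$dtw_ratio <- dtw_ratio(a, b)
    row
  })
  summary <- tibble::tibble(
    mean_intra = mean(intra$mean_intra),
    mean_nearest = mean(pairs$mean_nearest),
    mean_inter = mean(pairs$mean_inter),
    inter_intra_ratio = mean(pairs$mean_inter) / mean(intra$mean_intra))
  if (dtw) summary$mean_dtw_ratio <- mean(pairs$dtw_ratio)
  list(intra = intra, pairs = pairs, summary = summary)
}
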