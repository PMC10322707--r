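#' Parallel analysis estimate of data dimensionality
#'
#' Horn-style parallel analysis on a frames x dimensions matrix: the
#' dimensionality estimate is the number of leading eigenvalues of the
#' sample correlation matrix exceeding the chosen percentile of the
#' corresponding eigenvalues of surrogate matrices in which every column is
#' independently permuted (which preserves marginals but destroys
#' correlations). Rows are subsampled without replacement to `n_sample` when
#' the data are larger.
#'
#' @param x numeric matrix, frames x dims (D >= 2).
#' @param n_sample rows to subsample.
#' @param n_surrogates surrogate permutations.
#' @param percentile surrogate eigenvalue percentile (95 by default;
#'   `method = "mean"` uses Horn's original mean criterion).
#' @param method `"percentile"` or `"mean"`.
#' @param seed RNG seed for subsampling and permutations.
#' @return integer dimensionality estimate, with attribute `eigenvalues`
#'   (observed) and `threshold` (surrogate criterion).
#' @export
parallel_analysis <- function(x, n_sample = 10000, n_surrogates = 20,
                              percentile = 95,
                              method = c("percentile", "mean"), seed = 1) {
  method <- match.arg(method)
  if (ncol(x) < 2) abort("need at least 2 dimensions")
  with_sim_seed(seed, {
    if (nrow(x) > n_sample) x <- x[sample(nrow(x), n_sample), , drop = FALSE]
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      warn(sprintf("%d zero-variance column(s) dropped", sum(sds == 0)))
      x <- x[, sds > 0, drop = FALSE]
      if (ncol(x) < 2) abort("fewer than 2 non-constant dimensions")
    }
    ev <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
    sur <- matrix(0, nrow = n_surrogates, ncol = ncol(x))
    for (s in seq_len(n_surrogates)) {
      xp <- apply(x, 2, sample)
      sur[s, ] <- eigen(stats::cor(xp), symmetric = TRUE,
                        only.values = TRUE)$values
    }
    thr <- if (method == "percentile") {
      apply(sur, 2, stats::quantile, probs = percentile / 100)
    } else {
      colMeans(sur)
    }
    exceeds <- ev > thr
    est <- if (all(exceeds)) length(ev) else which(!exceeds)[1] - 1L
    structure(as.integer(est), eigenvalues = ev, threshold = thr)
  })
}

#' Silhouette score of animal identity in pattern space
#'
#' Standard Euclidean silhouette coefficient of the frames, using animal
#' identity as the cluster label, averaged over (subsampled) points. Scores
#' near 0 indicate animals' patterns largely overlap; near 1, well-separated
#' animals. Labels represented by a single sampled point are skipped.
#'
#' @param x numeric matrix, frames x dims.
#' @param animal_labels per-frame labels (length `nrow(x)`).
#' @param n_sample points to subsample.
#' @param seed RNG seed.
#' @return mean silhouette width (scalar).
#' @export
silhouette_by_animal <- function(x, animal_labels, n_sample = 10000,
                                 seed = 1) {
  stopifnot(nrow(x) == length(animal_labels))
  if (length(unique(animal_labels)) < 2) abort("need at least 2 animals")
  with_sim_seed(seed, {
    if (nrow(x) > n_sample) {
      idx <- sample(nrow(x), n_sample)
      x <- x[idx, , drop = FALSE]
      animal_labels <- animal_labels[idx]
    }
    counts <- table(animal_labels)
    keep <- animal_labels %in% names(counts)[counts > 1]
    x <- x[keep, , drop = FALSE]
    animal_labels <- animal_labels[keep]
    if (length(unique(animal_labels)) < 2) {
      abort("fewer than 2 animals with more than one sampled point")
    }
    sil <- cluster::silhouette(as.integer(factor(animal_labels)),
                               dist(x))
    mean(sil[, "sil_width"])
  })
}

#' Pool trajectory frames into one matrix with labels
#'
#' @param trajectories list of [pattern_trajectory()] objects.
#' @return list with `x` (pooled frames x dims matrix) and tibble `meta`
#'   (`animal_id`, `bout_id`, `frame`).
#' @export
pool_frames <- function(trajectories) {
  x <- do.call(rbind, lapply(trajectories, function(tr) tr$features))
  meta <- purrr::map_dfr(trajectories, function(tr) {
    tibble::tibble(animal_id = tr$animal_id, bout_id = tr$bout_id,
                   frame = seq_len(nrow(tr$features)))
  })
  list(x = x, meta = meta)
}

#' Project trajectories onto the first two principal components
#'
#' Principal components are fit on the pooled frames of all trajectories
#' (the "AS pattern space"); each trajectory is then projected onto the
#' first two components.
#'
#' @param trajectories list of [pattern_trajectory()] objects.
#' @return tibble with `animal_id`, `bout_id`, `frame`, `time_s`, `pc1`,
#'   `pc2`; the fitted `prcomp` object is attached as attribute `fit`.
#' @export
pca_project <- function(trajectories) {
  pooled <- pool_frames(trajectories)
  if (nrow(pooled$x) < 3) abort("need at least 3 pooled frames")
  if (all(apply(pooled$x, 2, stats::sd) == 0)) abort("zero-variance data")
  fit <- stats::prcomp(pooled$x, center = TRUE, scale. = FALSE, rank. = 2)
  out <- purrr::map_dfr(trajectories, function(tr) {
    sc <- scale(tr$features, center = fit$center, scale = FALSE) %*%
      fit$rotation
    tibble::tibble(animal_id = tr$animal_id, bout_id = tr$bout_id,
                   frame = seq_len(nrow(sc)),
                   time_s = (seq_len(nrow(sc)) - 1) / tr$fps,
                   pc1 = sc[, 1], pc2 = sc[, 2])
  })
  attr(out, "fit") <- fit
  out
}

#' Do waking patterns fall within active-sleep pattern space?
#'
#' For each waking feature vector, the nearest Euclidean distance to any AS
#' trajectory frame is computed and compared with the distribution of
#' intra-trajectory (consecutive-frame) distances. A wake vector is "within"
#' AS space when its nearest distance does not exceed the chosen quantile of
#' the intra distances; the overall criterion is that the median nearest
#' distance passes the same bound.
#'
#' @param wake_vectors matrix n x dims of waking pattern features.
#' @param as_trajectories list of AS [pattern_trajectory()] objects.
#' @param quantile_intra quantile of intra distances used as the bound.
#' @return list with `per_vector` tibble (`nearest`, `within`), `bound`,
#'   `fraction_within`, `median_nearest` and `within_space` (logical).
#' @export
wake_in_as_test <- function(wake_vectors, as_trajectories,
                            quantile_intra = 0.95) {
  if (!length(as_trajectories) || !nrow(wake_vectors)) abort("empty inputs")
  pooled <- pool_frames(as_trajectories)
  d <- cross_dist(wake_vectors, pooled$x)
  nearest <- apply(d, 1, min)
  intra_all <- unlist(lapply(as_trajectories, function(tr) {
    attr(intra_distance(tr), "steps")
  }))
  bound <- stats::quantile(intra_all, quantile_intra, names = FALSE)
  per_vector <- tibble::tibble(nearest = nearest, within = nearest <= bound)
  list(per_vector = per_vector, bound = bound,
       fraction_within = mean(per_vector$within),
       median_nearest = stats::median(nearest),
       within_space = stats::median(nearest) <= bound)
}
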