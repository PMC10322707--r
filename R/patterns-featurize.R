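#' Featurizer interface
#'
#' A featurizer maps a single-channel mantle image to a fixed-length feature
#' vector deterministically. The default implementation is a multi-scale
#' oriented filter bank ([default_featurizer()]); pretrained-network
#' featurizers can be plugged in through the same interface.
#'
#' @param name label.
#' @param dim output dimensionality.
#' @param transform function(image matrix) -> numeric vector of length
#'   `dim`.
#' @return list of class `featurizer`.
#' @export
featurizer <- function(name, dim, transform) {
  stopifnot(is.function(transform), dim >= 1)
  structure(list(name = name, dim = dim, transform = transform),
            class = "featurizer")
}

gabor_kernel <- function(wavelength, theta, sigma = 0.6 * wavelength) {
  half <- ceiling(2.5 * sigma)
  xs <- seq(-half, half)
  gx <- matrix(xs, 2 * half + 1, 2 * half + 1, byrow = TRUE)
  gy <- matrix(xs, 2 * half + 1, 2 * half + 1)
  xr <- gx * cos(theta) + gy * sin(theta)
  yr <- -gx * sin(theta) + gy * cos(theta)
  g <- exp(-(xr^2 + yr^2) / (2 * sigma^2)) *
    exp(1i * 2 * pi * xr / wavelength)
  g - mean(g)   # exact zero response to uniform images
}

# Centred FFT convolution with reflective padding (no artificial border
# edges: a uniform image yields an exactly uniform response).
fft_conv2 <- function(img, kern) {
  kr <- nrow(kern); kc <- ncol(kern)
  ro <- (kr - 1) %/% 2; co <- (kc - 1) %/% 2
  ri <- c(pmin(nrow(img), rev(seq_len(ro))), seq_len(nrow(img)),
          pmax(1, nrow(img) - seq_len(ro) + 1))
  ci <- c(pmin(ncol(img), rev(seq_len(co))), seq_len(ncol(img)),
          pmax(1, ncol(img) - seq_len(co) + 1))
  padded <- img[ri, ci, drop = FALSE]
  nr <- nrow(padded); nc <- ncol(padded)
  pr <- nr + kr - 1; pc <- nc + kc - 1
  a <- matrix(0 + 0i, pr, pc); a[1:nr, 1:nc] <- padded
  b <- matrix(0 + 0i, pr, pc); b[1:kr, 1:kc] <- kern
  full <- stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE) / (pr * pc)
  full[(1 + 2 * ro):(nrow(img) + 2 * ro), (1 + 2 * co):(ncol(img) + 2 * co)]
}

#' Filter-bank skin-pattern featurizer
#'
#' Deterministic 512-dimensional description of a mantle image: the modulus
#' (local energy) of a complex Gabor filter bank -- 4 wavelengths x 8
#' orientations -- averaged over a 4 x 4 spatial grid of cells, concatenated
#' as scale x orientation x cell. Kernels have exactly zero DC response, so
#' a uniform image maps to the zero vector.
#'
#' @param image numeric matrix (single-channel, 8-bit scale), background
#'   masked to uniform grey.
#' @param wavelengths_px filter wavelengths, pixels.
#' @param n_orientations orientation count.
#' @param grid_n pooling grid (grid_n x grid_n cells).
#' @return numeric feature vector of length
#'   `length(wavelengths_px) * n_orientations * grid_n^2` (512 by default).
#' @export
default_featurizer <- function(image, wavelengths_px = c(4, 8, 16, 32),
                               n_orientations = 8, grid_n = 4) {
  if (!is.matrix(image)) abort("image must be a matrix")
  if (!all(is.finite(image))) abort("non-finite pixels in image")
  img <- image / 255
  nr <- nrow(img); nc <- ncol(img)
  rb <- floor(seq(0, nr, length.out = grid_n + 1))
  cb <- floor(seq(0, nc, length.out = grid_n + 1))
  feats <- numeric(0)
  for (wl in wavelengths_px) {
    for (o in seq_len(n_orientations)) {
      theta <- (o - 1) * pi / n_orientations
      resp <- Mod(fft_conv2(img, gabor_kernel(wl, theta)))
      for (i in seq_len(grid_n)) {
        for (j in seq_len(grid_n)) {
          cell <- resp[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1]]
          feats <- c(feats, mean(cell))
        }
      }
    }
  }
  feats
}

#' @rdname default_featurizer
#' @export
filter_bank_featurizer <- function(wavelengths_px = c(4, 8, 16, 32),
                                   n_orientations = 8, grid_n = 4) {
  dim <- length(wavelengths_px) * n_orientations * grid_n^2
  featurizer("filter_bank", dim, function(image) {
    default_featurizer(image, wavelengths_px, n_orientations, grid_n)
  })
}
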