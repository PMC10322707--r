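#' Mantle image container
#'
#' @param pixels numeric matrix (8-bit grey scale).
#' @param mask logical matrix of the foreground mantle (same size); default
#'   marks pixels darker than the modal background.
#' @param pixel_scale pixels per mm, if known.
#' @return list of class `mantle_image`.
#' @export
mantle_image <- function(pixels, mask = NULL, pixel_scale = NA_real_) {
  stopifnot(is.matrix(pixels))
  if (is.null(mask)) mask <- pixels < stats::quantile(pixels, 0.5)
  stopifnot(is.logical(mask), all(dim(mask) == dim(pixels)))
  if (!any(mask)) abort("empty mantle mask")
  structure(list(pixels = pixels, mask = mask, pixel_scale = pixel_scale),
            class = "mantle_image")
}

# Second-moment ellipse of a logical mask: centroid, axis angle, axis SDs.
mask_ellipse <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 100) abort("degenerate mask (area < 100 px)")
  y <- idx[, 1]; x <- idx[, 2]
  cx <- mean(x); cy <- mean(y)
  cm <- stats::cov(cbind(x - cx, y - cy))
  eg <- eigen(cm, symmetric = TRUE)
  ang <- atan2(eg$vectors[2, 1], eg$vectors[1, 1])
  list(cx = cx, cy = cy, angle = ang,
       major_sd = sqrt(eg$values[1]), minor_sd = sqrt(max(eg$values[2], 0)))
}

bilinear_sample <- function(img, x, y, background) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & y0 >= 1 & x0 + 1 <= nc & y0 + 1 <= nr
  out <- rep(background, length(x))
  if (any(ok)) {
    i00 <- (x0[ok] - 1) * nr + y0[ok]
    v00 <- img[i00]; v01 <- img[i00 + nr]
    v10 <- img[i00 + 1]; v11 <- img[i00 + nr + 1]
    fxo <- fx[ok]; fyo <- fy[ok]
    out[ok] <- v00 * (1 - fxo) * (1 - fyo) + v01 * fxo * (1 - fyo) +
      v10 * (1 - fxo) * fyo + v11 * fxo * fyo
  }
  out
}

#' Align a mantle image onto a reference by ellipse fit and similarity
#' transform
#'
#' Fits a second-moment ellipse to each mantle mask and maps the image onto
#' the reference by the similarity transform (rotation, isotropic scale,
#' translation) carrying the image ellipse's centre and major axis onto the
#' reference's. The aligned image is cropped to the reference mask bounding
#' box, downsampled (default to 20% size), and its background painted
#' uniform grey. The major axis carries a 180-degree ambiguity; the
#' anterior/posterior direction is an explicit input flag.
#'
#' @param image,reference [mantle_image()] objects.
#' @param flip_anterior flip the image 180 degrees before aligning.
#' @param downsample output scale relative to the reference crop.
#' @param background background grey level.
#' @return `mantle_image` in reference coordinates, with the fitted
#'   transform (`rotation_rad`, `scale`) attached as attribute `transform`.
#' @export
align_mantle <- function(image, reference, flip_anterior = FALSE,
                         downsample = 0.2, background = 127) {
  stopifnot(inherits(image, "mantle_image"),
            inherits(reference, "mantle_image"))
  ei <- mask_ellipse(image$mask)
  er <- mask_ellipse(reference$mask)
  rot <- er$angle - ei$angle + if (flip_anterior) pi else 0
  sc <- er$major_sd / ei$major_sd
  # reference crop grid
  idx <- which(reference$mask, arr.ind = TRUE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  out_nr <- max(2, round((r1 - r0 + 1) * downsample))
  out_nc <- max(2, round((c1 - c0 + 1) * downsample))
  ys <- seq(r0, r1, length.out = out_nr)
  xs <- seq(c0, c1, length.out = out_nc)
  gx <- rep(xs, each = out_nr)
  gy <- rep(ys, times = out_nc)
  # backward map: reference coords -> image coords
  dx <- gx - er$cx; dy <- gy - er$cy
  ca <- cos(-rot); sa <- sin(-rot)
  sx <- (ca * dx - sa * dy) / sc + ei$cx
  sy <- (sa * dx + ca * dy) / sc + ei$cy
  src_pix <- image$pixels
  src_pix[!image$mask] <- background     # uniform grey background
  vals <- bilinear_sample(src_pix, sx, sy, background)
  maskv <- bilinear_sample(image$mask * 1, sx, sy, 0) > 0.5
  pix <- matrix(vals, nrow = out_nr)
  msk <- matrix(maskv, nrow = out_nr)
  pix[!msk] <- background
  out <- mantle_image(pix, msk, reference$pixel_scale)
  attr(out, "transform") <- list(rotation_rad = rot, scale = sc,
                                 center_src = c(ei$cx, ei$cy),
                                 center_ref = c(er$cx, er$cy))
  out
}

#' Control-point moving-least-squares map
#'
#' Similarity-variant moving least squares: for each query point, a weighted
#' similarity transform (rotation + isotropic scale) is fit to the control
#' pairs with inverse-square distance weights, so the deformation
#' interpolates the control points exactly and reduces to the global
#' similarity transform when one exists.
#'
#' @param points numeric matrix n x 2 of query points (x, y).
#' @param src,dst numeric matrices m x 2 of paired control points.
#' @return numeric matrix n x 2 of mapped points.
#' @export
mls_map <- function(points, src, dst) {
  stopifnot(ncol(points) == 2, nrow(src) == nrow(dst), nrow(src) >= 1)
  v <- complex(real = points[, 1], imaginary = points[, 2])
  p <- complex(real = src[, 1], imaginary = src[, 2])
  q <- complex(real = dst[, 1], imaginary = dst[, 2])
  d2 <- outer(v, p, function(a, b) Mod(a - b)^2)
  hit <- d2 < 1e-12
  d2[hit] <- 1e-12
  w <- 1 / d2
  wsum <- rowSums(w)
  pstar <- as.vector(w %*% p) / wsum
  qstar <- as.vector(w %*% q) / wsum
  phat <- outer(rep(1, length(v)), p) - pstar
  qhat <- outer(rep(1, length(v)), q) - qstar
  num <- rowSums(w * Conj(phat) * qhat)
  den <- rowSums(w * Mod(phat)^2)
  z <- num / den
  f <- z * (v - pstar) + qstar
  # exact interpolation at control points
  if (any(hit)) {
    rows <- which(rowSums(hit) > 0)
    for (r in rows) f[r] <- q[which(hit[r, ])[1]]
  }
  cbind(Re(f), Im(f))
}

check_control_points <- function(cps) {
  need <- c("x_src", "y_src", "x_dst", "y_dst")
  if (!all(need %in% names(cps))) {
    abort("control points need columns x_src, y_src, x_dst, y_dst")
  }
  if (nrow(cps) < 3) abort("need at least 3 control points")
  src <- cbind(cps$x_src, cps$y_src)
  if (anyDuplicated(src)) abort("duplicate source control points")
  cen <- sweep(src, 2, colMeans(src))
  if (qr(cen)$rank < 2) abort("control points are collinear")
  invisible(cps)
}

#' Warp an image by moving-least-squares control points
#'
#' Deforms `image` so that each source control point lands on its
#' destination, interpolating smoothly in between ([mls_map()]). Uses
#' backward mapping (the inverse correspondence is queried at every output
#' pixel) with bilinear sampling; pixels mapping outside the input are
#' filled with `background`.
#'
#' @param image numeric matrix.
#' @param cps control-point tibble (`x_src`, `y_src`, `x_dst`, `y_dst`);
#'   at least 3 non-collinear pairs, x = column, y = row.
#' @param background fill value.
#' @return warped matrix, same size as `image`.
#' @export
mls_warp <- function(image, cps, background = 127) {
  stopifnot(is.matrix(image))
  check_control_points(cps)
  if (all(cps$x_src == cps$x_dst & cps$y_src == cps$y_dst)) return(image)
  nr <- nrow(image); nc <- ncol(image)
  gx <- rep(seq_len(nc), each = nr)
  gy <- rep(seq_len(nr), times = nc)
  srcpos <- mls_map(cbind(gx, gy),
                    src = cbind(cps$x_dst, cps$y_dst),
                    dst = cbind(cps$x_src, cps$y_src))
  vals <- bilinear_sample(image, srcpos[, 1], srcpos[, 2], background)
  matrix(vals, nrow = nr)
}

otsu_threshold <- function(img) {
  h <- tabulate(pmin(255, pmax(0, floor(img))) + 1, nbins = 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) - 1
}

#' Threshold-overlap comparison of two pattern images
#'
#' Inverts both greyscale images (dark pattern regions become bright),
#' binarizes each at an image-specific 8-bit threshold -- Otsu's threshold
#' clipped to the 180-230 interval unless given explicitly -- and scores the
#' pattern match as the intersection-over-union of the two masks.
#'
#' @param image_a,image_b numeric matrices of equal size (8-bit scale).
#' @param thresh explicit threshold(s) in `[0, 255]` applied to the inverted
#'   images (length 1 or 2), or `NULL` for per-image Otsu clipped to
#'   `clip`.
#' @param clip clipping interval for the automatic threshold.
#' @return list with `mask_a`, `mask_b` (logical matrices), `threshold`
#'   (length 2) and `iou`.
#' @export
threshold_match <- function(image_a, image_b, thresh = NULL,
                            clip = c(180, 230)) {
  stopifnot(all(dim(image_a) == dim(image_b)))
  inv_a <- 255 - image_a
  inv_b <- 255 - image_b
  if (is.null(thresh)) {
    th <- c(min(max(otsu_threshold(inv_a), clip[1]), clip[2]),
            min(max(otsu_threshold(inv_b), clip[1]), clip[2]))
  } else {
    stopifnot(all(thresh >= 0 & thresh <= 255))
    th <- rep_len(thresh, 2)
  }
  mask_a <- inv_a >= th[1]
  mask_b <- inv_b >= th[2]
  union <- sum(mask_a | mask_b)
  if (union == 0) abort("both masks are empty; overlap undefined")
  list(mask_a = mask_a, mask_b = mask_b, threshold = th,
       iou = sum(mask_a & mask_b) / union)
}
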