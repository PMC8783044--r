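#' Gaussian PSF model
#'
#' Separable Gaussian approximation of the microscope point spread function,
#' parameterized by its lateral (x, y) and axial (z) standard deviations in
#' micrometres. Discretized kernels are truncated at 4 sigma and renormalized
#' to unit sum.
#'
#' @param sigma_lateral lateral standard deviation, um.
#' @param sigma_axial axial standard deviation, um.
#' @return an object of class `psf_model`.
#' @export
psf_model <- function(sigma_lateral, sigma_axial) {
  if (!is.finite(sigma_lateral) || sigma_lateral <= 0 ||
      !is.finite(sigma_axial) || sigma_axial <= 0)
    stop("PSF sigmas must be strictly positive")
  structure(list(sigma_lateral = sigma_lateral, sigma_axial = sigma_axial),
            class = "psf_model")
}

# 1D Gaussian kernel, sigma in voxel units, truncated at 4 sigma, unit sum
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# banded convolution matrix for an odd-length kernel, zero boundary
kernel_matrix <- function(n, k) {
  half <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (o in seq(-half, half)) {
    idx <- seq_len(n - abs(o))
    w <- k[o + half + 1L]
    if (o >= 0) K[cbind(idx + o, idx)] <- w else K[cbind(idx, idx - o)] <- w
  }
  K
}

# separable convolution of a 3D array along one axis (zero boundary)
conv_axis <- function(a, k, axis) {
  if (length(k) == 1L) return(a * k)
  d <- dim(a)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  b <- aperm(a, perm)
  db <- dim(b)
  m <- kernel_matrix(db[1], k) %*% matrix(b, nrow = db[1])
  dim(m) <- db
  aperm(m, order(perm))
}

# blur a (z,y,x) array with a separable Gaussian PSF; voxel_size = (dz,dy,dx) um
blur_psf <- function(a, psf, voxel_size) {
  sig <- c(psf$sigma_axial, psf$sigma_lateral, psf$sigma_lateral) / voxel_size
  for (ax in 1:3) a <- conv_axis(a, gaussian_kernel_1d(sig[ax]), ax)
  a
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative Richardson-Lucy update under a separable Gaussian
#' PSF. Intensities stay non-negative at every iteration; the denominator is
#' floored at `1e-12` to avoid division by zero in empty regions.
#'
#' @param grid a [voxel_grid()] with non-negative intensities.
#' @param psf a [psf_model()].
#' @param n_iter number of iterations (default 20).
#' @return the deconvolved [voxel_grid()].
#' @export
richardson_lucy <- function(grid, psf, n_iter = 20L) {
  stopifnot(is_voxel_grid(grid), inherits(psf, "psf_model"))
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop("`n_iter` must be at least 1")
  a <- grid$values
  if (any(a < 0)) stop("Richardson-Lucy requires non-negative intensities")
  if (all(a == 0)) {
    warning("all-zero input: returned unchanged")
    return(grid)
  }
  eps <- 1e-12
  est <- a
  for (i in seq_len(n_iter)) {
    denom <- pmax(blur_psf(est, psf, grid$voxel_size), eps)
    # Gaussian kernels are symmetric, so the adjoint blur equals the blur
    est <- est * blur_psf(a / denom, psf, grid$voxel_size)
  }
  voxel_grid(pmax(est, 0), grid$voxel_size, channel = grid$channel,
             time = grid$time)
}

# translate a matrix by integer (dy, dx), zero fill
shift_image <- function(img, dy, dx) {
  d <- dim(img)
  out <- matrix(0, d[1], d[2])
  ys <- seq_len(d[1]); xs <- seq_len(d[2])
  ysrc <- ys - dy; xsrc <- xs - dx
  keep_y <- ysrc >= 1 & ysrc <= d[1]
  keep_x <- xsrc >= 1 & xsrc <= d[2]
  out[ys[keep_y], xs[keep_x]] <- img[ysrc[keep_y], xsrc[keep_x]]
  out
}

# integer-pixel shift taking frame `a` to frame `b`, by FFT cross-correlation;
# optional parabolic sub-pixel refinement
estimate_shift <- function(a, b, subpixel = FALSE) {
  stopifnot(identical(dim(a), dim(b)))
  if (sd(a) == 0 || sd(b) == 0) {
    warning("constant frame: returning zero shift")
    return(c(0, 0))
  }
  d <- dim(a)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE))
  p <- which(cc == max(cc), arr.ind = TRUE)[1, ] - 1L  # 0-based
  s <- ifelse(p > d / 2, p - d, p)
  if (any(abs(s) >= d / 2))
    stop("shift at or beyond half the frame size: ambiguous wrap")
  # cross-correlation peaks at index +s when b(x) = a(x - s); report s such
  # that b == shift_image(a, s)
  s <- -s
  if (subpixel) {
    refine <- function(axis) {
      grab <- function(off) {
        idx <- (p + if (axis == 1) c(off, 0) else c(0, off)) %% d
        cc[idx[1] + 1L, idx[2] + 1L]
      }
      y0 <- grab(-1); y1 <- grab(0); y2 <- grab(1)
      den <- (y0 - 2 * y1 + y2)
      if (den == 0) 0 else 0.5 * (y0 - y2) / den
    }
    s <- s - c(refine(1), refine(2))
  }
  unname(s)
}

#' Translation registration of a frame series
#'
#' Estimates consecutive-frame translations by the cross-correlation peak
#' (integer pixels; optional sub-pixel refinement by parabolic interpolation of
#' the correlation peak), accumulates them against frame 1, and shifts every
#' frame back onto frame 1 with zero fill.
#'
#' @param frames list of equally sized 2D matrices (a time series).
#' @param subpixel report sub-pixel shift estimates (applied shifts are rounded
#'   to integer pixels).
#' @return list with `shifts` (n x 2 matrix of cumulative `(dy, dx)` per frame,
#'   relative to frame 1) and `registered` (list of shifted frames).
#' @export
register_translation <- function(frames, subpixel = FALSE) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("need a list of at least 2 frames")
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("all frames must share the same shape")
  n <- length(frames)
  shifts <- matrix(0, n, 2, dimnames = list(NULL, c("dy", "dx")))
  for (i in 2:n) {
    s <- estimate_shift(frames[[i - 1]], frames[[i]], subpixel = subpixel)
    shifts[i, ] <- shifts[i - 1, ] + s
  }
  registered <- vector("list", n)
  registered[[1]] <- frames[[1]]
  for (i in 2:n) {
    s <- round(shifts[i, ])
    registered[[i]] <- shift_image(frames[[i]], -s[1], -s[2])
  }
  list(shifts = shifts, registered = registered)
}

project_along <- function(a, axis, fun) {
  if (is.matrix(a)) return(a)  # idempotent on 2D input
  stopifnot(length(dim(a)) == 3L)
  axis <- if (is.character(axis)) match(axis, c("z", "y", "x")) else as.integer(axis)
  if (is.na(axis) || axis < 1L || axis > 3L) stop("invalid projection axis")
  apply(a, setdiff(1:3, axis), fun)
}

#' Maximum / summed intensity projection
#'
#' @param grid a [voxel_grid()] or a 3D `(z,y,x)` array; a 2D matrix is
#'   returned unchanged.
#' @param axis axis to collapse: `"z"`, `"y"`, `"x"` or 1..3. Projecting over
#'   `"z"` yields the usual `(y, x)` image.
#' @return a 2D matrix.
#' @export
max_project <- function(grid, axis = "z") {
  project_along(as_grid_values(grid), axis, max)
}

#' @rdname max_project
#' @export
sum_project <- function(grid, axis = "z") {
  project_along(as_grid_values(grid), axis, sum)
}

#' Crop an image centred on its brightest pixel
#'
#' Standard preparation of AC time-lapse frames before binarization: the frame
#' is cropped to `crop_h` x `crop_w` pixels (default 90 x 144, the
#' field-standard crop) with the brightest pixel at the centre pixel
#' `(floor(h/2) + 1, floor(w/2) + 1)`. Ties are broken towards the first
#' maximum in row-major order; regions outside the original image are
#' zero-padded.
#'
#' @param image 2D matrix.
#' @param crop_h,crop_w crop height and width in pixels.
#' @return `crop_h` x `crop_w` matrix.
#' @export
center_crop_on_peak <- function(image, crop_h = 90L, crop_w = 144L) {
  stopifnot(is.matrix(image))
  crop_at(image, find_peak(image), crop_h, crop_w)
}

# brightest pixel, first in row-major order on ties
find_peak <- function(image) {
  idx <- which(image == max(image), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
}

# crop_h x crop_w window with `center` (y, x) at the centre pixel, zero-padded
crop_at <- function(image, center, crop_h, crop_w) {
  stopifnot(crop_h >= 1, crop_w >= 1)
  cy <- floor(crop_h / 2) + 1L
  cx <- floor(crop_w / 2) + 1L
  out <- matrix(0, crop_h, crop_w)
  ys <- seq_len(crop_h) - cy + center[1]
  xs <- seq_len(crop_w) - cx + center[2]
  keep_y <- ys >= 1 & ys <= nrow(image)
  keep_x <- xs >= 1 & xs <= ncol(image)
  out[keep_y, keep_x] <- image[ys[keep_y], xs[keep_x]]
  out
}

otsu_threshold <- function(image) {
  rg <- range(image)
  if (diff(rg) == 0)
    stop("uniform image: Otsu threshold undefined (no bimodality)")
  EBImage::otsu(EBImage::Image(image), range = rg)
}

#' Binarize an image
#'
#' `fixed-normalized` (the default) scales intensities by the image (or
#' supplied reference) maximum and keeps pixels at or above `level`; the
#' default level of 0.05 is the constant threshold used for AC reporter
#' channels. The Otsu modes compute the threshold either on a supplied
#' reference frame (`otsu-first-frame`) or on the image itself
#' (`otsu-per-frame`).
#'
#' @param image 2D or 3D numeric array.
#' @param mode `"fixed-normalized"`, `"otsu-first-frame"` or `"otsu-per-frame"`.
#' @param level threshold as a fraction of the maximum (fixed mode).
#' @param reference for `fixed-normalized`, an optional scalar maximum to
#'   normalize by (e.g. the stack-wide maximum); for `otsu-first-frame`, the
#'   frame on which to compute the threshold.
#' @return logical mask with the shape of `image`.
#' @export
binarize <- function(image,
                     mode = c("fixed-normalized", "otsu-first-frame",
                              "otsu-per-frame"),
                     level = 0.05, reference = NULL) {
  mode <- match.arg(mode)
  image <- as_grid_values(image)
  if (mode == "fixed-normalized") {
    mx <- if (is.null(reference)) max(image) else as.numeric(reference)
    if (mx <= 0) {
      warning("all-zero image: empty mask")
      return(array(FALSE, dim = dim(image)))
    }
    return(image / mx >= level)
  }
  thr <- if (mode == "otsu-first-frame") {
    if (is.null(reference)) stop("otsu-first-frame mode needs a reference frame")
    otsu_threshold(as_grid_values(reference))
  } else {
    otsu_threshold(image)
  }
  image > thr
}
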