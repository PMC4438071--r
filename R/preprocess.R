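# Preprocessing operators: adaptive Wiener denoising, Gaussian pyramid with
# per-level resizing, and linear temporal resampling to a fixed frame count.

# Moving-window box mean with edge-replication padding.
box_mean <- function(img, window) {
  wr <- window[1]; wc <- window[2]
  hr <- (wr - 1) %/% 2; hc <- (wc - 1) %/% 2
  p <- pad_replicate(img, hr, hr, hc, hc)
  out <- matrix(0, nrow(img), ncol(img))
  for (dr in 0:(wr - 1))
    for (dc in 0:(wc - 1))
      out <- out + p[dr + seq_len(nrow(img)), dc + seq_len(ncol(img)), drop = FALSE]
  out / (wr * wc)
}

#' Adaptive (local) Wiener filter
#'
#' Classical pixel-wise adaptive Wiener denoising: within a sliding window
#' the local mean `m` and local variance `v` are estimated, and the output
#' is `m + max(0, v - nu) / max(v, nu) * (pixel - m)` where `nu` is the
#' noise variance.  Where the local variance is at or below the noise level
#' the pixel collapses to the local mean; where it is far above, the pixel
#' passes through nearly unchanged.  Edges are handled by replication, so a
#' constant image is returned unchanged.
#'
#' @param img Numeric matrix of intensities.
#' @param window Odd window dimensions `(rows, cols)`; default `c(3, 3)`.
#' @param noise Noise variance; `NULL` (default) estimates it as the mean of
#'   the local variances, the standard automatic rule.
#' @return Filtered image of the same dimensions.
#' @export
wiener_filter <- function(img, window = c(3, 3), noise = NULL) {
  check_image(img)
  stopifnot(length(window) == 2, all(window >= 1), all(window %% 2 == 1))
  if (window[1] > nrow(img) || window[2] > ncol(img))
    stop("Wiener window larger than the image", call. = FALSE)
  m <- box_mean(img, window)
  v <- pmax(box_mean(img^2, window) - m^2, 0)
  if (is.null(noise)) noise <- mean(v)
  if (noise < 0) stop("noise variance must be non-negative", call. = FALSE)
  gain <- ifelse(v > noise, (v - noise) / v, 0)
  m + gain * (img - m)
}

# Separable 5-tap binomial smoothing [1,4,6,4,1]/16 with reflective borders.
binomial_smooth <- function(img) {
  k <- c(1, 4, 6, 4, 1) / 16
  conv1 <- function(m) {  # along rows (i.e. down columns)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in -2:2) {
      idx <- seq_len(n) + j
      idx <- ifelse(idx < 1, 2 - idx, ifelse(idx > n, 2 * n - idx, idx))
      idx <- pmin(pmax(idx, 1L), n)  # tiny images: clamp residual overshoot
      out <- out + k[j + 3] * m[idx, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(img))))
}

#' Bilinear image resize
#'
#' Resizes with corner-aligned bilinear interpolation: output pixel `(i, j)`
#' (0-based) samples the input at
#' `(i * (h - 1) / (H - 1), j * (w - 1) / (W - 1))`.
#'
#' @param img Numeric matrix.
#' @param size Target `(height, width)`.
#' @return Resized matrix.
#' @export
resize_bilinear <- function(img, size) {
  check_image(img)
  stopifnot(length(size) == 2, all(size >= 1))
  H <- size[1]; W <- size[2]
  ys <- if (H == 1) 0 else (seq_len(H) - 1) * (nrow(img) - 1) / (H - 1)
  xs <- if (W == 1) 0 else (seq_len(W) - 1) * (ncol(img) - 1) / (W - 1)
  grid <- expand.grid(y = ys, x = xs)
  matrix(sample_intensity(img, grid$x, grid$y), H, W)
}

#' Gaussian pyramid of an image
#'
#' Level 1 is the input; each further level smooths the previous one with
#' the separable 5-tap binomial kernel `[1,4,6,4,1]/16` (reflective borders)
#' and keeps every second pixel (even 0-based indices), so an `n`-pixel axis
#' becomes `ceiling(n/2)`.  When `resize_to` is given, every level is then
#' resized bilinearly to that common shape, the form consumed by the
#' descriptor functions in multiscale experiments.
#'
#' @param img Numeric matrix.
#' @param levels Number of pyramid levels (>= 1).
#' @param resize_to Optional `(height, width)` applied to every level after
#'   downsampling; `NULL` keeps native per-level shapes.
#' @return List of `levels` images, coarsest last.
#' @export
#' @examples
#' p <- gaussian_pyramid(matrix(runif(64 * 48), 64, 48), levels = 3)
#' vapply(p, nrow, 1L)  # 64 32 16
gaussian_pyramid <- function(img, levels = 4, resize_to = NULL) {
  check_image(img)
  stopifnot(is_count(levels))
  out <- vector("list", levels)
  cur <- img
  for (k in seq_len(levels)) {
    if (k > 1) {
      if (nrow(cur) < 2 || ncol(cur) < 2)
        stop(sprintf("image exhausted at pyramid level %d; reduce `levels`", k),
             call. = FALSE)
      sm <- binomial_smooth(cur)
      cur <- sm[seq(1, nrow(sm), by = 2), seq(1, ncol(sm), by = 2), drop = FALSE]
    }
    out[[k]] <- cur
  }
  if (!is.null(resize_to)) out <- lapply(out, resize_bilinear, size = resize_to)
  out
}

#' Linear temporal resampling of a video volume
#'
#' Resamples a video to a fixed number of frames by per-voxel linear
#' interpolation at `target_length` positions uniformly spaced over the
#' original temporal extent; the first and last frames are preserved
#' exactly.  This is the package's plain stand-in for model-based temporal
#' interpolation schemes used to normalize clip length (e.g. to 10 frames)
#' before descriptor extraction.
#'
#' @param video Numeric 3-D array (height x width x length), length >= 2.
#' @param target_length Number of output frames (>= 2).
#' @return Resampled video of shape height x width x `target_length`.
#' @export
temporal_resample <- function(video, target_length) {
  check_video(video)
  l <- dim(video)[3]
  if (l < 2) stop("video must have at least 2 frames", call. = FALSE)
  if (!is_count(target_length) || target_length < 2)
    stop("`target_length` must be an integer >= 2", call. = FALSE)
  pos <- seq(0, l - 1, length.out = target_length)
  out <- array(0, c(dim(video)[1:2], target_length))
  for (i in seq_len(target_length)) {
    t0 <- min(floor(pos[i]), l - 2); f <- pos[i] - t0
    out[, , i] <- (1 - f) * video[, , t0 + 1] + f * video[, , t0 + 2]
  }
  out
}
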