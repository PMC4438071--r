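# Seeded synthetic video corpora emulating multi-subject, multi-class
# collections of subtle moving textures, so descriptors and the evaluation
# harness are testable end-to-end without restricted data.

#' Synthetic corpus specification
#'
#' Describes a labeled multi-subject corpus of subtle dynamic textures.
#' Each subject carries an individual band-limited base texture (an identity
#' confound, as in real face data); the class signal is a small Gabor patch
#' whose sinusoidal carrier drifts over time at a class-specific speed while
#' its spatial structure is shared across classes — so class information
#' lives in the temporal dynamics, not in any single frame's appearance.
#' Sensor noise is i.i.d. Gaussian per voxel.
#'
#' Intensities are on a 0–255 scale.  Defaults describe the study
#' conditions used throughout the package's tests: 16 subjects with 2 clips
#' each over 3 classes (the leave-one-subject-out geometry of small
#' micro-movement corpora), 24 x 24 frames, 10 frames per clip (the usual
#' length-normalized clip), drift amplitude 16 against noise sd 2.
#'
#' @param n_subjects Number of subjects.
#' @param videos_per_subject Clips per subject.
#' @param n_classes Number of classes (>= 2).
#' @param shape Volume shape `(height, width, length)`, each >= 8.
#' @param motion_amplitude Peak amplitude of the drifting patch (intensity
#'   units); 0 gives static videos.
#' @param noise_sd Standard deviation of additive sensor noise.
#' @param seed Integer master seed; every video is a pure function of
#'   `(seed, subject, class, index)`.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_subjects = 16, videos_per_subject = 2, n_classes = 3,
                       shape = c(24, 24, 10), motion_amplitude = 16,
                       noise_sd = 2, seed = 1) {
  stopifnot(is_count(n_subjects), is_count(videos_per_subject),
            is_count(n_classes), n_classes >= 2,
            length(shape) == 3, all(shape >= 8),
            motion_amplitude >= 0, noise_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 videos_per_subject = as.integer(videos_per_subject),
                 n_classes = as.integer(n_classes),
                 shape = as.integer(shape),
                 motion_amplitude = motion_amplitude,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Band-limited subject base texture: white noise smoothed to gentle blobs,
# rescaled to mean 128, sd 25.
subject_texture <- function(h, w, seed) {
  with_seed(seed, {
    z <- matrix(rnorm(h * w), h, w)
    for (i in 1:3) z <- binomial_smooth(z)
    128 + 25 * (z - mean(z)) / sd(z)
  })
}

#' Generate one synthetic video
#'
#' See [synth_spec()] for the generative model.  The same
#' `(spec, subject, class, index)` always yields the identical volume.
#'
#' @param spec A [synth_spec()].
#' @param subject Subject index (1-based).
#' @param class Class index in `1..n_classes`.
#' @param index Clip index within the subject, disambiguating replicates.
#' @return Numeric 3-D array (height x width x length).
#' @export
make_video <- function(spec, subject, class, index = 1) {
  stopifnot(inherits(spec, "synth_spec"), is_count(subject),
            is_count(class), class <= spec$n_classes, is_count(index))
  h <- spec$shape[1]; w <- spec$shape[2]; l <- spec$shape[3]
  base <- subject_texture(h, w, derive_seed(spec$seed, 1, subject))
  # Shared spatial carrier: frequency 0.18 cyc/px at 30 degrees, Gaussian
  # envelope over the central region.  Class k drifts the carrier phase at
  # (2k - 1) / (4 * n_classes * 3) cycles per frame: at the reference
  # temporal radius of 3 frames the classes' phase offsets are evenly
  # spaced in (0, 1/2) cycle, so their temporal code statistics are
  # maximally distinct and no pair aliases to the same offset magnitude.
  ang <- pi / 6; freq <- 0.18
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), w), h, w)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  sigma <- min(h, w) / 3
  env <- exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2))
  phase_xy <- 2 * pi * freq * (x * cos(ang) + y * sin(ang))
  speed <- (2 * class - 1) / (4 * spec$n_classes) / 3
  video <- array(0, c(h, w, l))
  noise <- if (spec$noise_sd > 0)
    with_seed(derive_seed(spec$seed, 2, subject, class, index),
              array(rnorm(h * w * l, sd = spec$noise_sd), c(h, w, l)))
  else array(0, c(h, w, l))
  for (t in 0:(l - 1)) {
    drift <- spec$motion_amplitude * env * cos(phase_xy - 2 * pi * speed * t)
    video[, , t + 1] <- base + drift + noise[, , t + 1]
  }
  video
}

#' Generate a labeled synthetic corpus
#'
#' Creates `n_subjects * videos_per_subject` videos with classes assigned
#' round-robin over the sample sequence, so class counts differ by at most
#' one.  Optionally writes frame directories and a manifest in the standard
#' on-disk layout via [write_corpus()].
#'
#' @param spec A [synth_spec()].
#' @param out_dir Optional directory; when given, frames (ASCII PGM) and a
#'   `manifest.tsv` are written there.
#' @return List of class `video_corpus`: `videos` (named list of arrays),
#'   `meta` (data frame: sample_id, subject_id, label), `spec`.
#' @export
#' @examples
#' cor <- make_corpus(synth_spec(n_subjects = 3, videos_per_subject = 2))
#' nrow(cor$meta)  # 6
make_corpus <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_subjects * spec$videos_per_subject
  meta <- data.frame(sample_id = character(n), subject_id = character(n),
                     label = character(n), stringsAsFactors = FALSE)
  videos <- vector("list", n)
  k <- 0
  for (s in seq_len(spec$n_subjects)) {
    for (v in seq_len(spec$videos_per_subject)) {
      k <- k + 1
      cls <- (k - 1) %% spec$n_classes + 1
      meta$sample_id[k] <- sprintf("s%02d_v%02d", s, v)
      meta$subject_id[k] <- sprintf("s%02d", s)
      meta$label[k] <- sprintf("class%d", cls)
      videos[[k]] <- make_video(spec, s, cls, v)
    }
  }
  names(videos) <- meta$sample_id
  out <- structure(list(videos = videos, meta = meta, spec = spec),
                   class = "video_corpus")
  if (!is.null(out_dir)) write_corpus(out, out_dir)
  out
}

#' @export
print.video_corpus <- function(x, ...) {
  cat(sprintf("<video_corpus> %d videos (%s), %d subjects, %d classes\n",
              length(x$videos), paste(x$spec$shape, collapse = "x"),
              x$spec$n_subjects, x$spec$n_classes))
  invisible(x)
}
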