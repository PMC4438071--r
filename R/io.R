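# Frame I/O, manifests, and feature-table extraction.
#
# Intensities are floating point on a 0-255 scale regardless of source
# format.  Frames of a video live in one directory; byte-wise (C-locale)
# lexicographic filename order defines the temporal order, so frame writers
# zero-pad indices.

read_pgm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  tok <- character(0)
  # header: magic, width, height, maxval, with #-comments allowed
  while (length(tok) < 4) {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) stop(sprintf("truncated PGM header: %s", path), call. = FALSE)
    line <- sub("#.*$", "", line)
    tok <- c(tok, strsplit(trimws(line), "\\s+")[[1]])
    tok <- tok[nzchar(tok)]
  }
  magic <- tok[1]; w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxval <- as.integer(tok[4])
  npix <- w * h
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = npix, quiet = TRUE)
  } else if (magic == "P5") {
    if (maxval > 255) stop("16-bit P5 PGM not supported", call. = FALSE)
    vals <- as.integer(readBin(con, "raw", npix))
  } else stop(sprintf("not a PGM file: %s", path), call. = FALSE)
  if (length(vals) < npix) stop(sprintf("truncated PGM data: %s", path), call. = FALSE)
  matrix(as.numeric(vals), h, w, byrow = TRUE)
}

write_pgm <- function(img, path) {
  vals <- pmin(pmax(round(img), 0), 255)
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  writeLines(apply(matrix(as.integer(vals), nrow(img)), 1, paste, collapse = " "), con)
  invisible(path)
}

# Decode one frame file to a grayscale matrix on the 0-255 scale; RGB is
# converted by the ITU-R BT.601 luminance weights.
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = , tiff = tiff::readTIFF(path),
              stop(sprintf("unsupported frame format '%s': %s", ext, path),
                   call. = FALSE))
  if (length(dim(a)) == 3) {
    if (dim(a)[3] >= 3)
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    else a <- a[, , 1]
  }
  a * 255
}

#' Read a video volume from a directory of frames
#'
#' Stacks all decodable frames (PNG, PGM, TIFF) found in `path` along the
#' temporal axis, in byte-wise lexicographic filename order (so `f10.png`
#' sorts before `f2.png`; writers should zero-pad).  Color frames are
#' converted to luminance.
#'
#' @param path Directory containing the frames of one video.
#' @return Numeric 3-D array (height x width x length), intensities 0-255.
#' @export
read_video <- function(path) {
  if (!dir.exists(path)) stop(sprintf("no such directory: %s", path), call. = FALSE)
  files <- list.files(path, pattern = "\\.(png|pgm|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0)
    stop(sprintf("no decodable frames in %s", path), call. = FALSE)
  files <- files[order(basename(files), method = "radix")]
  frames <- lapply(files, read_frame)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop(sprintf("frames in %s have mixed sizes", path), call. = FALSE)
  array(unlist(frames), c(dims[1, 1], dims[2, 1], length(frames)))
}

#' Write a video volume as a directory of ASCII PGM frames
#'
#' Frames are written as `frame_0001.pgm`, `frame_0002.pgm`, ... with
#' intensities rounded and clamped to 0-255; a volume that is already
#' integer-valued in that range round-trips exactly through
#' [read_video()].
#'
#' @param video Numeric 3-D array.
#' @param path Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_video <- function(video, path) {
  check_video(video)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_len(dim(video)[3]))
    write_pgm(video[, , t], file.path(path, sprintf("frame_%04d.pgm", t)))
  invisible(path)
}

#' Write a video corpus to disk in the standard layout
#'
#' One frame directory per sample (named by sample id) plus a tab-delimited
#' `manifest.tsv` with columns `sample_id`, `path`, `subject_id`, `label`.
#'
#' @param corp A `video_corpus` from [make_corpus()].
#' @param dir Output directory.
#' @return Path to the manifest file, invisibly.
#' @export
write_corpus <- function(corp, dir) {
  stopifnot(inherits(corp, "video_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in corp$meta$sample_id)
    write_video(corp$videos[[id]], file.path(dir, id))
  manifest <- data.frame(sample_id = corp$meta$sample_id,
                         path = corp$meta$sample_id,
                         subject_id = corp$meta$subject_id,
                         label = corp$meta$label)
  mf <- file.path(dir, "manifest.tsv")
  write.table(manifest, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mf)
}

#' Read a sample manifest
#'
#' A manifest is a tab-delimited table with header columns `sample_id`,
#' `path` (frame directory, relative paths resolved against the manifest's
#' directory), `subject_id` and `label`.
#'
#' @param path Manifest file path.
#' @return Data frame with absolute frame-directory paths.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "path", "subject_id", "label")
  if (!all(need %in% names(m)))
    stop(sprintf("manifest must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(m$sample_id))
    stop("manifest sample ids must be unique", call. = FALSE)
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(normalizePath(path)), m$path[rel])
  m
}

descriptor_fun <- function(method, params) {
  method <- match.arg(method, c("top", "sip", "mop"))
  function(video) {
    switch(method,
           top = do.call(lbp_top, c(list(video), params)),
           sip = do.call(lbp_sip, c(list(video), params)),
           mop = do.call(lbp_mop, c(list(video), params)))
  }
}

apply_preprocess <- function(video, preprocess) {
  if (!is.null(preprocess$target_length))
    video <- temporal_resample(video, preprocess$target_length)
  if (isTRUE(preprocess$wiener) &&
      !identical(preprocess$wiener_on, "means")) {
    for (t in seq_len(dim(video)[3]))
      video[, , t] <- wiener_filter(video[, , t],
                                    window = preprocess$wiener_window %||% c(3, 3))
  }
  video
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract a feature table from a corpus or manifest
#'
#' Runs one descriptor over every sample and returns a data frame with one
#' row per sample and one column per histogram bin, columns named
#' `<segment label>.<bin>` (e.g. `XY.b1.1.003`), preceded by `sample_id`.
#' Optional preprocessing: temporal resampling to a fixed length, and
#' Wiener denoising applied either to every frame (`wiener_on = "frames"`)
#' or — for the mean-plane descriptor — to the three mean plane images
#' (`wiener_on = "means"`), both orders being legitimate readings of the
#' published protocols.
#'
#' @param x A `video_corpus` ([make_corpus()]) or a manifest data frame
#'   ([read_manifest()]).
#' @param method `"top"`, `"sip"` or `"mop"`.
#' @param params List of arguments passed to the descriptor (e.g.
#'   `list(R = c(1, 1, 3), grid = c(5, 5))`).
#' @param preprocess List with optional elements `target_length`, `wiener`
#'   (logical), `wiener_on` (`"frames"` or `"means"`), `wiener_window`.
#' @return Data frame of features; attribute `layout` keeps the segment
#'   table of the first sample.
#' @export
extract_features <- function(x, method = c("top", "sip", "mop"),
                             params = list(), preprocess = list()) {
  method <- match.arg(method)
  if (inherits(x, "video_corpus")) {
    ids <- x$meta$sample_id
    get_video <- function(i) x$videos[[ids[i]]]
    meta <- x$meta
  } else if (is.data.frame(x)) {
    ids <- x$sample_id
    get_video <- function(i) read_video(x$path[i])
    meta <- x
  } else stop("`x` must be a video_corpus or a manifest data frame", call. = FALSE)
  if (isTRUE(preprocess$wiener) && identical(preprocess$wiener_on, "means") &&
      method != "mop")
    stop("wiener_on = 'means' applies only to the mean-plane descriptor", call. = FALSE)
  fun <- descriptor_fun(method, params)
  rows <- vector("list", length(ids))
  layout <- NULL
  for (i in seq_along(ids)) {
    video <- apply_preprocess(get_video(i), preprocess)
    if (method == "mop" && isTRUE(preprocess$wiener) &&
        identical(preprocess$wiener_on, "means")) {
      mp <- mean_planes(video)
      mp <- lapply(unclass(mp), wiener_filter,
                   window = preprocess$wiener_window %||% c(3, 3))
      h <- do.call(mop_from_planes, c(list(mp), params))
    } else {
      h <- fun(video)
    }
    if (is.null(layout)) layout <- attr(h, "segments")
    rows[[i]] <- as.numeric(unclass(h))
  }
  lens <- vapply(rows, length, 1L)
  if (any(lens != lens[1]))
    stop("samples produced features of different lengths; check video shapes",
         call. = FALSE)
  feat <- do.call(rbind, rows)
  colnames(feat) <- feature_colnames(layout)
  out <- data.frame(sample_id = ids, feat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "layout") <- layout
  attr(out, "meta") <- meta
  out
}

feature_colnames <- function(layout) {
  unlist(mapply(function(lab, len) sprintf("%s.%03d", lab, seq_len(len)),
                layout$label, layout$length, SIMPLIFY = FALSE), use.names = FALSE)
}

# LBP-MOP from pre-computed (possibly filtered) mean planes.
mop_from_planes <- function(mp, P = 4, R = 1, grid_xy = c(1, 1),
                            grid_xt = c(1, 1), grid_yt = c(1, 1),
                            border = "exclude") {
  planes <- list(XY = list(mp$xy_mean, grid_xy),
                 XT = list(mp$xt_mean, grid_xt),
                 YT = list(mp$yt_mean, grid_yt))
  values <- numeric(0); seg_label <- character(0); seg_len <- integer(0)
  ncmp <- 0
  for (plane in names(planes)) {
    hst <- lbp_histogram(planes[[plane]][[1]], P = P, R = R,
                         grid = planes[[plane]][[2]], border = border)
    seg <- attr(hst, "segments")
    values <- c(values, as.numeric(unclass(hst)))
    seg_label <- c(seg_label, paste0(plane, ".", seg$label))
    seg_len <- c(seg_len, seg$length)
    ncmp <- ncmp + attr(hst, "n_comparisons")
  }
  out <- feature_histogram(values,
                           data.frame(label = seg_label,
                                      offset = cumsum(c(1L, seg_len[-length(seg_len)])),
                                      length = seg_len))
  attr(out, "n_comparisons") <- ncmp
  out
}

#' Corpus of features from a feature table
#'
#' Joins an [extract_features()] table with its metadata into a [corpus()]
#' ready for [cross_validated_accuracy()].
#'
#' @param features An [extract_features()] result (or equivalent data frame
#'   whose first column is `sample_id`).
#' @param meta Data frame with `sample_id`, `subject_id`, `label`; defaults
#'   to the metadata carried by the feature table.
#' @return A [corpus()].
#' @export
feature_corpus <- function(features, meta = attr(features, "meta")) {
  if (is.null(meta)) stop("metadata required", call. = FALSE)
  i <- match(features$sample_id, meta$sample_id)
  if (any(is.na(i))) stop("metadata missing for some samples", call. = FALSE)
  corpus(as.matrix(features[, -1, drop = FALSE]),
         features$sample_id, meta$subject_id[i], meta$label[i])
}

#' Multiscale (Gaussian pyramid) features of a video
#'
#' Builds a spatial Gaussian pyramid of every frame, reassembles one video
#' per level (each level resized to a common shape), extracts the chosen
#' descriptor per level, and also returns the concatenation over all
#' levels.
#'
#' @param video Numeric 3-D array.
#' @param method,params As in [extract_features()].
#' @param levels Number of pyramid levels.
#' @param resize_to `(height, width)` shared by all levels; defaults to the
#'   input frame size.
#' @return List with `per_level` (list of [feature_histogram()]s) and
#'   `all_levels` (their plain concatenation as a numeric vector).
#' @export
pyramid_features <- function(video, method = c("top", "sip", "mop"),
                             params = list(), levels = 4, resize_to = NULL) {
  check_video(video)
  method <- match.arg(method)
  if (is.null(resize_to)) resize_to <- dim(video)[1:2]
  fun <- descriptor_fun(method, params)
  l <- dim(video)[3]
  level_videos <- lapply(seq_len(levels), function(k) array(0, c(resize_to, l)))
  for (t in seq_len(l)) {
    p <- gaussian_pyramid(video[, , t], levels = levels, resize_to = resize_to)
    for (k in seq_len(levels)) level_videos[[k]][, , t] <- p[[k]]
  }
  per_level <- lapply(level_videos, fun)
  list(per_level = per_level,
       all_levels = unlist(lapply(per_level, as.numeric)))
}
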