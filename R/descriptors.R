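# Spatio-temporal descriptors on a video volume.
#
# A volume is indexed [y+1, x+1, t+1] (height x width x length).  Plane
# semantics: XY = frame at fixed t; XT = slice at fixed y (axes x, t);
# YT = slice at fixed x (axes y, t).  Block grids partition the spatial
# (y, x) frame extent; all frames of a block feed that block's segments.

# Interior index ranges (1-based) after removing margins, or all indices
# under replicate padding (handled by callers padding the volume).
check_temporal <- function(l, r_t) {
  need <- 2 * ceiling(r_t) + 1
  if (l < need)
    stop(sprintf("video length %d is shorter than 2*R_T + 1 = %d", l, need),
         call. = FALSE)
}

# Sample frames at a real-valued (1-based) temporal position by linear
# interpolation between adjacent frames; exact frame at integer positions.
tsample <- function(video, yy, xx, tf) {
  t0 <- floor(tf); f <- tf - t0
  if (f == 0) return(video[yy, xx, t0, drop = TRUE])
  (1 - f) * video[yy, xx, t0, drop = TRUE] + f * video[yy, xx, t0 + 1, drop = TRUE]
}

pad_volume <- function(video, my, mx, mt) {
  d <- dim(video)
  ri <- c(rep(1L, my), seq_len(d[1]), rep(d[1], my))
  ci <- c(rep(1L, mx), seq_len(d[2]), rep(d[2], mx))
  ti <- c(rep(1L, mt), seq_len(d[3]), rep(d[3], mt))
  video[ri, ci, ti, drop = FALSE]
}

top_segment_labels <- function(grid) {
  m <- prod(grid)
  br <- rep(seq_len(grid[1]), each = grid[2]); bc <- rep(seq_len(grid[2]), grid[1])
  list(block = sprintf("b%d.%d", br, bc), m = m)
}

#' LBP-TOP descriptor of a video volume
#'
#' Codes every voxel three times, once per orthogonal plane (XY, XT, YT),
#' with an independent LBP neighborhood in each plane, and accumulates the
#' three code streams into per-block histograms.  For each spatial block the
#' three `2^P`-bin segments are concatenated in XY, XT, YT order; blocks are
#' concatenated row-major.  With 4 neighbors per plane and a 1x1 grid the
#' result has `16 * 3 = 48` entries.
#'
#' Neighbors in a plane with per-axis radii `(Ra, Rb)` lie on the ellipse
#' `(Ra cos a, Rb sin a)` at angles `2*pi*p/P`; with `P = 4` they are the
#' four axis-aligned points, e.g. `(x +/- R_x, t)` and `(x, t +/- R_t)` on
#' the XT plane.
#'
#' @param video Numeric 3-D array (height x width x length).
#' @param P Neighbor counts per plane, length 1 or 3 `(XY, XT, YT)`.
#' @param R Radii per axis, length 3 `(R_x, R_y, R_t)`.
#' @param grid Spatial block grid `(rows, cols)` over the frame extent.
#' @param border `"exclude"` codes only voxels whose full spatio-temporal
#'   neighborhood is inside the volume; `"replicate"` pads with edge values
#'   so every voxel is coded.
#' @return A [feature_histogram()] of length `2^P * 3 * rows * cols` with
#'   per-block-per-plane segments labelled `<plane>.b<row>.<col>`, and an
#'   `n_comparisons` attribute counting neighbor-vs-centre comparisons.
#' @export
#' @examples
#' v <- array(runif(10 * 10 * 9), c(10, 10, 9))
#' length(lbp_top(v, R = c(1, 1, 3)))  # 48
lbp_top <- function(video, P = c(4, 4, 4), R = c(1, 1, 4), grid = c(1, 1),
                    border = c("exclude", "replicate")) {
  check_video(video)
  border <- match.arg(border)
  if (length(P) == 1) P <- rep(P, 3)
  stopifnot(length(P) == 3, all(vapply(P, is_count, TRUE)),
            length(R) == 3, all(R > 0), length(grid) == 2, all(grid >= 1))
  grid <- as.integer(grid)
  d <- dim(video); h <- d[1]; w <- d[2]; l <- d[3]
  rx <- R[1]; ry <- R[2]; rt <- R[3]
  check_temporal(l, rt)
  mx <- ceiling(rx); my <- ceiling(ry); mt <- ceiling(rt)
  if (border == "replicate") {
    video <- pad_volume(video, my, mx, mt)
  }
  dd <- dim(video)
  yy <- (my + 1):(dd[1] - my); xx <- (mx + 1):(dd[2] - mx); tt <- (mt + 1):(dd[3] - mt)
  # 0-based spatial coordinates of the coded voxels in the original frame:
  # under replicate padding the interior of the padded volume is exactly the
  # original extent.
  gy <- if (border == "replicate") seq_len(h) - 1L else yy - 1L
  gx <- if (border == "replicate") seq_len(w) - 1L else xx - 1L
  m <- prod(grid)
  blk_xy <- block_ids(gy, gx, h, w, grid)
  counts <- list(XY = matrix(0, 2^P[1], m), XT = matrix(0, 2^P[2], m),
                 YT = matrix(0, 2^P[3], m))
  ncmp <- 0
  # XY plane: per frame
  offs_xy <- neighbor_offsets(P[1], rx, ry)
  for (t in tt) {
    res <- code_image(video[, , t], offs_xy, "exclude")
    counts$XY <- counts$XY + tab_codes(res$codes, blk_xy, 2^P[1], m)
    ncmp <- ncmp + res$n_comparisons
  }
  # XT plane: slice at fixed y; matrix rows = x, cols = t
  offs_xt <- neighbor_offsets(P[2], rt, rx)  # cols (t) radius rt, rows (x) radius rx
  for (i in seq_along(yy)) {
    res <- code_image(video[yy[i], , ], offs_xt, "exclude")
    blk_row <- block_ids(gy[i], gx, h, w, grid)  # 1 x length(gx)
    blk <- matrix(blk_row[1, ], nrow(res$codes), ncol(res$codes))
    counts$XT <- counts$XT + tab_codes(res$codes, blk, 2^P[2], m)
    ncmp <- ncmp + res$n_comparisons
  }
  # YT plane: slice at fixed x; matrix rows = y, cols = t
  offs_yt <- neighbor_offsets(P[3], rt, ry)
  for (j in seq_along(xx)) {
    res <- code_image(video[, xx[j], ], offs_yt, "exclude")
    blk_col <- block_ids(gy, gx[j], h, w, grid)  # length(gy) x 1
    blk <- matrix(blk_col[, 1], nrow(res$codes), ncol(res$codes))
    counts$YT <- counts$YT + tab_codes(res$codes, blk, 2^P[3], m)
    ncmp <- ncmp + res$n_comparisons
  }
  assemble_planes_blockmajor(counts, grid, ncmp)
}

# Interleave per-plane count matrices block-major (block, then plane) into a
# normalized feature_histogram.
assemble_planes_blockmajor <- function(counts, grid, ncmp) {
  m <- prod(grid)
  lab <- top_segment_labels(grid)$block
  values <- numeric(0)
  seg_label <- character(0); seg_len <- integer(0)
  for (b in seq_len(m)) {
    for (plane in names(counts)) {
      col <- counts[[plane]][, b]
      s <- sum(col)
      if (s == 0)
        stop(sprintf("block %s received no codable voxels on the %s plane",
                     lab[b], plane), call. = FALSE)
      values <- c(values, col / s)
      seg_label <- c(seg_label, paste0(plane, ".", lab[b]))
      seg_len <- c(seg_len, length(col))
    }
  }
  out <- feature_histogram(values,
                           data.frame(label = seg_label,
                                      offset = cumsum(c(1L, seg_len[-length(seg_len)])),
                                      length = seg_len))
  attr(out, "n_comparisons") <- ncmp
  out
}

#' LBP-SIP descriptor of a video volume
#'
#' The six-intersection-points variant: for each voxel only the six unique
#' points where the three orthogonal planes' intersection lines pierce the
#' neighborhood are coded — the four axis-aligned XY-plane neighbors
#' `(x +/- R_x, y)` and `(x, y +/- R_y)`, plus the two temporal neighbors
#' `(x, y, t +/- R_t)`.  Codes are grouped "XY+2": a 4-bit spatial code
#' (bits east, north, west, south) and a 2-bit temporal code (bit 0 = past
#' frame `t - R_t`, bit 1 = future frame `t + R_t`), giving a
#' `2^4 + 2^2 = 20`-bin histogram per spatial block.
#'
#' @inheritParams lbp_top
#' @param R Radii per axis `(R_x, R_y, R_t)`.
#' @return A [feature_histogram()] of length `20 * rows * cols` with
#'   per-block segments `XY.b<r>.<c>` (16 bins) and `T.b<r>.<c>` (4 bins),
#'   plus an `n_comparisons` attribute.
#' @export
#' @examples
#' v <- array(runif(10 * 10 * 9), c(10, 10, 9))
#' length(lbp_sip(v, R = c(1, 1, 3)))  # 20
lbp_sip <- function(video, R = c(1, 1, 4), grid = c(1, 1),
                    border = c("exclude", "replicate")) {
  check_video(video)
  border <- match.arg(border)
  stopifnot(length(R) == 3, all(R > 0), length(grid) == 2, all(grid >= 1))
  grid <- as.integer(grid)
  d <- dim(video); h <- d[1]; w <- d[2]; l <- d[3]
  rx <- R[1]; ry <- R[2]; rt <- R[3]
  check_temporal(l, rt)
  mx <- ceiling(rx); my <- ceiling(ry); mt <- ceiling(rt)
  if (border == "replicate") video <- pad_volume(video, my, mx, mt)
  dd <- dim(video)
  tt <- (mt + 1):(dd[3] - mt)
  gy <- if (border == "replicate") seq_len(h) - 1L else (my + 1):(dd[1] - my) - 1L
  gx <- if (border == "replicate") seq_len(w) - 1L else (mx + 1):(dd[2] - mx) - 1L
  m <- prod(grid)
  blk <- block_ids(gy, gx, h, w, grid)
  counts_s <- matrix(0, 16, m); counts_t <- matrix(0, 4, m)
  ncmp <- 0
  offs_xy <- neighbor_offsets(4, rx, ry)
  yy <- (my + 1):(dd[1] - my); xx <- (mx + 1):(dd[2] - mx)
  for (t in tt) {
    frame <- video[, , t]
    res <- code_image(frame, offs_xy, "exclude")
    counts_s <- counts_s + tab_codes(res$codes, blk, 16L, m)
    centre <- frame[yy, xx, drop = FALSE]
    tcode <- (tsample(video, yy, xx, t - rt) >= centre) +
             2L * (tsample(video, yy, xx, t + rt) >= centre)
    counts_t <- counts_t + tab_codes(tcode, blk, 4L, m)
    ncmp <- ncmp + res$n_comparisons + 2 * length(centre)
  }
  values <- numeric(0); seg_label <- character(0); seg_len <- integer(0)
  lab <- top_segment_labels(grid)$block
  for (b in seq_len(m)) {
    for (part in list(c("XY", "s"), c("T", "t"))) {
      col <- if (part[2] == "s") counts_s[, b] else counts_t[, b]
      s <- sum(col)
      if (s == 0)
        stop(sprintf("block %s received no codable voxels", lab[b]), call. = FALSE)
      values <- c(values, col / s)
      seg_label <- c(seg_label, paste0(part[1], ".", lab[b]))
      seg_len <- c(seg_len, length(col))
    }
  }
  out <- feature_histogram(values,
                           data.frame(label = seg_label,
                                      offset = cumsum(c(1L, seg_len[-length(seg_len)])),
                                      length = seg_len))
  attr(out, "n_comparisons") <- ncmp
  out
}

#' Mean orthogonal plane images of a video volume
#'
#' Collapses each of the three plane stacks of a volume to its pixel-wise
#' arithmetic mean: `xy_mean` (height x width, averaged over t), `xt_mean`
#' (width x length, rows = x, cols = t, averaged over y) and `yt_mean`
#' (height x length, rows = y, cols = t, averaged over x).  Means are kept
#' in floating point; they are not re-quantized.
#'
#' @param video Numeric 3-D array (height x width x length).
#' @return List of class `mean_planes` with elements `xy_mean`, `xt_mean`,
#'   `yt_mean`.
#' @export
mean_planes <- function(video) {
  check_video(video)
  structure(list(xy_mean = apply(video, c(1, 2), mean),
                 xt_mean = apply(video, c(2, 3), mean),
                 yt_mean = apply(video, c(1, 3), mean)),
            class = "mean_planes")
}

#' LBP-MOP descriptor of a video volume
#'
#' The mean-orthogonal-planes variant: averages each plane stack of the
#' volume into a single image ([mean_planes()]) and computes a block-wise
#' 2-D LBP histogram ([lbp_histogram()]) on each of the three mean images
#' only.  Histogram dimensionality matches LBP-TOP (`2^P` bins per block per
#' plane) but the comparison cost drops from `3P * w * h * l` to
#' `P * (w*h + w*l + h*l)`.
#'
#' Grids are per plane; for XT and YT planes `grid = c(a, b)` means `a`
#' blocks along the spatial axis (rows) and `b` along the temporal axis
#' (columns).
#'
#' @inheritParams lbp_top
#' @param P Neighbor count for the 2-D LBP on every plane.
#' @param R Spatial radius for the 2-D LBP.
#' @param grid_xy,grid_xt,grid_yt Block grids for the three mean images.
#' @return A [feature_histogram()] with segments ordered XY blocks, then XT
#'   blocks, then YT blocks, labelled `<plane>.b<r>.<c>`; `n_comparisons`
#'   attribute as above.
#' @export
#' @examples
#' v <- array(runif(12 * 12 * 10), c(12, 12, 10))
#' length(lbp_mop(v))  # 48
lbp_mop <- function(video, P = 4, R = 1, grid_xy = c(1, 1), grid_xt = c(1, 1),
                    grid_yt = c(1, 1), border = c("exclude", "replicate")) {
  check_video(video)
  border <- match.arg(border)
  mp <- mean_planes(video)
  planes <- list(XY = list(mp$xy_mean, grid_xy),
                 XT = list(mp$xt_mean, grid_xt),
                 YT = list(mp$yt_mean, grid_yt))
  values <- numeric(0); seg_label <- character(0); seg_len <- integer(0)
  ncmp <- 0
  for (plane in names(planes)) {
    img <- planes[[plane]][[1]]; grid <- planes[[plane]][[2]]
    hst <- tryCatch(lbp_histogram(img, P = P, R = R, grid = grid, border = border),
                    error = function(e)
                      stop(sprintf("%s plane: %s", plane, conditionMessage(e)),
                           call. = FALSE))
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

#' Closed-form neighbor-comparison counts of the descriptors
#'
#' Number of neighbor-vs-centre comparisons each descriptor performs on an
#' idealized full `w x h x l` volume (no border exclusion), with 4 neighbors
#' per plane: `12*w*h*l` for LBP-TOP, `6*w*h*l` for LBP-SIP and
#' `4*(w*h + w*l + h*l)` for LBP-MOP.  The instrumented `n_comparisons`
#' attribute of each descriptor reproduces these exactly when run with
#' `border = "replicate"`.
#'
#' @param method One of `"top"`, `"sip"`, `"mop"`.
#' @param w,h,l Volume width, height and length (positive integers).
#' @return Integer comparison count.
#' @export
comparison_count <- function(method = c("top", "sip", "mop"), w, h, l) {
  method <- match.arg(method)
  stopifnot(is_count(w), is_count(h), is_count(l))
  switch(method,
         top = 12 * w * h * l,
         sip = 6 * w * h * l,
         mop = 4 * (w * h + w * l + h * l))
}
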