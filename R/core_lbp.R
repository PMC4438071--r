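#' Construct a feature histogram
#'
#' A feature histogram is a concatenation of per-segment histograms (one
#' segment per block and, for spatio-temporal descriptors, per plane), each
#' segment L1-normalized independently.  The segment layout is carried as a
#' data frame so downstream code can slice the vector without re-deriving
#' offsets.
#'
#' @param values Numeric vector of non-negative bin values.
#' @param segments Data frame with columns `label` (character), `offset`
#'   (1-based start index of the segment within `values`) and `length`.
#' @return An object of class `feature_histogram`: the numeric vector with a
#'   `segments` attribute.
#' @export
feature_histogram <- function(values, segments) {
  stopifnot(is.numeric(values), is.data.frame(segments),
            all(c("label", "offset", "length") %in% names(segments)))
  ends <- segments$offset + segments$length - 1L
  if (segments$offset[1] != 1L || any(segments$offset[-1] != ends[-nrow(segments)] + 1L) ||
      ends[nrow(segments)] != length(values))
    stop("segment layout has gaps or overlaps", call. = FALSE)
  structure(values, segments = segments, class = "feature_histogram")
}

#' @export
print.feature_histogram <- function(x, ...) {
  seg <- attr(x, "segments")
  cat(sprintf("<feature_histogram> %d values in %d segments\n",
              length(x), nrow(seg)))
  cat("  segments:", paste(utils::head(seg$label, 6), collapse = ", "),
      if (nrow(seg) > 6) "...", "\n")
  invisible(x)
}

#' Extract one segment of a feature histogram
#'
#' @param h A [feature_histogram()].
#' @param label Segment label to extract.
#' @return Numeric vector of that segment's values.
#' @export
fh_segment <- function(h, label) {
  seg <- attr(h, "segments")
  i <- match(label, seg$label)
  if (is.na(i)) stop(sprintf("no segment labelled '%s'", label), call. = FALSE)
  as.numeric(unclass(h)[seg$offset[i] + seq_len(seg$length[i]) - 1L])
}

#' Bilinearly sample an image at real-valued coordinates
#'
#' Coordinates are 0-based: `x` is the column and `y` the row index, so
#' `sample_intensity(img, 0, 0)` is the top-left pixel.  At integer
#' coordinates the exact pixel value is returned; elsewhere the four
#' surrounding pixels are blended bilinearly.
#'
#' @param img Numeric matrix of intensities.
#' @param x,y Vectors of 0-based sample coordinates (recycled to a common
#'   length).
#' @return Numeric vector of sampled intensities.
#' @export
#' @examples
#' m <- matrix(c(0, 20, 10, 30), 2, 2)  # column-major: rows y, cols x
#' sample_intensity(m, 0.5, 0.5)        # centre of a 2x2 patch -> mean
sample_intensity <- function(img, x, y) {
  check_image(img)
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  h <- nrow(img); w <- ncol(img)
  if (any(x < 0 | x > w - 1 | y < 0 | y > h - 1))
    stop("sample coordinates out of image bounds", call. = FALSE)
  x0 <- pmin(floor(x), w - 2 + (w == 1)); y0 <- pmin(floor(y), h - 2 + (h == 1))
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i01 <- img[cbind(y0 + 1, pmin(x0 + 2, w))]
  i10 <- img[cbind(pmin(y0 + 2, h), x0 + 1)]
  i11 <- img[cbind(pmin(y0 + 2, h), pmin(x0 + 2, w))]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Circular neighbor offsets for P neighbors at radii (r_x horizontal,
# r_y vertical).  Neighbor p (p = 0..P-1) sits at angle 2*pi*p/P
# counter-clockwise from the positive x-axis in display orientation, i.e.
# at (x + r_x cos a, y - r_y sin a) with y the downward row index: p = 0 is
# east, and for P = 4 the order is east, north, west, south.  Offsets within
# 1e-9 of an integer are snapped so the paper's P=4, R=1 configuration needs
# no interpolation.
neighbor_offsets <- function(P, r_x, r_y = r_x) {
  a <- 2 * pi * (0:(P - 1)) / P
  snap <- function(v) { r <- round(v); ifelse(abs(v - r) < 1e-9, r, v) }
  cbind(dx = snap(r_x * cos(a)), dy = snap(-r_y * sin(a)))
}

# Vectorized LBP coding of every interior pixel of a matrix.
# offs: P x 2 matrix of (dx, dy) neighbor offsets (dy in row units).
# Returns codes over the interior, the 0-based (y, x) origin of the interior
# within the original image, and the number of neighbor-vs-center
# comparisons performed.
code_image <- function(img, offs, border = c("exclude", "replicate")) {
  border <- match.arg(border)
  P <- nrow(offs)
  mx <- ceiling(max(abs(offs[, "dx"]))); my <- ceiling(max(abs(offs[, "dy"])))
  y0 <- my; x0 <- mx
  if (border == "replicate") {
    img <- pad_replicate(img, my, my, mx, mx)
    y0 <- 0L; x0 <- 0L
  }
  h <- nrow(img); w <- ncol(img)
  if (h < 2 * my + 1 || w < 2 * mx + 1)
    stop("image too small for the requested neighborhood radius", call. = FALSE)
  rows <- (my + 1):(h - my); cols <- (mx + 1):(w - mx)
  centre <- img[rows, cols, drop = FALSE]
  codes <- matrix(0L, nrow(centre), ncol(centre))
  for (p in seq_len(P)) {
    dx <- offs[p, "dx"]; dy <- offs[p, "dy"]
    if (dx == floor(dx) && dy == floor(dy)) {
      nb <- img[rows + dy, cols + dx, drop = FALSE]
    } else {
      xf <- floor(dx); yf <- floor(dy); fx <- dx - xf; fy <- dy - yf
      nb <- (1 - fy) * ((1 - fx) * img[rows + yf,     cols + xf,     drop = FALSE] +
                             fx  * img[rows + yf,     cols + xf + 1, drop = FALSE]) +
                 fy  * ((1 - fx) * img[rows + yf + 1, cols + xf,     drop = FALSE] +
                             fx  * img[rows + yf + 1, cols + xf + 1, drop = FALSE])
    }
    codes <- codes + (nb >= centre) * (2L^(p - 1L))
  }
  list(codes = codes, y0 = y0, x0 = x0, n_comparisons = P * length(centre))
}

#' LBP code of a single pixel
#'
#' Thresholds the `P` circular neighbors at radius `R` against the centre
#' pixel: bit `p` (weight `2^p`) is 1 when neighbor `p` is greater than or
#' equal to the centre.  Neighbor `p` lies at angle `2*pi*p/P`
#' counter-clockwise from the positive x-axis (east first; see
#' [lbp_histogram()] for the full convention).
#'
#' @param img Numeric matrix.
#' @param x,y 0-based centre pixel position (column, row).
#' @param P Number of neighbors.
#' @param R Neighborhood radius in pixels.
#' @return Integer code in `[0, 2^P - 1]`.
#' @export
#' @examples
#' lbp_code(matrix(5, 3, 3), 1, 1, P = 8, R = 1)  # constant image -> 255
lbp_code <- function(img, x, y, P = 8, R = 1) {
  check_image(img)
  stopifnot(is_count(P), R > 0)
  offs <- neighbor_offsets(P, R)
  h <- nrow(img); w <- ncol(img)
  nx <- x + offs[, "dx"]; ny <- y + offs[, "dy"]
  if (any(nx < 0 | nx > w - 1 | ny < 0 | ny > h - 1))
    stop("neighborhood exceeds image bounds; restrict centres to the interior",
         call. = FALSE)
  centre <- img[y + 1, x + 1]
  nb <- sample_intensity(img, nx, ny)
  as.integer(sum((nb >= centre) * 2^(seq_len(P) - 1)))
}

# Tabulate codes into per-block histograms.  blk is a matrix of 1-based
# row-major block ids congruent with codes; returns an nbins x m count matrix.
tab_codes <- function(codes, blk, nbins, m) {
  matrix(tabulate((blk - 1L) * nbins + codes + 1L, nbins * m), nrow = nbins)
}

# Row-major block-id matrix for a code matrix whose element (i, j) sits at
# global 0-based spatial position (ycoords[i], xcoords[j]).
block_ids <- function(ycoords, xcoords, h, w, grid) {
  br <- block_index(ycoords, block_bounds(h, grid[1]))
  bc <- block_index(xcoords, block_bounds(w, grid[2]))
  outer(br - 1L, bc, function(a, b) a * grid[2] + b)
}

# Normalize count columns to unit L1 mass; zero columns raise in callers.
l1_normalize <- function(counts) sweep(counts, 2, colSums(counts), "/")

#' Block-wise LBP histogram of an image
#'
#' Codes every pixel whose full circular neighborhood lies inside the image
#' (`border = "exclude"`, the default) or every pixel after edge-replication
#' padding (`border = "replicate"`), then accumulates codes into one
#' `2^P`-bin histogram per block of a `rows x cols` grid laid over the full
#' image extent.  Block boundaries sit at `floor(i * extent / k)`, so
#' trailing blocks absorb indivisible remainders.  Segments are ordered
#' block-row-major and labelled `b<row>.<col>`.
#'
#' @param img Numeric matrix of intensities.
#' @param P Number of circular neighbors (histogram has `2^P` bins per block).
#' @param R Neighborhood radius in pixels.
#' @param grid Length-2 integer vector `(rows, cols)` of the block grid.
#' @param normalize If `TRUE` (default) each block's histogram is scaled to
#'   sum to 1.
#' @param border `"exclude"` drops border pixels lacking a full
#'   neighborhood; `"replicate"` pads with edge values so every pixel is
#'   coded.
#' @return A [feature_histogram()] of length `2^P * rows * cols`, with
#'   attribute `n_comparisons` giving the number of neighbor-vs-centre
#'   comparisons performed.
#' @export
#' @examples
#' img <- matrix(runif(100), 10, 10)
#' h <- lbp_histogram(img, P = 4, R = 1, grid = c(2, 2))
#' sum(fh_segment(h, "b1.1"))  # each block segment sums to 1
lbp_histogram <- function(img, P = 8, R = 1, grid = c(1, 1), normalize = TRUE,
                          border = c("exclude", "replicate")) {
  check_image(img)
  border <- match.arg(border)
  stopifnot(is_count(P), R > 0, length(grid) == 2, all(grid >= 1))
  grid <- as.integer(grid)
  h <- nrow(img); w <- ncol(img)
  res <- code_image(img, neighbor_offsets(P, R), border)
  blk <- block_ids(res$y0 + seq_len(nrow(res$codes)) - 1L,
                   res$x0 + seq_len(ncol(res$codes)) - 1L, h, w, grid)
  nbins <- 2L^P
  m <- prod(grid)
  counts <- tab_codes(res$codes, blk, nbins, m)
  empty <- which(colSums(counts) == 0)
  if (length(empty)) {
    r <- (empty[1] - 1L) %/% grid[2] + 1L; c <- (empty[1] - 1L) %% grid[2] + 1L
    stop(sprintf("block (%d,%d) contains no codable pixels; coarsen the grid or use border = 'replicate'",
                 r, c), call. = FALSE)
  }
  if (normalize) counts <- l1_normalize(counts)
  lab <- sprintf("b%d.%d", rep(seq_len(grid[1]), each = grid[2]),
                 rep(seq_len(grid[2]), grid[1]))
  out <- feature_histogram(as.numeric(counts),
                           data.frame(label = lab,
                                      offset = seq(1L, by = nbins, length.out = m),
                                      length = nbins))
  attr(out, "n_comparisons") <- res$n_comparisons
  out
}
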