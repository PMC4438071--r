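# Independent brute-force reference implementations used as oracles.
# These deliberately share nothing with the package internals beyond the
# documented conventions: 0-based (x = col, y = row) coordinates, neighbor p
# at angle 2*pi*p/P counter-clockwise from east (bit p weighted 2^p), block
# boundaries at floor(i * extent / k).

oracle_bilinear <- function(img, x, y) {
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  g <- function(yy, xx) img[min(yy, nrow(img) - 1) + 1, min(xx, ncol(img) - 1) + 1]
  (1 - fy) * ((1 - fx) * g(y0, x0) + fx * g(y0, x0 + 1)) +
       fy  * ((1 - fx) * g(y0 + 1, x0) + fx * g(y0 + 1, x0 + 1))
}

oracle_lbp_code <- function(img, x, y, P, R) {
  code <- 0
  centre <- img[y + 1, x + 1]
  for (p in 0:(P - 1)) {
    a <- 2 * pi * p / P
    nx <- x + R * cos(a); ny <- y - R * sin(a)
    nx <- ifelse(abs(nx - round(nx)) < 1e-9, round(nx), nx)
    ny <- ifelse(abs(ny - round(ny)) < 1e-9, round(ny), ny)
    if (oracle_bilinear(img, nx, ny) >= centre) code <- code + 2^p
  }
  code
}

oracle_block_of <- function(v, extent, k) {
  for (i in k:1) if (floor((i - 1) * extent / k) <= v) return(i)
  stop("unreachable")
}

# Unnormalized per-block code counts: nbins x (rows*cols), blocks row-major.
oracle_lbp_counts <- function(img, P, R, grid) {
  h <- nrow(img); w <- ncol(img); m <- ceiling(R)
  counts <- matrix(0, 2^P, prod(grid))
  for (y in m:(h - 1 - m)) for (x in m:(w - 1 - m)) {
    b <- (oracle_block_of(y, h, grid[1]) - 1) * grid[2] + oracle_block_of(x, w, grid[2])
    code <- oracle_lbp_code(img, x, y, P, R)
    counts[code + 1, b] <- counts[code + 1, b] + 1
  }
  counts
}

# Naive LBP-TOP with P = 4 per plane: explicit neighbor lists per the
# documented plane orientations (bit order on each plane starts at the
# positive first-axis direction and proceeds counter-clockwise).
oracle_top_counts <- function(video, R, grid) {
  d <- dim(video); h <- d[1]; w <- d[2]; l <- d[3]
  rx <- R[1]; ry <- R[2]; rt <- R[3]
  cnt <- list(XY = matrix(0, 16, prod(grid)), XT = matrix(0, 16, prod(grid)),
              YT = matrix(0, 16, prod(grid)))
  g <- function(y, x, t) video[y + 1, x + 1, t + 1]
  for (t in rt:(l - 1 - rt)) for (y in ry:(h - 1 - ry)) for (x in rx:(w - 1 - rx)) {
    b <- (oracle_block_of(y, h, grid[1]) - 1) * grid[2] + oracle_block_of(x, w, grid[2])
    c0 <- g(y, x, t)
    nb <- list(
      XY = list(g(y, x + rx, t), g(y - ry, x, t), g(y, x - rx, t), g(y + ry, x, t)),
      XT = list(g(y, x, t + rt), g(y, x - rx, t), g(y, x, t - rt), g(y, x + rx, t)),
      YT = list(g(y, x, t + rt), g(y - ry, x, t), g(y, x, t - rt), g(y + ry, x, t)))
    for (plane in names(nb)) {
      code <- sum((unlist(nb[[plane]]) >= c0) * 2^(0:3))
      cnt[[plane]][code + 1, b] <- cnt[[plane]][code + 1, b] + 1
    }
  }
  cnt
}

oracle_sip_counts <- function(video, R, grid) {
  d <- dim(video); h <- d[1]; w <- d[2]; l <- d[3]
  rx <- R[1]; ry <- R[2]; rt <- R[3]
  cs <- matrix(0, 16, prod(grid)); ct <- matrix(0, 4, prod(grid))
  g <- function(y, x, t) video[y + 1, x + 1, t + 1]
  for (t in rt:(l - 1 - rt)) for (y in ry:(h - 1 - ry)) for (x in rx:(w - 1 - rx)) {
    b <- (oracle_block_of(y, h, grid[1]) - 1) * grid[2] + oracle_block_of(x, w, grid[2])
    c0 <- g(y, x, t)
    sp <- sum((c(g(y, x + rx, t), g(y - ry, x, t), g(y, x - rx, t), g(y + ry, x, t)) >= c0) * 2^(0:3))
    tp <- (g(y, x, t - rt) >= c0) + 2 * (g(y, x, t + rt) >= c0)
    cs[sp + 1, b] <- cs[sp + 1, b] + 1
    ct[tp + 1, b] <- ct[tp + 1, b] + 1
  }
  list(spatial = cs, temporal = ct)
}

oracle_mean_planes <- function(video) {
  d <- dim(video)
  xy <- matrix(0, d[1], d[2]); xt <- matrix(0, d[2], d[3]); yt <- matrix(0, d[1], d[3])
  for (y in 1:d[1]) for (x in 1:d[2]) xy[y, x] <- mean(video[y, x, ])
  for (x in 1:d[2]) for (t in 1:d[3]) xt[x, t] <- mean(video[, x, t])
  for (y in 1:d[1]) for (t in 1:d[3]) yt[y, t] <- mean(video[y, , t])
  list(xy = xy, xt = xt, yt = yt)
}

rand_image <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w, 0, 255), h, w)
}

rand_video <- function(h, w, l, seed) {
  set.seed(seed)
  array(runif(h * w * l, 0, 255), c(h, w, l))
}
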