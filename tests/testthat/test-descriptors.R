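test_that("descriptor dimensionality follows 48m, 20m and 16(m_xy+m_xt+m_yt)", {
  v <- rand_video(10, 10, 9, seed = 1)
  expect_length(lbp_top(v, R = c(1, 1, 3)), 48)
  expect_length(lbp_sip(v, R = c(1, 1, 3)), 20)
  expect_length(lbp_mop(v), 48)
  v2 <- rand_video(20, 20, 9, seed = 2)
  expect_length(lbp_top(v2, R = c(1, 1, 3), grid = c(5, 5)), 1200)
  expect_length(lbp_sip(v2, R = c(1, 1, 3), grid = c(5, 5)), 500)
  # coarse per-plane grids: 3x3, 3x2, 3x2 -> 16 * (9 + 6 + 6) = 336
  v3 <- rand_video(24, 24, 10, seed = 3)
  expect_length(lbp_mop(v3, grid_xy = c(3, 3), grid_xt = c(3, 2), grid_yt = c(3, 2)),
                336)
})

test_that("constant videos put all mass in the all-ones code on every plane", {
  v <- array(42, c(9, 9, 9))
  h <- lbp_top(v, R = c(1, 1, 3))
  for (lab in c("XY.b1.1", "XT.b1.1", "YT.b1.1"))
    expect_equal(fh_segment(h, lab), c(rep(0, 15), 1))
  s <- lbp_sip(v, R = c(1, 1, 3))
  expect_equal(fh_segment(s, "XY.b1.1"), c(rep(0, 15), 1))
  expect_equal(fh_segment(s, "T.b1.1"), c(0, 0, 0, 1))
  m <- lbp_mop(v)
  for (lab in c("XY.b1.1", "XT.b1.1", "YT.b1.1"))
    expect_equal(fh_segment(m, lab), c(rep(0, 15), 1))
})

test_that("LBP-TOP matches the naive triple-loop reference", {
  for (cfg in list(list(d = c(12, 12, 9), R = c(1, 1, 3), grid = c(1, 1)),
                   list(d = c(12, 10, 9), R = c(1, 1, 3), grid = c(2, 2)),
                   list(d = c(11, 12, 9), R = c(1, 1, 2), grid = c(2, 1)))) {
    v <- rand_video(cfg$d[1], cfg$d[2], cfg$d[3], seed = sum(cfg$d))
    got <- lbp_top(v, R = cfg$R, grid = cfg$grid)
    ref <- oracle_top_counts(v, cfg$R, cfg$grid)
    m <- prod(cfg$grid)
    for (b in seq_len(m)) {
      br <- (b - 1) %/% cfg$grid[2] + 1; bc <- (b - 1) %% cfg$grid[2] + 1
      for (plane in c("XY", "XT", "YT")) {
        ref_seg <- ref[[plane]][, b] / sum(ref[[plane]][, b])
        expect_equal(fh_segment(got, sprintf("%s.b%d.%d", plane, br, bc)), ref_seg,
                     info = sprintf("%s block %d dims %s", plane, b,
                                    paste(cfg$d, collapse = "x")))
      }
    }
  }
})

test_that("LBP-SIP matches the naive triple-loop reference", {
  for (cfg in list(list(d = c(12, 12, 9), R = c(1, 1, 3), grid = c(1, 1)),
                   list(d = c(10, 12, 9), R = c(1, 1, 4), grid = c(2, 2)))) {
    v <- rand_video(cfg$d[1], cfg$d[2], cfg$d[3], seed = 100 + sum(cfg$d))
    got <- lbp_sip(v, R = cfg$R, grid = cfg$grid)
    ref <- oracle_sip_counts(v, cfg$R, cfg$grid)
    for (b in seq_len(prod(cfg$grid))) {
      br <- (b - 1) %/% cfg$grid[2] + 1; bc <- (b - 1) %% cfg$grid[2] + 1
      expect_equal(fh_segment(got, sprintf("XY.b%d.%d", br, bc)),
                   ref$spatial[, b] / sum(ref$spatial[, b]))
      expect_equal(fh_segment(got, sprintf("T.b%d.%d", br, bc)),
                   ref$temporal[, b] / sum(ref$temporal[, b]))
    }
  }
})

test_that("SIP's spatial segment equals the per-frame 4-neighbor LBP histogram", {
  v <- rand_video(10, 10, 9, seed = 7)
  rt <- 3
  s <- lbp_sip(v, R = c(1, 1, rt))
  acc <- rep(0, 16)
  for (t in (rt + 1):(dim(v)[3] - rt))
    acc <- acc + as.numeric(lbp_histogram(v[, , t], P = 4, R = 1, normalize = FALSE))
  expect_equal(fh_segment(s, "XY.b1.1"), acc / sum(acc))
})

test_that("the six SIP points are the union of TOP's per-plane neighbor sets", {
  r <- 2
  neighbors <- list(
    XY = list(c(r, 0, 0), c(0, -r, 0), c(-r, 0, 0), c(0, r, 0)),
    XT = list(c(0, 0, r), c(-r, 0, 0), c(0, 0, -r), c(r, 0, 0)),
    YT = list(c(0, 0, r), c(0, -r, 0), c(0, 0, -r), c(0, r, 0)))
  all_pts <- unique(do.call(rbind, lapply(neighbors, function(p) do.call(rbind, p))))
  expect_equal(nrow(all_pts), 6)
  sip_pts <- rbind(c(r, 0, 0), c(-r, 0, 0), c(0, r, 0), c(0, -r, 0),
                   c(0, 0, r), c(0, 0, -r))
  expect_setequal(apply(all_pts, 1, paste, collapse = ","),
                  apply(sip_pts, 1, paste, collapse = ","))
})

test_that("reversing frame order swaps SIP's temporal bits and fixes the spatial segment", {
  v <- rand_video(10, 10, 9, seed = 11)
  rev_v <- v[, , dim(v)[3]:1]
  a <- lbp_sip(v, R = c(1, 1, 3))
  b <- lbp_sip(rev_v, R = c(1, 1, 3))
  expect_equal(fh_segment(b, "XY.b1.1"), fh_segment(a, "XY.b1.1"))
  expect_equal(fh_segment(b, "T.b1.1"), fh_segment(a, "T.b1.1")[c(1, 3, 2, 4)])
})

test_that("mean planes are exact axis averages with the documented orientations", {
  v <- rand_video(7, 8, 5, seed = 13)
  mp <- mean_planes(v)
  ref <- oracle_mean_planes(v)
  expect_equal(mp$xy_mean, ref$xy, tolerance = 1e-9)
  expect_equal(mp$xt_mean, ref$xt, tolerance = 1e-9)
  expect_equal(mp$yt_mean, ref$yt, tolerance = 1e-9)
  expect_equal(dim(mp$xy_mean), c(7L, 8L))
  expect_equal(dim(mp$xt_mean), c(8L, 5L))
  expect_equal(dim(mp$yt_mean), c(7L, 5L))
  # ramp video: frame t is constant t
  l <- 6
  ramp <- array(rep(0:(l - 1), each = 20), c(4, 5, l))
  mpr <- mean_planes(ramp)
  expect_equal(mpr$xy_mean, matrix((l - 1) / 2, 4, 5))
  expect_equal(mpr$xt_mean, matrix(rep(0:(l - 1), each = 5), 5, l))
  # static video: mean frame is the frame
  st <- array(rep(rand_image(6, 6, 14), 4), c(6, 6, 4))
  expect_equal(mean_planes(st)$xy_mean, st[, , 1])
})

test_that("LBP-MOP equals 2-D LBP histograms of the mean planes", {
  v <- rand_video(12, 12, 9, seed = 17)
  got <- lbp_mop(v, grid_xy = c(2, 2), grid_xt = c(2, 1), grid_yt = c(1, 2))
  ref <- oracle_mean_planes(v)
  pieces <- c(as.numeric(lbp_histogram(ref$xy, P = 4, R = 1, grid = c(2, 2))),
              as.numeric(lbp_histogram(ref$xt, P = 4, R = 1, grid = c(2, 1))),
              as.numeric(lbp_histogram(ref$yt, P = 4, R = 1, grid = c(1, 2))))
  expect_equal(as.numeric(got), pieces)
  # a static video's XY segment is the single-frame histogram
  st <- array(rep(rand_image(10, 10, 18), 5), c(10, 10, 5))
  expect_equal(fh_segment(lbp_mop(st), "XY.b1.1"),
               as.numeric(lbp_histogram(st[, , 1], P = 4, R = 1)))
})

test_that("MOP's XY segment is invariant to frame permutations", {
  v <- rand_video(10, 10, 8, seed = 19)
  set.seed(20); perm <- sample(8)
  expect_equal(fh_segment(lbp_mop(v[, , perm]), "XY.b1.1"),
               fh_segment(lbp_mop(v), "XY.b1.1"))
})

test_that("descriptors are invariant to a constant intensity shift", {
  v <- rand_video(10, 10, 9, seed = 21)
  expect_equal(as.numeric(lbp_top(v + 50, R = c(1, 1, 3))),
               as.numeric(lbp_top(v, R = c(1, 1, 3))))
  expect_equal(as.numeric(lbp_sip(v + 50, R = c(1, 1, 3))),
               as.numeric(lbp_sip(v, R = c(1, 1, 3))))
  expect_equal(as.numeric(lbp_mop(v + 50)), as.numeric(lbp_mop(v)))
})

test_that("closed-form and instrumented comparison counts agree", {
  expect_equal(comparison_count("top", 7, 5, 11), 12 * 7 * 5 * 11)
  expect_equal(comparison_count("sip", 7, 5, 11), 6 * 7 * 5 * 11)
  expect_equal(comparison_count("mop", 10, 10, 10), 1200)
  expect_error(comparison_count("vlbp", 1, 1, 1))
  v <- rand_video(9, 11, 10, seed = 23)
  w <- 11; h <- 9; l <- 10
  expect_equal(attr(lbp_top(v, R = c(1, 1, 3), border = "replicate"), "n_comparisons"),
               comparison_count("top", w, h, l))
  expect_equal(attr(lbp_sip(v, R = c(1, 1, 3), border = "replicate"), "n_comparisons"),
               comparison_count("sip", w, h, l))
  expect_equal(attr(lbp_mop(v, border = "replicate"), "n_comparisons"),
               comparison_count("mop", w, h, l))
})

test_that("too-short videos raise a temporal-extent error", {
  v <- rand_video(8, 8, 6, seed = 29)
  expect_error(lbp_top(v, R = c(1, 1, 3)), "shorter than")
  expect_error(lbp_sip(v, R = c(1, 1, 4)), "shorter than")
})
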