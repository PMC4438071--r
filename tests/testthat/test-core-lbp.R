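test_that("bilinear sampling is exact at grid points and interpolates between them", {
  img <- matrix(runif(30, 0, 255), 5, 6)
  expect_equal(sample_intensity(img, 2, 3), img[4, 3])
  patch <- matrix(c(0, 20, 10, 30), 2, 2)  # [y+1, x+1]: (0,0)=0 (1,0)=20 (0,1)=10 (1,1)=30
  expect_equal(sample_intensity(patch, 0.5, 0.5), mean(patch))
  row2 <- matrix(c(0, 100), 1, 2)
  expect_equal(sample_intensity(row2, 0.25, 0), 25)
  expect_error(sample_intensity(img, -0.1, 0), "out of image bounds")
  expect_error(sample_intensity(img, 0, 5.1), "out of image bounds")
})

test_that("single-pixel codes follow the sign convention and neighbor order", {
  expect_equal(lbp_code(matrix(7, 5, 5), 2, 2, P = 8, R = 1), 255)
  expect_equal(lbp_code(matrix(7, 5, 5), 2, 2, P = 4, R = 1), 15)
  img <- matrix(0, 3, 3); img[2, 2] <- 10
  expect_equal(lbp_code(img, 1, 1, P = 8, R = 1), 0)
  # east, north, west, south = 20, 0, 20, 0 against centre 10 -> bits 1,0,1,0
  img <- matrix(0, 3, 3)
  img[2, 2] <- 10; img[2, 3] <- 20; img[1, 2] <- 0; img[2, 1] <- 20; img[3, 2] <- 0
  expect_equal(lbp_code(img, 1, 1, P = 4, R = 1), 5)
  expect_error(lbp_code(img, 0, 0, P = 4, R = 1), "neighborhood exceeds")
})

test_that("codes agree with a naive per-pixel oracle, including interpolated radii", {
  for (cfg in list(list(P = 4, R = 1), list(P = 8, R = 1), list(P = 8, R = 2.5))) {
    img <- rand_image(16, 16, seed = cfg$P * 10 + cfg$R)
    m <- ceiling(cfg$R)
    for (y in c(m, 7, 15 - m)) for (x in c(m, 4, 15 - m)) {
      expect_equal(lbp_code(img, x, y, cfg$P, cfg$R),
                   oracle_lbp_code(img, x, y, cfg$P, cfg$R),
                   info = sprintf("P=%d R=%g (%d,%d)", cfg$P, cfg$R, x, y))
    }
  }
})

test_that("block histograms match a nested-loop re-count of per-pixel codes", {
  img <- rand_image(12, 12, seed = 31)
  h <- lbp_histogram(img, P = 4, R = 1, grid = c(2, 2), normalize = FALSE)
  expect_equal(matrix(as.numeric(h), nrow = 16),
               oracle_lbp_counts(img, 4, 1, c(2, 2)))
  # non-divisible extents: 13x11 with a 3x2 grid
  img2 <- rand_image(13, 11, seed = 32)
  h2 <- lbp_histogram(img2, P = 4, R = 1, grid = c(3, 2), normalize = FALSE)
  expect_equal(matrix(as.numeric(h2), nrow = 16),
               oracle_lbp_counts(img2, 4, 1, c(3, 2)))
})

test_that("histogram layout has the advertised bin count and segment structure", {
  img <- rand_image(10, 10, seed = 5)
  expect_length(lbp_histogram(img, P = 8, R = 1), 256)
  hc <- lbp_histogram(matrix(10, 10, 10), P = 4, R = 1)
  expect_equal(as.numeric(hc), c(rep(0, 15), 1))  # constant image -> code 15
  seg <- attr(lbp_histogram(img, P = 4, R = 1, grid = c(2, 3)), "segments")
  expect_equal(seg$label[1:3], c("b1.1", "b1.2", "b1.3"))
  expect_equal(seg$offset, seq(1, by = 16, length.out = 6))
})

test_that("codes are invariant under increasing intensity transforms", {
  # exact for configurations whose neighbors fall on grid points (any
  # monotone map), and for interpolated neighbors under affine maps --
  # interpolation commutes only with affine transforms
  for (s in 1:3) {
    img <- rand_image(14, 14, seed = 40 + s)
    expect_equal(as.numeric(lbp_histogram(3 * img^1.3 + 7, P = 4, R = 1,
                                          grid = c(2, 2))),
                 as.numeric(lbp_histogram(img, P = 4, R = 1, grid = c(2, 2))))
    expect_equal(as.numeric(lbp_histogram(2 * img + 31, P = 8, R = 1,
                                          grid = c(2, 2))),
                 as.numeric(lbp_histogram(img, P = 8, R = 1, grid = c(2, 2))))
  }
})

test_that("unnormalized counts conserve the number of interior pixels per block", {
  img <- rand_image(11, 13, seed = 50)
  h <- lbp_histogram(img, P = 4, R = 1, grid = c(2, 2), normalize = FALSE)
  counts <- matrix(as.numeric(h), nrow = 16)
  per_block <- integer(4)
  for (y in 1:9) for (x in 1:11)  # 0-based interior
    per_block[(oracle_block_of(y, 11, 2) - 1) * 2 + oracle_block_of(x, 13, 2)] <-
      per_block[(oracle_block_of(y, 11, 2) - 1) * 2 + oracle_block_of(x, 13, 2)] + 1L
  expect_equal(colSums(counts), per_block)
  # replicate border codes every pixel
  hr <- lbp_histogram(img, P = 4, R = 1, normalize = FALSE, border = "replicate")
  expect_equal(sum(hr), 11 * 13)
})

test_that("normalized segments sum to one and degenerate blocks raise", {
  img <- rand_image(16, 16, seed = 60)
  h <- lbp_histogram(img, P = 4, R = 1, grid = c(3, 3))
  seg <- attr(h, "segments")
  for (lab in seg$label)
    expect_equal(sum(fh_segment(h, lab)), 1, tolerance = 1e-9)
  # 4 blocks across a 4-pixel axis leaves the outermost blocks without
  # interior pixels
  expect_error(lbp_histogram(rand_image(4, 10, seed = 61), P = 4, R = 1,
                             grid = c(4, 1)),
               "block \\(1,1\\)")
})
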