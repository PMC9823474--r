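test_that("area-average resize preserves means and constants", {
  m <- matrix(runif(130 * 130, 0, 255), 130, 130)
  out <- resize_area(m, 32, 32)
  expect_equal(dim(out), c(32, 32))
  expect_equal(mean(out), mean(m), tolerance = 1e-10)
  expect_equal(resize_area(matrix(7, 50, 50), 13, 9),
               matrix(7, 13, 9), tolerance = 1e-10)
  # integer-factor downsampling equals block means
  b <- matrix(1:16, 4, 4)
  expect_equal(resize_area(b, 2, 2),
               matrix(c(mean(b[1:2, 1:2]), mean(b[3:4, 1:2]),
                        mean(b[1:2, 3:4]), mean(b[3:4, 3:4])), 2, 2))
})

test_that("unrolled features are scaled row-major pixels", {
  expect_equal(unroll_normalize(matrix(255L, 32, 32)), rep(1, 1024))
  expect_equal(unroll_normalize(matrix(0L, 32, 32)), rep(0, 1024))
  expect_length(unroll_normalize(matrix(0L, 520, 520), 32), 1024)
  m <- matrix(0L, 32, 32); m[1, 2] <- 255L  # row 1, col 2 -> second entry
  expect_equal(which(unroll_normalize(m) == 1), 2)
})

test_that("HOG layout follows the 8-orientation 4x4-cell configuration", {
  f <- matrix(as.integer(round(runif(64 * 64, 0, 255))), 64, 64)
  expect_length(hog_features(f, 32), 8 * (32 / 4)^2)   # 512
  expect_length(hog_features(f, 64), 8 * (64 / 4)^2)   # 2048
  expect_equal(hog_features(matrix(100L, 32, 32), 32), rep(0, 512))
  expect_error(hog_features(f, 30), "divisible")
  # a vertical step edge excites a single orientation bin in its cells
  e <- matrix(0L, 32, 32); e[, 17:32] <- 255L
  h <- matrix(hog_features(e, 32), nrow = 8)
  active_bins <- which(rowSums(h) > 0)
  expect_equal(active_bins, 1)  # horizontal gradient, orientation 0
})

test_that("LBP histograms are normalized uniform-pattern counts", {
  f <- matrix(as.integer(round(runif(40 * 40, 0, 255))), 40, 40)
  v <- lbp_features(f, 32)
  expect_length(v, 102)
  expect_equal(sum(v), 1)
  # constant image: every neighbor ties the center -> all-ones uniform code
  vc <- lbp_features(matrix(100L, 40, 40), 32)
  expect_equal(which(vc > 0), 101)
  expect_equal(vc[101], 1)
  expect_error(lbp_features(f, 12, radius = 5), "small")
  # direct per-pixel oracle on a tiny image with a small circle
  side <- 16; radius <- 2; points <- 8
  img <- resize_area(matrix(as.integer(round(runif(side^2, 0, 255))),
                            side, side), side, side)
  oracle <- numeric(points + 2)
  for (cy in (radius + 1):(side - radius)) {
    for (cx in (radius + 1):(side - radius)) {
      bits <- logical(points)
      for (p in seq_len(points)) {
        ang <- 2 * pi * (p - 1) / points
        sx <- cx + radius * cos(ang); sy <- cy - radius * sin(ang)
        x0 <- floor(sx); y0 <- floor(sy)
        fx <- sx - x0; fy <- sy - y0
        x1 <- min(x0 + 1, side); y1 <- min(y0 + 1, side)
        v <- img[y0, x0] * (1 - fx) * (1 - fy) +
          img[y0, x1] * fx * (1 - fy) +
          img[y1, x0] * (1 - fx) * fy + img[y1, x1] * fx * fy
        bits[p] <- v >= img[cy, cx] - 1e-9
      }
      tr <- sum(bits != bits[c(2:points, 1)])
      code <- if (tr <= 2) sum(bits) else points + 1
      oracle[code + 1] <- oracle[code + 1] + 1
    }
  }
  expect_equal(lbp_features(img, side, radius = radius, points = points),
               oracle / sum(oracle))
})

test_that("features are bit-for-bit deterministic", {
  ds <- small_suite()
  f <- ds$frames[[1]]
  expect_identical(unroll_normalize(f, 32), unroll_normalize(f, 32))
  expect_identical(hog_features(f, 32), hog_features(f, 32))
  expect_identical(lbp_features(f, 32), lbp_features(f, 32))
})
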