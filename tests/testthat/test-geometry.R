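test_that("region_of follows the central-circle and diagonal rules", {
  g <- annotation_geometry()
  expect_equal(region_of(c(260, 260), g), "central")   # distance 0
  expect_equal(region_of(c(260, 100), g), "up")        # y offset -160
  expect_equal(region_of(c(450, 260), g), "right")     # x offset +190
  expect_equal(region_of(c(260, 450), g), "down")
  expect_equal(region_of(c(100, 260), g), "left")
  # edge of the central region is included
  expect_equal(region_of(c(260 + 69, 260), g), "central")
  expect_equal(region_of(c(260 + 69.0001, 260), g), "right")
  # points exactly on a diagonal take the fixed priority up > right > down > left
  expect_equal(region_of(c(100, 100), g), "up")
  expect_equal(region_of(c(420, 100), g), "up")
  expect_equal(region_of(c(420, 420), g), "right")
  expect_equal(region_of(c(100, 420), g), "down")
  expect_error(region_of(c(-1, 10), g), "outside")
})

test_that("region_of agrees with a brute-force sign/circle oracle", {
  g <- annotation_geometry()
  oracle <- function(p) {
    dx <- p[1] - 260; dy <- p[2] - 260
    if (dx^2 + dy^2 <= 69^2) return("central")
    above_main <- dy - dx   # main diagonal y = x, negative above it
    above_anti <- dy + dx   # anti-diagonal y = 520 - x, negative above it
    if (above_main < 0 && above_anti < 0) return("up")
    if (above_main < 0 && above_anti > 0) return("right")
    if (above_main > 0 && above_anti > 0) return("down")
    if (above_main > 0 && above_anti < 0) return("left")
    # on a diagonal: same priority as the implementation contract
    if (dy <= 0) "up" else if (dx >= 0) "right" else "down"
  }
  set.seed(101)
  pts <- matrix(runif(2e4, 0, 520), ncol = 2)
  got <- apply(pts, 1, region_of, geometry = g)
  want <- apply(pts, 1, oracle)
  expect_identical(got, want)
})

test_that("reflection across the vertical midline swaps left and right only", {
  g <- annotation_geometry()
  set.seed(7)
  pts <- matrix(runif(600, 0, 520), ncol = 2)
  swap <- c(up = "up", down = "down", left = "right", right = "left",
            central = "central")
  for (i in seq_len(nrow(pts))) {
    r1 <- region_of(pts[i, ], g)
    r2 <- region_of(c(520 - pts[i, 1], pts[i, 2]), g)
    expect_identical(r2, unname(swap[r1]))
  }
})

test_that("assign_label implements the six annotation rules and is total", {
  expect_equal(assign_label(c(260, 260), 1.00), "correct")
  expect_equal(assign_label(c(260, 260), 0.85), "closed")   # > 10% covered
  expect_equal(assign_label(c(400, 260), 0.50), "right")
  expect_equal(assign_label(c(400, 260), 0.10), "closed")   # > 85% covered
  expect_equal(assign_label(NULL, 0), "closed")
  expect_equal(assign_label(c(NA, NA), 0.5), "closed")
  # boundary conventions: 0.90 inside -> closed; 0.15 outside -> directional
  expect_equal(assign_label(c(260, 260), 0.90), "closed")
  expect_equal(assign_label(c(400, 260), 0.15), "right")
  # totality over a (distance, visibility) grid, against a rule table
  g <- annotation_geometry()
  for (d in c(0, 30, 69, 70, 150, 250)) {
    for (v in c(0, 0.1, 0.15, 0.5, 0.9, 0.95, 1)) {
      lab <- assign_label(c(260 + d, 260), v, g)
      expect_true(lab %in% eye_labels())
      want <- if (d <= 69) {
        if (v > 0.90) "correct" else "closed"
      } else {
        if (v >= 0.15) "right" else "closed"
      }
      expect_identical(lab, want)
    }
  }
})

test_that("geometry scaling is linear and label-invariant", {
  g <- annotation_geometry()
  g260 <- scale_geometry(g, 260)
  expect_equal(g260$central_radius, 34.5)
  expect_equal(g260$center, c(130, 130))
  expect_equal(scale_geometry(g, 520)$central_radius, 69)
  expect_equal(scale_geometry(g, 130)$central_radius, 17.25)
  expect_error(scale_geometry(g, 0), "positive")
  set.seed(11)
  for (i in 1:50) {
    p <- runif(2, 1, 519); v <- runif(1)
    s <- sample(c(0.125, 0.25, 0.5, 2), 1)
    expect_identical(assign_label(p, v, g),
                     assign_label(p * s, v, scale_geometry(g, 520 * s)))
  }
})
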