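test_that("preprocessing yields an empty mask on a blank frame", {
  pre <- es_preprocess(matrix(0L, 520, 772))
  expect_equal(sum(pre$mask), 0)
  expect_equal(dim(pre$mask), c(520, 520))
})

test_that("no foreground survives beyond the ring radius", {
  # saturate everything: any dark structure near the rim must be cut
  f <- render_frame(clean_spec(), seed = 3)
  pre <- es_preprocess(f)
  idx <- which(pre$mask > 0, arr.ind = TRUE)
  if (nrow(idx)) {
    d <- sqrt((idx[, 2] - 0.5 - 260)^2 + (idx[, 1] - 0.5 - 260)^2)
    expect_true(all(d <= 245 + 1e-9))
  }
  succeed()
})

test_that("a clean centered pupil produces one component overlapping it", {
  spec <- clean_spec()
  f <- render_frame(spec, seed = 3)
  pre <- es_preprocess(f)
  lab <- EBImage::bwlabel(pre$mask)
  expect_equal(max(lab), 1)
  # oracle: the generator's own pupil disc in cropped coordinates
  xs <- seq_len(520) - 0.5
  pupil <- outer((xs - 260)^2, (xs - 260)^2, "+") <= 55^2
  expect_gt(sum(pre$mask > 0 & pupil) / sum(pupil), 0.8)
})

test_that("candidate filters enforce size and darkness rules", {
  params <- es_params()
  ref <- matrix(255, 520, 520)
  put_disc <- function(mask, cx, cy, r) {
    xs <- seq_len(520) - 0.5
    mask[outer((xs - cy)^2, (xs - cx)^2, "+") <= r^2] <- 1
    mask
  }
  # inscribed radius 15 < 20: rejected
  m <- put_disc(matrix(0, 520, 520), 260, 260, 15)
  expect_length(es_find_candidates(m, ref * 0, params), 0)
  # inscribed radius 160 > 150: rejected
  m <- put_disc(matrix(0, 520, 520), 260, 260, 160)
  expect_length(es_find_candidates(m, ref * 0, params), 0)
  # the right size but too bright on the reference: rejected
  m <- put_disc(matrix(0, 520, 520), 260, 260, 55)
  expect_length(es_find_candidates(m, ref, params), 0)
  # the right size and dark: kept, with sane descriptors
  cands <- es_find_candidates(m, ref * 0, params)
  expect_length(cands, 1)
  expect_equal(cands[[1]]$center, c(260, 260), tolerance = 0.01)
  expect_gt(cands[[1]]$circularity, 0.95)
  expect_lte(cands[[1]]$circularity, 1)
  expect_equal(cands[[1]]$area, pi * 55^2, tolerance = 0.05)
})

test_that("selection prefers circular, dark, large candidates with fixed ties", {
  expect_null(es_select(list()))
  c1 <- list(center = c(100, 100), bbox = c(xmin = 80, xmax = 120,
             ymin = 80, ymax = 120), hull = NULL,
             circularity = 0.9, darkness = 0.8, area = 3000)
  expect_identical(es_select(list(c1))$center, c1$center)
  c2 <- c1; c2$area <- 5000; c2$center <- c(300, 300)
  expect_identical(es_select(list(c1, c2))$center, c(300, 300))
  # exact tie on all three: larger area wins, then leftmost-topmost
  c3 <- c1; c3$center <- c(50, 50)
  expect_identical(es_select(list(c1, c3))$center, c(50, 50))
})

test_that("frame classification matches generator ground truth end to end", {
  expect_equal(es_classify_frame(matrix(0L, 520, 772))$label, "closed")
  r <- es_classify_frame(render_frame(clean_spec(), 3))
  expect_equal(r$label, "correct")
  expect_equal(r$detection$center, c(260, 260), tolerance = 3)
  r2 <- es_classify_frame(render_frame(
    clean_spec(pupil_center = c(386 + 160, 260)), 4))
  expect_equal(r2$label, "right")
  r3 <- es_classify_frame(render_frame(
    clean_spec(eyelid_coverage = 0.9), 5))
  expect_equal(r3$label, "closed")
  # totality on pathological inputs
  expect_true(es_classify_frame(matrix(255L, 520, 772))$label %in% eye_labels())
  set.seed(1)
  noise <- matrix(as.integer(sample.int(256, 520 * 772, TRUE) - 1), 520, 772)
  expect_true(es_classify_frame(noise)$label %in% eye_labels())
})

test_that("classification is deterministic", {
  f <- render_frame(scene_spec(noise_sigma = 4), 77)
  r1 <- es_classify_frame(f)
  r2 <- es_classify_frame(f)
  expect_identical(r1, r2)
})

test_that("parameter scaling halves pixel quantities with odd rounding", {
  p <- es_params()
  expect_equal(es_scale_params(p, 520), p)
  p260 <- es_scale_params(p, 260)
  expect_equal(p260$gaussian_kernel, c(11, 5))
  expect_equal(p260$morph_kernel, 11)
  expect_equal(p260$inscribed_radius_range, c(10, 75))
  expect_equal(p260$ring_radius, 122.5)
  expect_equal(p260$mask_threshold, 80)   # intensity thresholds unchanged
  p65 <- es_scale_params(p, 65)
  expect_equal(p65$adaptive_block, 3)     # floored at the minimum block
  expect_equal(p65$gaussian_kernel, c(3, 3))
  expect_error(es_scale_params(p, -10), "positive")
})

test_that("a scaled detector still reads scaled frames", {
  spec <- clean_spec(frame_width = 260, frame_height = 260,
                     lens_center = c(130, 130), lens_radius = 125,
                     pupil_center = c(130, 130), pupil_axes = c(27, 27),
                     iris_radius = 60, glint_ring_radius = 44)
  f <- render_frame(spec, 9)
  r <- es_classify_frame(f, es_scale_params(es_params(), 260))
  expect_equal(r$label, "correct")
})
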