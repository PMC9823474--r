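test_that("rendering is deterministic and respects the scene contract", {
  spec <- clean_spec()
  f1 <- render_frame(spec, seed = 5)
  f2 <- render_frame(spec, seed = 5)
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(520, 772))
  # noiseless: everything beyond the lens disc is exactly black
  xs <- seq_len(772) - 0.5; ys <- seq_len(520) - 0.5
  D2 <- outer((ys - 260)^2, (xs - 386)^2, "+")
  expect_true(all(f1[D2 > 250^2] == 0))
  # pupil darker than iris, exact level at the center
  expect_equal(f1[260, 386], 30)
  expect_lt(f1[260, 386], spec$iris_intensity)
  # saturated glints present
  expect_gte(sum(f1 == 255), spec$glint_count)
  # a different seed changes the noisy render
  spec_n <- scene_spec(noise_sigma = 4)
  expect_false(identical(render_frame(spec_n, 1), render_frame(spec_n, 2)))
})

test_that("scene invariants are validated", {
  expect_error(scene_spec(pupil_intensity = 200, iris_intensity = 110),
               "darker")
  expect_error(scene_spec(eyelid_coverage = 1.4), "eyelid_coverage")
  expect_error(scene_spec(pupil_center = c(700, 260)), "lens")
  expect_error(scene_spec(noise_sigma = -1), "noise")
})

test_that("ground truth matches the labeling rules", {
  gt <- ground_truth(clean_spec())
  expect_equal(gt$visible_fraction, 1.0)
  expect_equal(gt$label, "correct")
  expect_equal(gt$pupil_center, c(260, 260))

  gt_closed <- ground_truth(clean_spec(eyelid_coverage = 1))
  expect_equal(gt_closed$visible_fraction, 0)
  expect_equal(gt_closed$label, "closed")

  gt_right <- ground_truth(clean_spec(pupil_center = c(386 + 150, 260)))
  expect_equal(gt_right$label, "right")
})

test_that("eyelid coverage is honored and visibility is monotone in it", {
  for (cov in c(0.2, 0.5, 0.8)) {
    gt <- ground_truth(clean_spec(eyelid_coverage = cov))
    expect_equal(gt$visible_fraction, 1 - cov, tolerance = 0.01)
  }
  covs <- seq(0, 1, by = 0.1)
  vis <- vapply(covs, function(cv)
    ground_truth(clean_spec(eyelid_coverage = cv))$visible_fraction,
    numeric(1))
  expect_true(all(diff(vis) <= 1e-12))
  # resting lids never occlude the pupil
  gt_rest <- ground_truth(clean_spec(eyelid_rest = 1, eyelid_lower_rest = 1))
  expect_equal(gt_rest$visible_fraction, 1.0)
})

test_that("generated datasets honor profile counts and are self-consistent", {
  ds <- small_suite()
  m <- ds$manifest
  expect_equal(nrow(m), 30)
  expect_equal(as.integer(table(m$label)[eye_labels()]), rep(5L, 6))
  # the stored ground truth re-derives the stored label
  g <- annotation_geometry()
  for (i in seq_len(nrow(m)))
    expect_identical(assign_label(c(m$cx[i], m$cy[i]),
                                  m$visible_fraction[i], g), m$label[i])
  # determinism of the full generation pipeline
  ds2 <- generate_dataset(stats::setNames(rep(5L, 6), eye_labels()),
                          seed = 424242L)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$frames, ds2$frames)
})

test_that("single-class profiles and infeasible ranges are handled", {
  one <- generate_dataset(c(correct = 3), seed = 7)
  expect_equal(nrow(one$manifest), 3)
  expect_true(all(one$manifest$label == "correct"))
  bad_ranges <- class_ranges()
  # feasible scenes, but the center always falls outside the central region
  bad_ranges$correct$r <- c(90, 105)
  expect_error(
    generate_dataset(c(correct = 1), seed = 1, ranges = bad_ranges,
                     max_attempts = 10L),
    "correct")
})

test_that("datasets round-trip through PNG files and the manifest CSV", {
  dir <- withr::local_tempdir()
  profile <- c(correct = 2, closed = 2)
  ds <- generate_dataset(profile, seed = 99L, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(m), 4)
  expect_true(all(file.exists(file.path(dir, m$path))))
  # the PNG holds the identical 8-bit frame
  spec_set <- generate_dataset(profile, seed = 99L)
  back <- read_frame(file.path(dir, m$path[1]))
  expect_identical(back, spec_set$frames[[1]])
})

test_that("manifests reject unknown labels and malformed rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  m <- data.frame(path = "a.png", label = "blink", cx = 1, cy = 2,
                  visible_fraction = 0.5, seed = 3)
  utils::write.csv(m, path, row.names = FALSE)
  expect_error(read_manifest(path), "blink")
  m$label <- "correct"
  write_manifest(m, path)
  expect_equal(read_manifest(path)$label, "correct")
  writeLines("path,label,cx,cy,visible_fraction,seed", path)
  expect_equal(nrow(read_manifest(path)), 0)
})
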