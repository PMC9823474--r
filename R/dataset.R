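#' Per-class frame counts for a dataset partition
#'
#' The instrument's annotated corpus is heavily imbalanced: frames with the
#' pupil centered and uncovered dominate, while blinks and off-axis gaze are
#' comparatively rare. `paper_profile()` returns the published train/test
#' composition (train 7410/1040/586/546/629/265 for
#' correct/closed/right/left/up/down; 750 per class in the balanced test
#' partition), optionally scaled down for desk-scale experiments.
#'
#' @param scale Multiplier applied to every count (counts are rounded and
#'   kept at least 1 when the unscaled count was positive).
#' @return A list with named integer vectors `train` and `test`.
#' @export
paper_profile <- function(scale = 1) {
  train <- c(correct = 7410, closed = 1040, right = 586, left = 546,
             up = 629, down = 265)
  test <- c(correct = 750, closed = 750, right = 750, left = 750,
            up = 750, down = 750)
  shrink <- function(x) ifelse(x > 0, pmax(1L, as.integer(round(x * scale))), 0L)
  list(train = shrink(train), test = shrink(test))
}

#' Randomization ranges used to sample scenes of each class
#'
#' For each of the six labels, defines how scene parameters are drawn so
#' that the resulting ground-truth label matches the class. Distances are
#' measured from the crop center in pixels of the 520-px geometry (ranges
#' scale with the geometry):
#' \describe{
#'   \item{correct}{pupil center within 55 px of the crop center, at most
#'     4% of the pupil occluded.}
#'   \item{right/down/left/up}{pupil center at 110--180 px in the matching
#'     diagonal sector (10 degrees away from the diagonals), at most 15%
#'     occluded.}
#'   \item{closed}{pupil center within 55 px of the crop center with 55--100%
#'     of the pupil occluded by the eyelid (a blink).}
#' }
#' Pupil semi-axes are drawn in 45--60 px with up to 10% x/y anisotropy.
#' Occlusion ranges deliberately sit well away from the 90%/15% visibility
#' rule boundaries so labels are unambiguous.
#'
#' @return A named list of per-class sampling ranges.
#' @export
class_ranges <- function() {
  base <- list(r = c(0, 55), coverage = c(0, 0.04), axes = c(32, 72))
  dir <- function(angle_deg) {
    list(r = c(110, 180), coverage = c(0, 0.15), axes = c(32, 72),
         angle = angle_deg)  # sector center, degrees; x right, y down
  }
  list(
    correct = base,
    closed = list(r = c(0, 55), coverage = c(0.55, 1), axes = c(32, 72)),
    right = dir(0), down = dir(90), left = dir(180), up = dir(270)
  )
}

# draw one scene_spec aimed at `class`; uses the current RNG stream
sample_scene <- function(class, ranges = class_ranges(),
                         frame_width = 772, frame_height = 520,
                         noise_sigma = 4, eyelashes = FALSE) {
  rg <- ranges[[class]]
  if (is.null(rg)) stop("unknown class: ", class)
  side <- frame_height
  geom_scale <- side / 520
  cx0 <- frame_width / 2; cy0 <- frame_height / 2
  a <- stats::runif(1, rg$axes[1], rg$axes[2]) * geom_scale
  b <- a * stats::runif(1, 0.9, 1.1)
  # keep the pupil ellipse inside the lens disc
  r_hi <- min(rg$r[2] * geom_scale, 248 * geom_scale - max(a, b))
  r_lo <- min(rg$r[1] * geom_scale, r_hi)
  r <- stats::runif(1, r_lo, r_hi)
  if (is.null(rg$angle)) {
    ang <- stats::runif(1, 0, 2 * pi)
  } else {
    # stay 10 degrees clear of the two diagonals bounding the sector
    ang <- (rg$angle + stats::runif(1, -35, 35)) * pi / 180
  }
  coverage <- stats::runif(1, rg$coverage[1], rg$coverage[2])
  # subject/session appearance variability: exposure, tissue reflectivity,
  # iris size and texture depth, resting lid position
  gain <- stats::runif(1, 0.92, 1.08)
  scene_spec(frame_width = frame_width, frame_height = frame_height,
             lens_radius = 250 * geom_scale,
             pupil_center = c(cx0 + r * cos(ang), cy0 + r * sin(ang)),
             pupil_axes = c(a, b),
             pupil_intensity = stats::runif(1, 20, 40),
             iris_intensity = stats::runif(1, 100, 135),
             sclera_intensity = stats::runif(1, 200, 245),
             skin_intensity = stats::runif(1, 135, 185),
             iris_radius = stats::runif(1, 1.9, 2.6) * max(a, b),
             iris_texture_amp = stats::runif(1, 6, 12),
             eyelid_coverage = coverage,
             eyelid_rest = stats::runif(1, 0, 1),
             eyelid_lower_rest = stats::runif(1, 0, 1),
             eyelashes = eyelashes,
             gain = gain,
             noise_sigma = noise_sigma)
}

#' Generate a labeled synthetic eye-frame dataset
#'
#' Draws scenes per class (rejection-sampling the randomization ranges until
#' the self-computed ground-truth label matches the requested class), renders
#' each frame, and returns frames together with a manifest of exact ground
#' truth. Everything is reproducible from the single master `seed`. When
#' `dir` is given, frames are written as 8-bit grayscale PNGs, the manifest
#' as `manifest.csv`, and a JSON sidecar records the profile and seed.
#'
#' @param profile Named integer vector of per-class frame counts (names from
#'   [eye_labels()]).
#' @param seed Master integer seed.
#' @param ranges Per-class sampling ranges, see [class_ranges()].
#' @param dir Optional output directory; created if missing.
#' @param cropped If `TRUE`, renders pre-cropped square frames
#'   (`side x side`) instead of native 772 x 520 frames.
#' @param side Square side used when `cropped = TRUE` (also the crop height
#'   of native frames).
#' @param noise_sigma Sensor-noise level passed to every scene.
#' @param eyelashes Draw lash streaks on occluded frames.
#' @param max_attempts Rejection-sampling cap per frame.
#' @return A list with `manifest` (data.frame: path, label, cx, cy,
#'   visible_fraction, seed) and `frames` (list of frame matrices; `NULL`
#'   entries when written to disk).
#' @export
generate_dataset <- function(profile, seed = 1L, ranges = class_ranges(),
                             dir = NULL, cropped = FALSE, side = 520,
                             noise_sigma = 4, eyelashes = FALSE,
                             max_attempts = 200L) {
  stopifnot(!is.null(names(profile)), all(names(profile) %in% eye_labels()),
            all(profile >= 0))
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  fw <- if (cropped) side else round(772 * side / 520)
  fh <- side
  n_total <- sum(profile)
  rows <- vector("list", n_total)
  frames <- vector("list", n_total)
  i <- 0L
  with_seed(seed, {
    for (class in names(profile)) {
      for (k in seq_len(profile[[class]])) {
        found <- FALSE
        for (attempt in seq_len(max_attempts)) {
          spec <- sample_scene(class, ranges, fw, fh, noise_sigma, eyelashes)
          gt <- ground_truth(spec)
          if (gt$label == class) { found <- TRUE; break }
        }
        if (!found)
          stop("could not generate a frame of class '", class,
               "' within ", max_attempts, " attempts")
        frame_seed <- sample.int(2147483646L, 1)
        frame <- render_frame(spec, seed = frame_seed)
        i <- i + 1L
        path <- sprintf("%s_%04d.png", class, k)
        if (!is.null(dir)) {
          write_frame(frame, file.path(dir, path))
        } else {
          frames[[i]] <- frame
        }
        rows[[i]] <- data.frame(
          path = path, label = class,
          cx = gt$pupil_center[1], cy = gt$pupil_center[2],
          visible_fraction = gt$visible_fraction, seed = frame_seed,
          stringsAsFactors = FALSE)
      }
    }
  })
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    jsonlite::write_json(
      list(profile = as.list(profile), seed = seed, cropped = cropped,
           side = side, noise_sigma = noise_sigma),
      file.path(dir, "dataset.json"), auto_unbox = TRUE, digits = NA)
    frames <- NULL
  }
  list(manifest = manifest, frames = frames)
}

#' The fixed "easy suite" of benchmark frames
#'
#' A balanced 600-frame evaluation set (100 per class, master seed
#' 20221229) rendered at moderate sensor noise without lash streaks, with
#' eyelid coverage drawn clear of the labeling-rule boundaries. Used
#' throughout the tests as a reproducible stand-in for real recordings.
#'
#' @param per_class Frames per class.
#' @param seed Master seed.
#' @param noise_sigma Sensor-noise level.
#' @param side Crop side in pixels.
#' @inheritParams generate_dataset
#' @return As [generate_dataset()], frames kept in memory.
#' @export
easy_suite <- function(per_class = 100L, seed = 20221229L, noise_sigma = 4,
                       side = 520, cropped = FALSE) {
  profile <- stats::setNames(rep(as.integer(per_class), 6), eye_labels())
  generate_dataset(profile, seed = seed, cropped = cropped, side = side,
                   noise_sigma = noise_sigma, eyelashes = FALSE)
}
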