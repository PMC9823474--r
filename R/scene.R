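#' Scene specification for a synthetic eye frame
#'
#' Parametrizes one rendered frame of the kind a monocular infrared
#' pupillometer produces: a bright circular lens field on a black background,
#' a uniform iris, a dark elliptical pupil, a ring of specular LED glints
#' around the pupil, an eyelid occluder descending from the top, and additive
#' sensor noise. All coordinates are native-frame image coordinates (x
#' rightward, y downward, origin top-left).
#'
#' The eyelid is modeled as a circular arc of skin-toned intensity (radius
#' 1.5 x the lens radius) whose descent depth is solved so that it occludes
#' exactly `eyelid_coverage` of the pupil area.
#'
#' @param frame_width,frame_height Frame size in pixels (device native
#'   772 x 520; pass equal values for a pre-cropped square frame).
#' @param lens_center Center of the illuminated lens disc (default frame
#'   center).
#' @param lens_radius Lens disc radius in pixels.
#' @param pupil_center Pupil ellipse center.
#' @param pupil_axes Numeric length-2 pupil semi-axes (x, y) in pixels.
#' @param pupil_intensity,iris_intensity,sclera_intensity,skin_intensity
#'   8-bit gray levels of the pupil, the iris disc surrounding it, the
#'   sclera filling the rest of the lens field, and the eyelid skin; the
#'   pupil must be darker than the iris.
#' @param iris_radius Radius of the iris disc, centered on (and moving
#'   with) the pupil; defaults to 2.3 x the larger pupil semi-axis.
#' @param iris_texture_amp Amplitude of the seeded radial iris texture
#'   (8-bit levels).
#' @param gain Global exposure gain applied to the rendered frame before
#'   noise (per-frame exposure variability).
#' @param glint_count Number of LED glints (device has 8).
#' @param glint_ring_radius Radius of the glint ring around the pupil
#'   center; defaults to 1.6 x the larger pupil semi-axis.
#' @param eyelid_coverage Fraction of the pupil area occluded by the eyelid,
#'   in \[0, 1\].
#' @param eyelid_rest Resting position of the upper lid in \[0, 1\]: 0 hides
#'   the lid above the frame, 1 brings it down to just touch the pupil.
#'   Occludes no pupil area; the effective lid position is the lower of the
#'   resting lid and the `eyelid_coverage`-driven lid.
#' @param eyelid_lower_rest Resting position of the lower lid in \[0, 1\]:
#'   0 hides it below the frame, 1 raises it to just touch the pupil;
#'   never occludes pupil area.
#' @param eyelashes If `TRUE`, draws a few dark lash streaks hanging from
#'   the eyelid edge.
#' @param noise_sigma Standard deviation of additive Gaussian sensor noise
#'   (8-bit levels).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(frame_width = 772, frame_height = 520,
                       lens_center = c(frame_width / 2, frame_height / 2),
                       lens_radius = 250,
                       pupil_center = lens_center,
                       pupil_axes = c(55, 55),
                       pupil_intensity = 30, iris_intensity = 110,
                       sclera_intensity = 210, skin_intensity = 180,
                       iris_radius = 2.3 * max(pupil_axes),
                       iris_texture_amp = 12,
                       glint_count = 8,
                       glint_ring_radius = 1.6 * max(pupil_axes),
                       eyelid_coverage = 0, eyelid_rest = 0,
                       eyelid_lower_rest = 0,
                       eyelashes = FALSE,
                       gain = 1, noise_sigma = 4) {
  spec <- list(frame_width = frame_width, frame_height = frame_height,
               lens_center = as.numeric(lens_center),
               lens_radius = lens_radius,
               pupil_center = as.numeric(pupil_center),
               pupil_axes = as.numeric(pupil_axes),
               pupil_intensity = pupil_intensity,
               iris_intensity = iris_intensity,
               sclera_intensity = sclera_intensity,
               skin_intensity = skin_intensity,
               iris_radius = iris_radius,
               iris_texture_amp = iris_texture_amp,
               glint_count = glint_count,
               glint_ring_radius = glint_ring_radius,
               eyelid_coverage = eyelid_coverage,
               eyelid_rest = eyelid_rest,
               eyelid_lower_rest = eyelid_lower_rest,
               eyelashes = isTRUE(eyelashes),
               gain = gain,
               noise_sigma = noise_sigma)
  validate_scene_spec(spec)
  structure(spec, class = "scene_spec")
}

validate_scene_spec <- function(spec) {
  with(spec, {
    if (frame_width < 1 || frame_height < 1) stop("frame size must be positive")
    ints <- c(pupil_intensity, iris_intensity, sclera_intensity,
              skin_intensity)
    if (any(ints < 0) || any(ints > 255)) stop("intensities must lie in [0, 255]")
    if (pupil_intensity >= iris_intensity) stop("pupil must be darker than the iris")
    if (gain <= 0) stop("gain must be positive")
    if (iris_radius <= max(pupil_axes)) stop("iris must be larger than the pupil")
    if (eyelid_coverage < 0 || eyelid_coverage > 1)
      stop("eyelid_coverage must lie in [0, 1]")
    if (eyelid_rest < 0 || eyelid_rest > 1)
      stop("eyelid_rest must lie in [0, 1]")
    if (eyelid_lower_rest < 0 || eyelid_lower_rest > 1)
      stop("eyelid_lower_rest must lie in [0, 1]")
    if (any(pupil_axes <= 0)) stop("pupil semi-axes must be positive")
    # the pupil ellipse must sit inside the lens disc
    r <- sqrt(sum((pupil_center - lens_center)^2))
    if (r + max(pupil_axes) > lens_radius)
      stop("pupil ellipse must lie within the lens disc")
    if (glint_count < 0) stop("glint_count must be non-negative")
    if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  })
  invisible(spec)
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Supersampled sample points of the pupil ellipse (4x4 per pixel).
# Returns a list with x, y coordinates of points inside the ellipse.
pupil_samples <- function(spec, factor = 4) {
  a <- spec$pupil_axes[1]; b <- spec$pupil_axes[2]
  cx <- spec$pupil_center[1]; cy <- spec$pupil_center[2]
  step <- 1 / factor
  xs <- seq(cx - a + step / 2, cx + a, by = step)
  ys <- seq(cy - b + step / 2, cy + b, by = step)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  inside <- ((gx - cx) / a)^2 + ((gy - cy) / b)^2 <= 1
  list(x = gx[inside], y = gy[inside])
}

# For the circular-arc eyelid with apex depth d (lowest boundary point at
# y = d under the lens center column), a point (x, y) is occluded iff
# d >= y + R - sqrt(R^2 - (x - xc)^2). Returns that per-point threshold.
lid_depth_threshold <- function(x, y, spec) {
  R <- 1.5 * spec$lens_radius
  dx <- x - spec$lens_center[1]
  s <- sqrt(pmax(R^2 - dx^2, 0))
  out <- y + R - s
  out[abs(dx) > R] <- Inf
  out
}

# Effective lid apex depth: the deeper of the coverage-driven lid (the
# nearest-rank quantile of the per-sample thresholds, so it occludes
# exactly the requested pupil-area fraction on the supersampling grid) and
# the resting lid (interpolated between the frame top and the pupil top,
# occluding nothing). -Inf when no lid is drawn.
lid_depth <- function(spec) {
  cov_d <- -Inf; rest_d <- -Inf
  dmin <- NULL
  if (spec$eyelid_coverage > 0 || spec$eyelid_rest > 0) {
    p <- pupil_samples(spec)
    dmin <- sort(lid_depth_threshold(p$x, p$y, spec))
  }
  if (spec$eyelid_coverage > 0) {
    n <- length(dmin)
    k <- min(n, max(1, ceiling(spec$eyelid_coverage * n)))
    cov_d <- if (spec$eyelid_coverage >= 1) dmin[n] + 1e-6 else dmin[k]
  }
  if (spec$eyelid_rest > 0) {
    # a resting lid hangs in the upper part of the lens: its apex never
    # descends below 0.55 lens radii above the lens center, and never
    # touches the pupil
    cap <- min(dmin[1] - 1e-3,
               spec$lens_center[2] - 0.55 * spec$lens_radius)
    rest_d <- spec$eyelid_rest * cap
  }
  max(cov_d, rest_d)
}

# apex depth of the (never-occluding) lower lid, in mirrored coordinates;
# its apex stays at least 0.55 lens radii below the lens center
lower_lid_depth <- function(spec) {
  if (spec$eyelid_lower_rest <= 0) return(-Inf)
  p <- pupil_samples(spec)
  dmin <- min(lid_depth_threshold(p$x, spec$frame_height - p$y, spec))
  cap <- min(dmin - 1e-3,
             spec$frame_height - spec$lens_center[2] -
               0.55 * spec$lens_radius)
  spec$eyelid_lower_rest * cap
}

#' Render a synthetic eye frame
#'
#' Deterministically renders the scene described by `spec`: pixels outside
#' the lens disc are black (exactly 0 when `noise_sigma = 0`), the iris
#' fills the disc, the pupil ellipse is drawn at `pupil_intensity`, glints
#' are saturated (255) Gaussian spots on a ring around the pupil, and the
#' eyelid arc covers the requested fraction of the pupil from above. Gaussian
#' noise is added last and the result clipped to 0..255.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed controlling the noise (and lash placement); the
#'   same `(spec, seed)` pair always renders a bit-identical frame.
#' @return An integer frame matrix (`frame_height` x `frame_width`).
#' @export
render_frame <- function(spec, seed = 1L) {
  validate_scene_spec(spec)
  h <- spec$frame_height; w <- spec$frame_width
  # pixel-center coordinate grids
  xs <- seq_len(w) - 0.5
  ys <- seq_len(h) - 0.5
  X <- matrix(xs, h, w, byrow = TRUE)
  Y <- matrix(ys, h, w)

  img <- matrix(0, h, w)
  in_lens <- (X - spec$lens_center[1])^2 + (Y - spec$lens_center[2])^2 <=
    spec$lens_radius^2
  img[in_lens] <- spec$sclera_intensity

  with_seed(seed, {
    # iris disc centered on (moving with) the pupil, with radial texture
    ir <- spec$iris_radius
    jj <- max(1, floor(spec$pupil_center[1] - ir)):
      min(w, ceiling(spec$pupil_center[1] + ir) + 1)
    ii <- max(1, floor(spec$pupil_center[2] - ir)):
      min(h, ceiling(spec$pupil_center[2] + ir) + 1)
    dxm <- matrix(jj - 0.5 - spec$pupil_center[1], length(ii), length(jj),
                  byrow = TRUE)
    dym <- matrix(ii - 0.5 - spec$pupil_center[2], length(ii), length(jj))
    in_iris <- dxm^2 + dym^2 <= ir^2
    phase <- stats::runif(1, 0, 2 * pi)
    tex <- spec$iris_intensity +
      spec$iris_texture_amp * sin(17 * atan2(dym, dxm) + phase)
    sub <- img[ii, jj, drop = FALSE]
    sel <- in_iris & in_lens[ii, jj, drop = FALSE]
    sub[sel] <- tex[sel]
    img[ii, jj] <- sub

    # pupil ellipse
    a <- spec$pupil_axes[1]; b <- spec$pupil_axes[2]
    jj <- max(1, floor(spec$pupil_center[1] - a)):
      min(w, ceiling(spec$pupil_center[1] + a) + 1)
    ii <- max(1, floor(spec$pupil_center[2] - b)):
      min(h, ceiling(spec$pupil_center[2] + b) + 1)
    in_pupil <- outer(((ii - 0.5 - spec$pupil_center[2]) / b)^2,
                      ((jj - 0.5 - spec$pupil_center[1]) / a)^2, "+") <= 1
    sub <- img[ii, jj, drop = FALSE]
    sub[in_pupil & in_lens[ii, jj, drop = FALSE]] <- spec$pupil_intensity
    img[ii, jj] <- sub
    if (spec$glint_count > 0) {
      ang <- 2 * pi * (seq_len(spec$glint_count) - 1) / spec$glint_count
      gx <- spec$pupil_center[1] + spec$glint_ring_radius * cos(ang)
      gy <- spec$pupil_center[2] + spec$glint_ring_radius * sin(ang)
      # snap to pixel centers so the peak is a saturated pixel
      gx <- round(gx - 0.5) + 0.5
      gy <- round(gy - 0.5) + 0.5
      for (k in seq_len(spec$glint_count)) {
        jlo <- max(1, round(gx[k] - 4.5)); jhi <- min(w, round(gx[k] + 5.5))
        ilo <- max(1, round(gy[k] - 4.5)); ihi <- min(h, round(gy[k] + 5.5))
        if (jlo > jhi || ilo > ihi) next
        jj <- jlo:jhi; ii <- ilo:ihi
        d2 <- outer((ii - 0.5 - gy[k])^2, (jj - 0.5 - gx[k])^2, "+")
        spot <- 255 * exp(-d2 / (2 * 1.5^2))
        spot[d2 <= 1] <- 255
        keep <- in_lens[ii, jj, drop = FALSE]
        img[ii, jj] <- pmax(img[ii, jj], spot * keep)
      }
    }

    if (spec$eyelid_coverage > 0 || spec$eyelid_rest > 0) {
      d <- lid_depth(spec)
      lid <- lid_depth_threshold(X, Y, spec) <= d
      img[lid & in_lens] <- spec$skin_intensity
      if (spec$eyelashes) {
        # dense dark lash fringe hanging from the upper-lid edge
        lx <- spec$lens_center[1] +
          seq(-0.85, 0.85, by = 0.04) * spec$lens_radius
        lx <- lx + stats::runif(length(lx), -2, 2)
        llen <- stats::runif(length(lx), 0.06, 0.18) * spec$lens_radius
        lint <- stats::runif(length(lx), 40, 70)
        lw <- max(1L, round(spec$lens_radius / 125))
        for (k in seq_along(lx)) {
          ylid <- d - (1.5 * spec$lens_radius) +
            sqrt(max((1.5 * spec$lens_radius)^2 -
                     (lx[k] - spec$lens_center[1])^2, 0))
          jj <- round(lx[k]) + seq_len(lw) - 1L
          jj <- jj[jj >= 1 & jj <= w]
          ii0 <- round(ylid)
          ii <- ii0:min(h, ii0 + round(llen[k]))
          ii <- ii[ii >= 1 & ii <= h]
          if (length(jj) && length(ii)) {
            sub <- img[ii, jj, drop = FALSE]
            sub[in_lens[ii, jj, drop = FALSE]] <- lint[k]
            img[ii, jj] <- sub
          }
        }
      }
    }

    if (spec$eyelid_lower_rest > 0) {
      dl <- lower_lid_depth(spec)
      lower <- lid_depth_threshold(X, spec$frame_height - Y, spec) <= dl
      img[lower & in_lens] <- spec$skin_intensity
    }

    img <- img * spec$gain
    if (spec$noise_sigma > 0)
      img <- img + stats::rnorm(length(img), 0, spec$noise_sigma)
  })

  as_frame(pmin(pmax(round(img), 0), 255))
}

#' Ground truth for a synthetic scene
#'
#' Computes, without rendering, the pupil center in cropped-square
#' coordinates, the visible pupil-area fraction (pupil ellipse area neither
#' under the eyelid occluder nor outside the lens disc, by supersampled
#' area integration), and the resulting six-class label under the square
#' crop annotation geometry.
#'
#' @param spec A [scene_spec()].
#' @return A list with `pupil_center` (cropped coordinates),
#'   `visible_fraction`, and `label`.
#' @export
ground_truth <- function(spec) {
  validate_scene_spec(spec)
  p <- pupil_samples(spec)
  vis <- (p$x - spec$lens_center[1])^2 + (p$y - spec$lens_center[2])^2 <=
    spec$lens_radius^2
  if (spec$eyelid_coverage > 0 || spec$eyelid_rest > 0) {
    d <- lid_depth(spec)
    vis <- vis & (lid_depth_threshold(p$x, p$y, spec) > d)
  }
  visible_fraction <- mean(vis)
  off <- crop_offset(spec$frame_width, spec$frame_height)
  center <- c(spec$pupil_center[1] - off, spec$pupil_center[2])
  geom <- annotation_geometry(side = spec$frame_height)
  label <- assign_label(center, visible_fraction, geom)
  list(pupil_center = center, visible_fraction = visible_fraction,
       label = label)
}
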