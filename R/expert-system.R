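#' Parameters of the rule-based pupil detector
#'
#' All pixel-denominated defaults refer to the native 520 x 520 cropped
#' frame (`base_side = 520`) and can be rescaled with [es_scale_params()]
#' for reduced-resolution experiments. Intensity thresholds are resolution
#' independent.
#'
#' @param base_side Square side (px) the pixel parameters refer to.
#' @param mask_threshold Fixed threshold masking the unlit region outside
#'   the lens: pixels below it are zeroed (default 80).
#' @param gaussian_kernel Width x height of the anisotropic Gaussian blur
#'   (default 21 x 9; the wider horizontal support smears eyelashes).
#' @param second_threshold_floor,second_threshold_percentile The second
#'   truncation threshold is `max(floor, percentile of the nonzero pixels)`
#'   (defaults 70 and 5); values above it are clipped before the second
#'   contrast stretch, so the darkest pixels span the full dynamic range.
#' @param adaptive_block Side of the local-mean neighborhood of the adaptive
#'   threshold (default 9).
#' @param adaptive_offset Offset subtracted from the local mean (default 5).
#' @param dark_floor Absolute gray level below which a pixel is always
#'   foreground in the adaptive step (default 128, i.e. the lower half of
#'   the stretched range). The local term alone cannot mark the interior of
#'   a dark region wider than the 9-px neighborhood.
#' @param ring_radius Foreground farther than this from the crop center is
#'   discarded (removes the dark field beyond the lens edge; default 245).
#' @param morph_kernel Side of the elliptical structuring element used for
#'   morphological opening then closing (default 21).
#' @param inscribed_radius_range Admissible range (px) of the radius of the
#'   circle inscribed in a candidate's bounding box (default \[20, 150\]).
#' @param darkness_min Minimum inverted mean intensity (255 - mean) of a
#'   candidate on the reference image (default 50); brighter contours are
#'   discarded.
#' @param aspect_ratio_closed Detections with bounding-box height/width
#'   below this are reported as `closed` (eyelid squashing the pupil;
#'   default 0.55).
#' @return An object of class `es_params`.
#' @export
es_params <- function(base_side = 520,
                      mask_threshold = 80,
                      gaussian_kernel = c(21, 9),
                      second_threshold_floor = 70,
                      second_threshold_percentile = 5,
                      adaptive_block = 9,
                      adaptive_offset = 5,
                      dark_floor = 128,
                      ring_radius = 245,
                      morph_kernel = 21,
                      inscribed_radius_range = c(20, 150),
                      darkness_min = 50,
                      aspect_ratio_closed = 0.55) {
  k <- c(gaussian_kernel, adaptive_block, morph_kernel)
  if (any(k < 3) || any(k %% 2 == 0))
    stop("kernel and block sizes must be odd and >= 3")
  if (inscribed_radius_range[1] >= inscribed_radius_range[2])
    stop("inscribed_radius_range must be increasing")
  if (ring_radius <= 0 || ring_radius >= base_side)
    stop("ring_radius must lie in (0, base_side)")
  structure(list(base_side = base_side, mask_threshold = mask_threshold,
                 gaussian_kernel = gaussian_kernel,
                 second_threshold_floor = second_threshold_floor,
                 second_threshold_percentile = second_threshold_percentile,
                 adaptive_block = adaptive_block,
                 adaptive_offset = adaptive_offset,
                 dark_floor = dark_floor,
                 ring_radius = ring_radius,
                 morph_kernel = morph_kernel,
                 inscribed_radius_range = inscribed_radius_range,
                 darkness_min = darkness_min,
                 aspect_ratio_closed = aspect_ratio_closed),
            class = "es_params")
}

# nearest odd integer >= 3
odd_round <- function(x) pmax(3L, as.integer(2 * round((x - 1) / 2) + 1))

#' Rescale detector parameters to a new input side
#'
#' Pixel-denominated parameters are multiplied by `new_side / base_side`;
#' kernel and block sizes are then rounded to the nearest odd integer (at
#' least 3). Intensity thresholds and ratios are unchanged.
#'
#' @param params An [es_params()].
#' @param new_side Target square side in pixels.
#' @return Rescaled `es_params`.
#' @export
es_scale_params <- function(params, new_side) {
  if (new_side <= 0) stop("new_side must be positive")
  s <- new_side / params$base_side
  es_params(base_side = new_side,
            mask_threshold = params$mask_threshold,
            gaussian_kernel = odd_round(params$gaussian_kernel * s),
            second_threshold_floor = params$second_threshold_floor,
            second_threshold_percentile = params$second_threshold_percentile,
            adaptive_block = odd_round(params$adaptive_block * s),
            adaptive_offset = params$adaptive_offset,
            dark_floor = params$dark_floor,
            ring_radius = params$ring_radius * s,
            morph_kernel = odd_round(params$morph_kernel * s),
            inscribed_radius_range = params$inscribed_radius_range * s,
            darkness_min = params$darkness_min,
            aspect_ratio_closed = params$aspect_ratio_closed)
}

# min-max stretch to [0, 255]; constant images map to 0
stretch_01 <- function(img) {
  lo <- min(img); hi <- max(img)
  if (hi <= lo) return(img * 0)
  (img - lo) / (hi - lo) * 255
}

# normalized 1-D Gaussian taps, sigma tied to the kernel size as in the
# usual blur implementations: sigma = 0.3 * ((k - 1)/2 - 1) + 0.8
gaussian_taps <- function(k) {
  sigma <- 0.3 * ((k - 1) * 0.5 - 1) + 0.8
  x <- seq_len(k) - (k + 1) / 2
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

.conv_cache <- new.env(parent = emptyenv())

# logical mask of pixels farther than `radius` from the crop center (cached)
ring_mask <- function(side, radius) {
  key <- paste("ring", side, signif(radius, 10), sep = "|")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  d2 <- (seq_len(side) - 0.5 - side / 2)^2
  m <- outer(d2, d2, "+") > radius^2
  .conv_cache[[key]] <- m
  m
}

# n x n sparse band matrix applying a 1-D convolution with replicate
# boundary handling; cached, since the suite reuses a handful of kernels
conv_band <- function(n, taps) {
  key <- paste(n, paste(signif(taps, 10), collapse = ","), sep = "|")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- length(taps)
  r <- (k - 1) / 2
  i <- rep(seq_len(n), each = k)
  j <- pmin(pmax(i + rep(-r:r, times = n), 1), n)
  B <- Matrix::sparseMatrix(i = i, j = j, x = rep(taps, times = n),
                            dims = c(n, n))
  .conv_cache[[key]] <- B
  B
}

# separable 2-D convolution with replicate boundary; ky along rows (y),
# kx along columns (x)
sep_convolve <- function(img, kx, ky) {
  out <- conv_band(nrow(img), ky) %*% img
  out <- out %*% Matrix::t(conv_band(ncol(img), kx))
  as.matrix(out)
}

#' Preprocess a frame into a pupil-candidate mask
#'
#' Runs the detector's image-processing chain: (1) crop to the central
#' square; (2) zero pixels below `mask_threshold` (the unlit field outside
#' the lens) and contrast-stretch; (3) anisotropic Gaussian blur; (4) clip
#' above `max(floor, 5th percentile of the nonzero pixels)` and stretch
#' again — this image is returned as the scoring reference; (5) adaptive
#' local-mean binarization marking dark pixels as foreground; (6) discard
#' foreground beyond `ring_radius` from the crop center (the lens edge and
#' the field beyond it); (7) morphological opening then closing with an
#' elliptical element.
#'
#' @param frame Integer frame matrix (native 772 x 520 or already square).
#' @param params An [es_params()]; its pixel parameters must match the
#'   cropped frame side (see [es_scale_params()]).
#' @return List with `mask` (0/1 matrix) and `reference` (stretched
#'   grayscale matrix in 0..255).
#' @export
es_preprocess <- function(frame, params = es_params()) {
  frame <- as_frame(frame)
  img <- crop_square(frame)
  side <- nrow(img)
  img <- matrix(as.numeric(img), side, side)

  # (2) suppress the unlit field, stretch
  img[img < params$mask_threshold] <- 0
  img <- stretch_01(img)

  # (3) anisotropic blur (wide horizontal support smears lashes)
  img <- sep_convolve(img,
                      kx = gaussian_taps(params$gaussian_kernel[1]),
                      ky = gaussian_taps(params$gaussian_kernel[2]))

  # (4) clip bright values so the darkest pixels span the full range
  nz <- img[img > 0]
  thr <- params$second_threshold_floor
  if (length(nz))
    thr <- max(thr, stats::quantile(
      nz, params$second_threshold_percentile / 100, names = FALSE))
  img[img > thr] <- thr
  reference <- stretch_01(img)

  # (5) dark-pixel binarization: below the local mean by more than the
  # offset, or below the absolute dark floor (flat dark interiors)
  box <- rep(1 / params$adaptive_block, params$adaptive_block)
  local_mean <- sep_convolve(reference, kx = box, ky = box)
  mask <- reference < local_mean - params$adaptive_offset
  # absolute dark floor only applies when the frame has contrast at all
  # (after the stretches a non-degenerate frame spans up to 255)
  if (max(reference) > 0)
    mask <- mask | (reference < params$dark_floor)

  # (6) remove foreground beyond the lens ring
  mask[ring_mask(side, params$ring_radius)] <- FALSE

  # (7) opening then closing with an elliptical element
  brush <- EBImage::makeBrush(params$morph_kernel, shape = "disc")
  m <- EBImage::closing(EBImage::opening(mask * 1, brush), brush)

  list(mask = matrix(as.numeric(m > 0), side, side), reference = reference)
}

# convex-hull helpers ------------------------------------------------------

# shoelace area of polygon given as matrix of (x, y) rows (counterclockwise
# or clockwise; absolute value taken)
polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

polygon_perimeter <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(sqrt((p[j, 1] - p[, 1])^2 + (p[j, 2] - p[, 2])^2))
}

# logical matrix of pixels (restricted to rows ii, cols jj) whose centers
# lie inside the convex polygon `p`
convex_raster <- function(p, ii, jj) {
  px <- matrix(jj - 0.5, length(ii), length(jj), byrow = TRUE)
  py <- matrix(ii - 0.5, length(ii), length(jj))
  inside <- matrix(TRUE, length(ii), length(jj))
  n <- nrow(p)
  # ensure counterclockwise orientation (in image coords, consistent sign)
  j2 <- c(2:n, 1)
  orient <- sum(p[, 1] * p[j2, 2] - p[j2, 1] * p[, 2])
  if (orient < 0) { p <- p[n:1, , drop = FALSE]; j2 <- c(2:n, 1) }
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    ex <- p[k2, 1] - p[k, 1]; ey <- p[k2, 2] - p[k, 2]
    cross <- ex * (py - p[k, 2]) - ey * (px - p[k, 1])
    inside <- inside & (cross >= -1e-9)
  }
  inside
}

#' Extract and filter pupil candidates from a binary mask
#'
#' Labels the connected foreground components, takes the convex hull of
#' each, and keeps a candidate iff the radius of the circle inscribed in its
#' bounding box lies in `inscribed_radius_range` and its inverted mean
#' intensity on the reference image exceeds `darkness_min` (discarding
#' too-small, too-large and too-bright contours). Each retained candidate
#' carries its hull, bounding box, centroid, circularity
#' (4 * pi * area / perimeter^2 of the hull), normalized darkness and hull
#' area, from which the best candidate is scored.
#'
#' @param mask Binary (0/1) matrix from [es_preprocess()].
#' @param reference Reference grayscale matrix from [es_preprocess()].
#' @param params An [es_params()].
#' @return A list of candidate detections (possibly empty); each is a list
#'   with `center`, `bbox` (xmin, xmax, ymin, ymax), `hull`, `circularity`,
#'   `darkness`, `area`.
#' @export
es_find_candidates <- function(mask, reference, params = es_params()) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0) return(list())
  side <- nrow(mask)
  scale <- side / params$base_side  # params already match side normally
  out <- list()
  for (comp in seq_len(n)) {
    idx <- which(lab == comp)
    rows <- ((idx - 1) %% side) + 1
    cols <- ((idx - 1) %/% side) + 1
    pts <- cbind(x = cols - 0.5, y = rows - 0.5)
    h <- grDevices::chull(pts)
    hull <- pts[h, , drop = FALSE]
    if (nrow(hull) < 3) next
    bw <- diff(range(cols)) + 1
    bh <- diff(range(rows)) + 1
    inscribed <- min(bw, bh) / 2
    if (inscribed < params$inscribed_radius_range[1] ||
        inscribed > params$inscribed_radius_range[2]) next
    ii <- min(rows):max(rows)
    jj <- min(cols):max(cols)
    inhull <- convex_raster(hull, ii, jj)
    vals <- reference[ii, jj, drop = FALSE][inhull]
    if (!length(vals)) next
    darkness_raw <- 255 - mean(vals)
    if (darkness_raw <= params$darkness_min) next
    area <- polygon_area(hull)
    per <- polygon_perimeter(hull)
    circ <- min(1, 4 * pi * area / per^2)
    # centroid of the filled hull
    cx <- mean(matrix(jj - 0.5, length(ii), length(jj), byrow = TRUE)[inhull])
    cy <- mean(matrix(ii - 0.5, length(ii), length(jj))[inhull])
    out[[length(out) + 1]] <- list(
      center = c(cx, cy),
      bbox = c(xmin = min(cols) - 1, xmax = max(cols),
               ymin = min(rows) - 1, ymax = max(rows)),
      hull = hull, circularity = circ,
      darkness = darkness_raw / 255, area = area)
  }
  out
}

#' Select the best pupil candidate
#'
#' Scores each candidate as the equal-weight sum of min-max normalized
#' circularity, darkness and area (the most circular, darkest and biggest
#' contour wins; a single candidate scores 3). Ties are broken by larger
#' area, then by the leftmost-topmost center.
#'
#' @param candidates List from [es_find_candidates()].
#' @return The winning candidate (with a `score` field) or `NULL`.
#' @export
es_select <- function(candidates) {
  if (!length(candidates)) return(NULL)
  norm01 <- function(v) {
    if (max(v) - min(v) < 1e-12) rep(1, length(v))
    else (v - min(v)) / (max(v) - min(v))
  }
  circ <- norm01(vapply(candidates, `[[`, numeric(1), "circularity"))
  dark <- norm01(vapply(candidates, `[[`, numeric(1), "darkness"))
  area_n <- norm01(vapply(candidates, `[[`, numeric(1), "area"))
  score <- circ + dark + area_n
  area <- vapply(candidates, `[[`, numeric(1), "area")
  cx <- vapply(candidates, function(c) c$center[1], numeric(1))
  cy <- vapply(candidates, function(c) c$center[2], numeric(1))
  ord <- order(-score, -area, cx, cy)
  best <- candidates[[ord[1]]]
  best$score <- score[ord[1]]
  best
}

#' Classify a frame with the rule-based detector
#'
#' Runs [es_preprocess()], [es_find_candidates()] and [es_select()]. With no
#' surviving candidate the frame is `closed`. A detection whose bounding-box
#' height/width ratio falls below `aspect_ratio_closed` is also `closed`
#' (the eyelid squashes the visible pupil). Otherwise the label is the
#' annotation-geometry region of the detected center: `correct` in the
#' central region, else the gaze direction.
#'
#' @param frame Integer frame matrix (native wide or square).
#' @param params An [es_params()] matching the cropped side.
#' @param geometry An [annotation_geometry()]; defaults to the geometry of
#'   the cropped side.
#' @return List with `label` and `detection` (`NULL` when no pupil found).
#' @export
es_classify_frame <- function(frame, params = es_params(), geometry = NULL) {
  pre <- es_preprocess(frame, params)
  side <- nrow(pre$mask)
  if (is.null(geometry))
    geometry <- scale_geometry(annotation_geometry(), side)
  best <- es_select(es_find_candidates(pre$mask, pre$reference, params))
  if (is.null(best)) return(list(label = "closed", detection = NULL))
  bw <- best$bbox["xmax"] - best$bbox["xmin"]
  bh <- best$bbox["ymax"] - best$bbox["ymin"]
  if (bh / bw < params$aspect_ratio_closed)
    return(list(label = "closed", detection = best))
  region <- region_of(pmin(pmax(best$center, 0), geometry$side), geometry)
  label <- if (region == "central") "correct" else region
  list(label = label, detection = best)
}
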