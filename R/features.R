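#' Resize a frame by area averaging
#'
#' Exact area-weighted downsampling (each output pixel is the mean of the
#' input area it covers), implemented as two banded weight-matrix products.
#' Area averaging avoids the aliasing a nearest-neighbor or bilinear
#' reduction of a 520-px frame to 32 px would introduce.
#'
#' @param frame Numeric or integer matrix.
#' @param out_h,out_w Output size in pixels.
#' @return Numeric matrix `out_h` x `out_w` on the input intensity scale.
#' @export
resize_area <- function(frame, out_h, out_w = out_h) {
  stopifnot(out_h >= 1, out_w >= 1)
  wmat <- function(n_out, n_in) {
    r <- n_in / n_out
    W <- matrix(0, n_out, n_in)
    for (i in seq_len(n_out)) {
      lo <- (i - 1) * r; hi <- i * r
      j <- floor(lo):min(ceiling(hi) - 1, n_in - 1)
      overlap <- pmin(hi, j + 1) - pmax(lo, j)
      W[i, j + 1] <- overlap / r
    }
    W
  }
  wmat(out_h, nrow(frame)) %*%
    matrix(as.numeric(frame), nrow(frame), ncol(frame)) %*%
    t(wmat(out_w, ncol(frame)))
}

#' Unrolled-pixel feature vector
#'
#' Resizes the frame to `side` x `side` (area averaging), scales intensities
#' by 1/255 into \[0, 1\], and flattens row-major into a vector of length
#' `side^2` — the simplest image representation fed to the classifiers.
#'
#' @param frame Frame matrix; non-square frames are first cropped to the
#'   central square, as in the rest of the pipeline.
#' @param side Feature input side in pixels (e.g. 32 giving 1024 features).
#' @return Numeric vector of length `side^2` with entries in \[0, 1\].
#' @export
unroll_normalize <- function(frame, side = 32) {
  img <- resize_area(crop_square(frame), side, side)
  as.numeric(t(img)) / 255
}

#' Histogram-of-oriented-gradients features
#'
#' Unsigned gradient orientations (0--180 degrees) are histogrammed into
#' `orientations` bins over non-overlapping `cell` x `cell` pixel cells,
#' each cell (1 x 1 cells per block) L2-normalized independently. Gradients
#' are central differences (one-sided at the borders). The vector length is
#' `orientations * (side/cell)^2`; a constant image yields all zeros.
#'
#' @param frame Frame matrix; resized to `side` first.
#' @param side Feature input side; must be divisible by `cell`.
#' @param orientations Number of orientation bins (default 8).
#' @param cell Cell side in pixels (default 4).
#' @return Numeric feature vector.
#' @export
hog_features <- function(frame, side = 32, orientations = 8, cell = 4) {
  if (side %% cell != 0)
    stop("side must be divisible by the cell size")
  img <- resize_area(crop_square(frame), side, side) / 255
  gx <- img; gy <- img
  gx[, 2:(side - 1)] <- (img[, 3:side] - img[, 1:(side - 2)]) / 2
  gx[, 1] <- img[, 2] - img[, 1]; gx[, side] <- img[, side] - img[, side - 1]
  gy[2:(side - 1), ] <- (img[3:side, ] - img[1:(side - 2), ]) / 2
  gy[1, ] <- img[2, ] - img[1, ]; gy[side, ] <- img[side, ] - img[side - 1, ]
  mag <- sqrt(gx^2 + gy^2)
  theta <- atan2(gy, gx) %% pi  # unsigned orientation in [0, pi)
  bin <- pmin(floor(theta / (pi / orientations)), orientations - 1)
  ncell <- side / cell
  # accumulate magnitude into (cell, orientation) slots in one pass
  ci <- matrix(rep((seq_len(side) - 1L) %/% cell, side), side, side)  # row cell
  cj <- t(ci)
  slot <- (ci * ncell + cj) * orientations + bin + 1
  acc <- numeric(orientations * ncell^2)
  sums <- rowsum(as.numeric(mag), as.integer(slot))
  acc[as.integer(rownames(sums))] <- sums
  h <- matrix(acc, nrow = orientations)      # one column per cell
  nrm <- sqrt(colSums(h^2))
  nrm[nrm < 1e-12] <- 1
  as.numeric(sweep(h, 2, nrm, "/"))
}

#' Uniform local-binary-pattern histogram features
#'
#' For every pixel whose sampling circle fits in the image, `points`
#' neighbors on a circle of the given `radius` are bilinearly interpolated
#' and compared (>=) to the center. Codes whose circular bit sequence has at
#' most two 0/1 transitions ("uniform" patterns) are binned by their number
#' of set bits (`points + 1` bins); all other codes share one extra bin. The
#' `points + 2`-bin histogram is normalized to sum 1. A constant image puts
#' all mass in the all-ones uniform bin.
#'
#' @param frame Frame matrix; resized to `side` first.
#' @param side Feature input side; must exceed `2 * radius + 2`.
#' @param radius Circle radius in pixels (default 5).
#' @param points Number of sampling points on the circle (default 100).
#' @return Numeric vector of length `points + 2` summing to 1.
#' @export
lbp_features <- function(frame, side = 32, radius = 5, points = 100) {
  if (side <= 2 * radius + 2)
    stop("image side too small for the requested LBP radius")
  img <- resize_area(crop_square(frame), side, side)
  g <- lbp_geometry(side, radius, points)
  center <- img[g$center_idx]
  # one sparse product interpolates all neighbors of all centers
  v <- matrix(g$interp %*% as.numeric(img), ncol = points)
  bits <- v >= center - 1e-9   # tolerance: exact ties count as >=
  transitions <- rowSums(bits != bits[, c(2:points, 1), drop = FALSE])
  ones <- rowSums(bits)
  code <- ifelse(transitions <= 2, ones, points + 1)
  h <- tabulate(code + 1L, nbins = points + 2)
  h / sum(h)
}

# cached sampling geometry: linear indices of the centers and a sparse
# bilinear-interpolation matrix mapping vec(img) to all (center, point)
# neighbor values
lbp_geometry <- function(side, radius, points) {
  key <- paste("lbp", side, radius, points, sep = "|")
  hit <- .feature_cache[[key]]
  if (!is.null(hit)) return(hit)
  rng <- (radius + 1):(side - radius)   # centers with a full circle inside
  cy <- rep(rng, times = length(rng))   # row
  cx <- rep(rng, each = length(rng))    # col
  n <- length(cy)
  rows <- integer(0); cols <- integer(0); wts <- numeric(0)
  for (p in seq_len(points)) {
    ang <- 2 * pi * (p - 1) / points
    sx <- cx + radius * cos(ang)
    sy <- cy - radius * sin(ang)
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    x1 <- pmin(x0 + 1, side); y1 <- pmin(y0 + 1, side)
    r <- (p - 1) * n + seq_len(n)
    rows <- c(rows, r, r, r, r)
    cols <- c(cols,
              (x0 - 1) * side + y0, (x1 - 1) * side + y0,
              (x0 - 1) * side + y1, (x1 - 1) * side + y1)
    wts <- c(wts, (1 - fx) * (1 - fy), fx * (1 - fy),
             (1 - fx) * fy, fx * fy)
  }
  out <- list(center_idx = (cx - 1) * side + cy,
              interp = Matrix::sparseMatrix(i = rows, j = cols, x = wts,
                                            dims = c(n * points, side^2)))
  .feature_cache[[key]] <- out
  out
}

.feature_cache <- new.env(parent = emptyenv())

#' Compute a feature matrix for a list of frames
#'
#' @param frames List of frame matrices.
#' @param kind One of `"unrolled"`, `"hog"`, `"lbp"`.
#' @param side Feature input side in pixels.
#' @param ... Passed to the feature function.
#' @return Numeric matrix, one row per frame.
#' @export
feature_matrix <- function(frames, kind = c("unrolled", "hog", "lbp"),
                           side = 32, ...) {
  kind <- match.arg(kind)
  fn <- switch(kind,
               unrolled = function(f) unroll_normalize(f, side),
               hog = function(f) hog_features(f, side, ...),
               lbp = function(f) lbp_features(f, side, ...))
  t(vapply(frames, fn, fn(frames[[1]])))
}
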