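#' Annotation geometry for the square eye-frame crop
#'
#' Describes the visual-aid geometry used to turn a pupil position into one of
#' six frame-quality labels: a square crop of edge `side`, its two diagonals
#' (partitioning the square into up/right/down/left triangles), and a central
#' circular region of radius `central_radius` around the optical axis. A pupil
#' centered inside the central region qualifies the frame as usable for
#' pupillary-light-reflex measurement; the defaults (520 px crop, 69 px
#' radius) match the instrument's cropped sensor frames.
#'
#' Coordinates are continuous image coordinates: origin at the top-left
#' corner, x rightward, y downward; the pixel at row i, column j (1-based)
#' has center (j - 0.5, i - 0.5). The geometry center defaults to the crop
#' center (side/2, side/2).
#'
#' @param side Edge of the square crop in pixels.
#' @param central_radius Radius of the central region in pixels.
#' @param center Numeric length-2, geometry center (x, y); defaults to the
#'   crop center.
#' @return An object of class `annotation_geometry`.
#' @examples
#' g <- annotation_geometry()
#' region_of(c(260, 100), g)  # "up"
#' @export
annotation_geometry <- function(side = 520, central_radius = 69 * side / 520,
                                center = c(side / 2, side / 2)) {
  stopifnot(is.numeric(side), length(side) == 1, side > 0)
  if (!(central_radius > 0 && central_radius < side / 2))
    stop("central_radius must lie in (0, side/2)")
  center <- as.numeric(center)
  if (length(center) != 2 || any(center <= 0) || any(center >= side))
    stop("center must lie strictly inside the square")
  structure(list(side = side, central_radius = central_radius,
                 center = center),
            class = "annotation_geometry")
}

#' @export
print.annotation_geometry <- function(x, ...) {
  cat(sprintf("annotation geometry: %g x %g crop, center (%g, %g), central radius %g px\n",
              x$side, x$side, x$center[1], x$center[2], x$central_radius))
  invisible(x)
}

#' The six admissible frame labels
#'
#' @return Character vector of the six labels in canonical order.
#' @export
eye_labels <- function() c("correct", "closed", "right", "down", "left", "up")

#' Region of the crop containing a point
#'
#' Maps a point to `"central"` (Euclidean distance to the geometry center at
#' most `central_radius`, edge included) or to the diagonal-bounded triangle
#' it falls into: `"up"`, `"right"`, `"down"` or `"left"`. Points exactly on
#' a diagonal are resolved by the fixed priority up > right > down > left so
#' the mapping is a deterministic partition.
#'
#' @param point Numeric length-2 (x, y), inside the square.
#' @param geometry An [annotation_geometry()].
#' @return One of `"central"`, `"up"`, `"right"`, `"down"`, `"left"`.
#' @export
region_of <- function(point, geometry = annotation_geometry()) {
  point <- as.numeric(point)
  stopifnot(length(point) == 2)
  if (any(point < 0) || any(point > geometry$side))
    stop("point lies outside the crop square")
  dx <- point[1] - geometry$center[1]
  dy <- point[2] - geometry$center[2]
  if (sqrt(dx * dx + dy * dy) <= geometry$central_radius) return("central")
  # strict triangle interiors, then the diagonal tie-break order
  if (dy < -abs(dx)) return("up")
  if (dx > abs(dy)) return("right")
  if (dy > abs(dx)) return("down")
  if (dx < -abs(dy)) return("left")
  if (dy <= 0) return("up")      # on a diagonal, upper half
  if (dx >= 0) return("right")   # on a diagonal, right half
  "down"
}

#' Assign one of six quality labels to a pupil observation
#'
#' Implements the deterministic annotation rules. With the pupil center
#' inside the central region, the frame is `correct` when more than 90% of
#' the pupil area is visible and `closed` otherwise (the eyelid covers more
#' than 10%). With the center outside the central region, the frame is
#' `closed` when less than 15% of the pupil is visible, and otherwise takes
#' the directional label of the triangle containing the center. An absent
#' center (`NULL` or `NA`) means the pupil is not detectable and the frame
#' is `closed`.
#'
#' Boundary conventions: exactly 90% visible with the center inside resolves
#' to `closed` (borderline frames are discarded); exactly 15% visible with
#' the center outside resolves to the directional label.
#'
#' @param center Numeric length-2 pupil center (x, y), or `NULL`/`NA` when
#'   the pupil is not detectable.
#' @param visible_fraction Fraction of the pupil area visible, in \[0, 1\].
#' @param geometry An [annotation_geometry()].
#' @return One of the six labels of [eye_labels()].
#' @examples
#' assign_label(c(260, 260), 1.0)    # "correct"
#' assign_label(c(400, 260), 0.5)    # "right"
#' assign_label(NULL, 0)             # "closed"
#' @export
assign_label <- function(center, visible_fraction,
                         geometry = annotation_geometry()) {
  stopifnot(is.numeric(visible_fraction), length(visible_fraction) == 1,
            visible_fraction >= 0, visible_fraction <= 1)
  if (is.null(center) || all(is.na(center))) return("closed")
  region <- region_of(center, geometry)
  if (region == "central") {
    if (visible_fraction > 0.90) "correct" else "closed"
  } else {
    if (visible_fraction >= 0.15) region else "closed"
  }
}

#' Rescale an annotation geometry to a new crop size
#'
#' All pixel-denominated fields (side, center, central radius) are scaled by
#' `new_side / side`, supporting experiments at reduced input resolutions.
#'
#' @param geometry An [annotation_geometry()].
#' @param new_side New crop edge in pixels (> 0).
#' @return The rescaled `annotation_geometry`.
#' @export
scale_geometry <- function(geometry, new_side) {
  stopifnot(is.numeric(new_side), length(new_side) == 1)
  if (new_side <= 0) stop("new_side must be positive")
  s <- new_side / geometry$side
  annotation_geometry(side = new_side,
                      central_radius = geometry$central_radius * s,
                      center = geometry$center * s)
}
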