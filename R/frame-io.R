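#' Eye frames as 8-bit grayscale matrices
#'
#' Throughout the package a frame is a plain integer matrix with `dim = c(h,
#' w)` (rows are image rows, i.e. y; columns are x) holding intensities in
#' 0..255. `as_frame()` validates and coerces; [read_frame()] /
#' [write_frame()] convert to and from 8-bit grayscale PNG.
#'
#' @param x Numeric or integer matrix.
#' @return Integer matrix with values in 0..255.
#' @export
as_frame <- function(x) {
  if (!is.matrix(x)) stop("a frame must be a matrix")
  if (any(is.na(x))) stop("frame contains NA pixels")
  if (min(x) < 0 || max(x) > 255) stop("frame intensities must lie in [0, 255]")
  storage.mode(x) <- "integer"
  x
}

#' Read an 8-bit grayscale eye frame from PNG
#'
#' @param path Path to a PNG file.
#' @return Integer matrix (h x w) with values 0..255; color images are
#'   reduced to their first channel.
#' @export
read_frame <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  as_frame(round(a * 255))
}

#' Write an eye frame to an 8-bit grayscale PNG
#'
#' @param frame Integer matrix with values 0..255.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  frame <- as_frame(frame)
  png::writePNG(frame / 255, target = path)
  invisible(path)
}

# Crop a native (wide) frame to its central square; frames already square
# pass through. The black side borders produced by the sensor are symmetric,
# so the crop box is centered horizontally.
crop_square <- function(frame) {
  h <- nrow(frame); w <- ncol(frame)
  if (w == h) return(frame)
  if (w < h) stop("frame is taller than wide; expected landscape or square")
  x0 <- floor((w - h) / 2)
  frame[, (x0 + 1):(x0 + h), drop = FALSE]
}

# x offset (in px) removed from native coordinates by crop_square()
crop_offset <- function(width, height) {
  if (width == height) 0 else floor((width - height) / 2)
}
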