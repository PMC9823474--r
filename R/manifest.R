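#' Read and write dataset manifests
#'
#' A manifest is a CSV table with one row per frame and columns
#' `path,label,cx,cy,visible_fraction,seed`: the image file (relative to the
#' manifest), its six-class label, the ground-truth pupil center in cropped
#' coordinates, the visible pupil-area fraction, and the per-frame render
#' seed. `read_manifest()` validates the header and labels and reports the
#' offending line on malformed rows; the pair round-trips losslessly.
#'
#' @param path CSV file path.
#' @return `read_manifest()`: a data.frame with the columns above.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("path", "label", "cx", "cy", "visible_fraction", "seed")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols))
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  bad <- which(!(m$label %in% eye_labels()))
  if (length(bad))
    stop("unknown label '", m$label[bad[1]], "' at manifest line ",
         bad[1] + 1L)
  numeric_cols <- c("cx", "cy", "visible_fraction", "seed")
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(m[[col]]))
    bad <- which(is.na(v) & nzchar(as.character(m[[col]])))
    if (length(bad))
      stop("malformed value in column '", col, "' at manifest line ",
           bad[1] + 1L)
    m[[col]] <- v
  }
  m[required]
}

#' @rdname read_manifest
#' @param manifest Data.frame as returned by [generate_dataset()].
#' @export
write_manifest <- function(manifest, path) {
  required <- c("path", "label", "cx", "cy", "visible_fraction", "seed")
  stopifnot(all(required %in% names(manifest)))
  utils::write.csv(manifest[required], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
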