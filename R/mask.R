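#' Binary segmentation mask
#'
#' A per-item pixel mask aligned to a depth map: `TRUE` where the item (plate,
#' rice, chicken, ...) covers the pixel. Masks must have the same shape as the
#' depth map they are applied to.
#'
#' @param values Logical matrix (or coercible numeric: nonzero = TRUE).
#' @param label Item class string, e.g. `"plate"` or `"rice"`.
#' @param frame_id Identifier of the originating frame.
#' @return An object of class `trayvol_mask`.
#' @export
binary_mask <- function(values, label = "item", frame_id = "frame") {
  if (is.numeric(values)) values <- values != 0
  if (!is.matrix(values) || !is.logical(values)) {
    abort("`values` must be a logical matrix.")
  }
  structure(
    list(values = values, label = as.character(label),
         frame_id = as.character(frame_id)),
    class = "trayvol_mask"
  )
}

#' @export
print.trayvol_mask <- function(x, ...) {
  cat(sprintf("<mask '%s'> %d x %d px, %d set (frame %s)\n",
              x$label, nrow(x$values), ncol(x$values), sum(x$values),
              x$frame_id))
  invisible(x)
}

n_pixels_set <- function(mask) sum(mask$values)

check_same_shape <- function(a, b, what = "rasters") {
  da <- dim(if (inherits(a, "trayvol_mask") ||
                inherits(a, "trayvol_depth_map") ||
                inherits(a, "trayvol_corrected_depth")) a$values else a)
  db <- dim(if (inherits(b, "trayvol_mask") ||
                inherits(b, "trayvol_depth_map") ||
                inherits(b, "trayvol_corrected_depth")) b$values else b)
  if (!identical(da, db)) {
    abort(sprintf("%s must have the same shape (%s vs %s).",
                  what, paste(da, collapse = "x"), paste(db, collapse = "x")))
  }
  invisible(TRUE)
}

#' Read and write mask PNG files
#'
#' Masks are 8-bit single-channel PNG, nonzero = inside. The item label is
#' taken from the file name (`mask_<label>.png`) unless given explicitly.
#'
#' @param path PNG file path.
#' @param mask A [binary_mask()] to write.
#' @param label,frame_id Metadata attached on read.
#' @return `read_mask_png()` returns a mask; `write_mask_png()` returns `path`
#'   invisibly.
#' @export
read_mask_png <- function(path, label = NULL, frame_id = "frame") {
  if (!file.exists(path)) abort(sprintf("mask not found: %s", path))
  vals <- png::readPNG(path)
  if (length(dim(vals)) == 3) vals <- vals[, , 1]
  if (is.null(label)) {
    # file naming convention: <frame>_mask_<label>.png or mask_<label>.png
    label <- sub("^(.*_)?mask_", "", sub("\\.png$", "", basename(path)))
  }
  binary_mask(vals > 0, label = label, frame_id = frame_id)
}

#' @rdname read_mask_png
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "trayvol_mask"))
  png::writePNG(mask$values * 1.0, path)
  invisible(path)
}

# Morphological erosion with out-of-image treated as background. EBImage's
# erode() replicates the border (outside counts as foreground), so pad first.
erode_mask <- function(values, radius) {
  stopifnot(radius >= 1)
  h <- nrow(values); w <- ncol(values)
  padded <- matrix(0L, h + 2L * radius, w + 2L * radius)
  padded[(radius + 1L):(radius + h), (radius + 1L):(radius + w)] <-
    values * 1L
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "box")
  eroded <- EBImage::erode(padded, brush)
  eroded[(radius + 1L):(radius + h), (radius + 1L):(radius + w)] > 0
}
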