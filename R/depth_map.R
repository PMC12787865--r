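#' Depth map container
#'
#' A depth map is a dense 2-D raster of relative depth values as produced by a
#' monocular depth model: dimensionless, typically normalized to \[0, 1\], and
#' only meaningful up to an unknown monotone scale. Coordinates follow the
#' image convention: `x` is the 0-based column index, `y` the 0-based row
#' index, origin at the top-left pixel.
#'
#' Because a relative depth model does not declare whether larger values mean
#' nearer to the camera, every depth map carries an explicit `polarity`:
#' `"higher_is_elevated"` means larger values are nearer to the overhead
#' camera, i.e. higher above the tray. All geometry in this package (base-plane
#' correction, positive-part volume integration) assumes that polarity; use
#' [normalize_polarity()] to convert.
#'
#' @param values Numeric matrix of finite depth values (rows = y, cols = x).
#' @param pixel_area Area covered by one pixel, in squared arbitrary length
#'   units. Scales every integrated volume linearly. Default 1.
#' @param polarity Either `"higher_is_elevated"` or `"lower_is_elevated"`.
#'
#' @return An object of class `trayvol_depth_map`.
#' @export
#' @examples
#' d <- depth_map(matrix(0.5, 8, 8))
#' d$pixel_area
depth_map <- function(values,
                      pixel_area = 1,
                      polarity = c("higher_is_elevated", "lower_is_elevated")) {
  polarity <- match.arg(polarity)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (!all(is.finite(values))) abort("depth values must all be finite.")
  if (!is.numeric(pixel_area) || length(pixel_area) != 1 || pixel_area <= 0) {
    abort("`pixel_area` must be a single positive number.")
  }
  structure(
    list(
      values = values,
      height = nrow(values),
      width = ncol(values),
      pixel_area = as.numeric(pixel_area),
      polarity = polarity
    ),
    class = "trayvol_depth_map"
  )
}

#' @export
print.trayvol_depth_map <- function(x, ...) {
  cat(sprintf(
    "<depth map> %d x %d px, pixel_area = %g, polarity = %s, range [%.4g, %.4g]\n",
    x$height, x$width, x$pixel_area, x$polarity,
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Normalize depth polarity
#'
#' Flips a depth map so that larger values mean higher elevation (or the
#' reverse). Flipping replaces every value `v` by `max(values) - v`, which
#' preserves the relative-depth ordering and keeps the result non-negative.
#' A map already in the target polarity is returned unchanged.
#'
#' @param depth A [depth_map()].
#' @param target Desired polarity.
#' @return A depth map with `polarity == target`.
#' @export
normalize_polarity <- function(depth,
                               target = c("higher_is_elevated",
                                          "lower_is_elevated")) {
  target <- match.arg(target)
  stopifnot(inherits(depth, "trayvol_depth_map"))
  if (depth$polarity == target) return(depth)
  depth_map(max(depth$values) - depth$values,
            pixel_area = depth$pixel_area, polarity = target)
}

#' Read and write depth rasters
#'
#' Depth rasters are stored as single-channel 32-bit float TIFF. Because TIFF
#' float storage is only well-defined on \[0, 1\], values are min-max
#' normalized on write; the JSON sidecar (`<file>.json`) records the `scale`
#' and `offset` needed to restore the original values, along with
#' `pixel_area` and `polarity`. Absent a sidecar, the raw values are used
#' with defaults.
#'
#' @param path File path of the TIFF raster.
#' @param depth A [depth_map()] to write.
#' @return `read_depth_raster()` returns a depth map; `write_depth_raster()`
#'   returns `path` invisibly.
#' @export
read_depth_raster <- function(path) {
  if (!file.exists(path)) abort(sprintf("depth raster not found: %s", path))
  vals <- tiff::readTIFF(path)
  if (length(dim(vals)) == 3) vals <- vals[, , 1]
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  vals <- vals * (meta$scale %||% 1) + (meta$offset %||% 0)
  depth_map(vals,
            pixel_area = meta$pixel_area %||% 1,
            polarity = meta$polarity %||% "higher_is_elevated")
}

#' @rdname read_depth_raster
#' @export
write_depth_raster <- function(depth, path) {
  stopifnot(inherits(depth, "trayvol_depth_map"))
  offset <- min(depth$values)
  scale <- max(depth$values) - offset
  if (scale == 0) scale <- 1
  tiff::writeTIFF((depth$values - offset) / scale, path,
                  bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(
    list(pixel_area = depth$pixel_area, polarity = depth$polarity,
         scale = scale, offset = offset),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
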