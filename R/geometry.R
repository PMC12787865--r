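#' Base plane model
#'
#' The fitted base plane `z = a*x + b*y + c` used to remove the global
#' perspective tilt that monocular depth models impose on a flat tray. `x` is
#' the 0-based column index and `y` the 0-based row index; `a` and `b` are
#' slopes per pixel and `c` an offset in depth units.
#'
#' @param a,b,c Plane coefficients.
#' @param n_points Number of rim samples used in the fit.
#' @param rms_residual Root-mean-square residual of the fit, depth units.
#' @return An object of class `trayvol_plane`.
#' @export
plane_model <- function(a, b, c, n_points = NA_integer_,
                        rms_residual = NA_real_) {
  coefs <- c(a = a, b = b, c = c)
  if (!all(is.finite(coefs))) abort("plane coefficients must be finite.")
  structure(
    list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
         n_points = as.integer(n_points),
         rms_residual = as.numeric(rms_residual)),
    class = "trayvol_plane"
  )
}

#' @export
print.trayvol_plane <- function(x, ...) {
  cat(sprintf("<base plane> z = %.6g*x + %.6g*y + %.6g  (n = %s, rms = %.3g)\n",
              x$a, x$b, x$c,
              ifelse(is.na(x$n_points), "?", x$n_points), x$rms_residual))
  invisible(x)
}

#' @method tidy trayvol_plane
#' @export
tidy.trayvol_plane <- function(x, ...) {
  tibble(term = c("a", "b", "c"), estimate = c(x$a, x$b, x$c))
}

#' @method glance trayvol_plane
#' @export
glance.trayvol_plane <- function(x, ...) {
  tibble(n_points = x$n_points, rms_residual = x$rms_residual)
}

# Evaluate a*x + b*y + c on the pixel grid (0-based x = col, y = row).
eval_plane <- function(plane, height, width) {
  outer(seq_len(height) - 1, seq_len(width) - 1,
        function(y, x) plane$a * x + plane$b * y + plane$c)
}

#' Sample the plate rim band
#'
#' The outer edge of the plate is assumed flat and serves as support for the
#' base-plane fit. The rim band is the annulus of width `band_width` just
#' inside the plate-mask boundary: the mask minus its morphological erosion by
#' `band_width` pixels. Pixels covered by any exclusion mask (food items
#' spilling over the rim) are removed so they cannot bias the fit.
#'
#' Points are returned in deterministic row-major order (by `y`, then `x`).
#' If the band holds more than `max_points` pixels, a deterministic uniform
#' stride subsample bounds the fitting cost without randomness.
#'
#' @param plate_mask Plate [binary_mask()].
#' @param band_width Band width in pixels (>= 1). Default 5.
#' @param exclusion_masks List of masks whose pixels are excluded.
#' @param max_points Subsampling cap; default 5000.
#' @return A tibble with integer columns `x`, `y` (0-based pixel coordinates).
#' @export
#' @examples
#' m <- matrix(FALSE, 20, 20); m[6:15, 6:15] <- TRUE
#' nrow(sample_rim(binary_mask(m, "plate"), band_width = 2))  # 64
sample_rim <- function(plate_mask, band_width = 5, exclusion_masks = list(),
                       max_points = 5000) {
  stopifnot(inherits(plate_mask, "trayvol_mask"))
  if (band_width < 1) abort("`band_width` must be >= 1.")
  if (n_pixels_set(plate_mask) == 0) abort("rim unavailable")
  band <- plate_mask$values & !erode_mask(plate_mask$values, band_width)
  for (ex in exclusion_masks) {
    stopifnot(inherits(ex, "trayvol_mask"))
    check_same_shape(plate_mask, ex, "plate and exclusion masks")
    band <- band & !ex$values
  }
  if (!any(band)) abort("rim unavailable")
  idx <- which(band, arr.ind = TRUE)
  pts <- tibble(x = as.integer(idx[, "col"] - 1L),
                y = as.integer(idx[, "row"] - 1L))
  pts <- arrange(pts, .data$y, .data$x)
  if (nrow(pts) > max_points) {
    stride <- ceiling(nrow(pts) / max_points)
    pts <- pts[seq(1L, nrow(pts), by = stride), ]
  }
  pts
}

#' Fit the base plane to rim samples by least squares
#'
#' Minimises `sum((z - (a*x + b*y + c))^2)` over the sampled rim points via a
#' singular value decomposition of the design matrix — an orthogonal
#' decomposition rather than the normal equations, so near-rank-deficient
#' configurations (collinear rim points) are detected reliably: a singular
#' value ratio below `1e-10` raises the degenerate-fit error.
#'
#' @param points Data frame with numeric columns `x`, `y`, `z` (at least 3
#'   non-collinear rows).
#' @return A [plane_model()] with `n_points` and `rms_residual` filled in.
#' @export
#' @examples
#' pts <- expand.grid(x = 0:4, y = 0:4)
#' pts$z <- 0.1 * pts$x - 0.05 * pts$y + 0.3
#' fit_plane(pts)
fit_plane <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("x", "y", "z") %in% names(points)))
  n <- nrow(points)
  if (n < 3) abort("degenerate plane fit")
  A <- cbind(points$x, points$y, 1)
  z <- points$z
  dec <- svd(A)
  if (dec$d[3] < 1e-10 * dec$d[1]) abort("degenerate plane fit")
  coef <- dec$v %*% ((t(dec$u) %*% z) / dec$d)
  resid <- z - A %*% coef
  plane_model(coef[1], coef[2], coef[3],
              n_points = n,
              rms_residual = sqrt(mean(resid^2)))
}

#' Subtract the base plane from a depth map
#'
#' Computes `z_corrected(x, y) = z_depth(x, y) - (a*x + b*y + c)` elementwise,
#' re-centering the scene so depth is measured relative to the plate surface.
#' With `clip = TRUE` negative values (pixels below the estimated base plane)
#' are set to zero, matching positive-part volume integration.
#'
#' The depth map must already be in `higher_is_elevated` polarity — see
#' [normalize_polarity()].
#'
#' @param depth A [depth_map()].
#' @param plane A [plane_model()].
#' @param clip Zero out negative corrected values? Default `TRUE`.
#' @return An object of class `trayvol_corrected_depth` with fields `values`,
#'   `pixel_area`, `source_plane`, `clipped`.
#' @export
correct_depth <- function(depth, plane, clip = TRUE) {
  stopifnot(inherits(depth, "trayvol_depth_map"),
            inherits(plane, "trayvol_plane"))
  if (depth$polarity != "higher_is_elevated") {
    abort("depth polarity must be normalized to higher_is_elevated first.")
  }
  vals <- depth$values - eval_plane(plane, depth$height, depth$width)
  if (clip) vals[vals < 0] <- 0
  structure(
    list(values = vals, pixel_area = depth$pixel_area,
         source_plane = plane, clipped = isTRUE(clip)),
    class = "trayvol_corrected_depth"
  )
}

#' @export
print.trayvol_corrected_depth <- function(x, ...) {
  cat(sprintf("<corrected depth> %d x %d px, clipped = %s, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$clipped,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Integrate corrected depth into a volume
#'
#' Treats each pixel as a vertical prism of base area `s^2` (the depth map's
#' `pixel_area`) and height equal to its corrected depth, and sums the prisms
#' over the item mask: `V = sum_{(x,y) in mask, z > 0} z_corrected(x,y) * s^2`.
#' Only strictly positive corrected values contribute; pixels at or below the
#' base plane add nothing. Volumes are in arbitrary cubic units unless the
#' pixel area has been metrically calibrated.
#'
#' An empty mask yields a zero-volume estimate with a warning rather than an
#' error, so one degenerate item does not abort a multi-item frame.
#'
#' @param corrected Output of [correct_depth()].
#' @param mask Item [binary_mask()], same shape as the depth map.
#' @return One-row tibble with columns `label`, `frame_id`, `volume`,
#'   `n_pixels` (count of contributing pixels).
#' @export
integrate_volume <- function(corrected, mask) {
  stopifnot(inherits(corrected, "trayvol_corrected_depth"),
            inherits(mask, "trayvol_mask"))
  check_same_shape(corrected, mask, "corrected depth and mask")
  if (n_pixels_set(mask) == 0) {
    warn(sprintf("empty mask '%s': zero volume reported.", mask$label))
  }
  # 64-bit accumulation regardless of raster storage precision
  z <- as.numeric(corrected$values[mask$values])
  pos <- z > 0
  tibble(
    label = mask$label,
    frame_id = mask$frame_id,
    volume = sum(z[pos]) * corrected$pixel_area,
    n_pixels = sum(pos)
  )
}
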