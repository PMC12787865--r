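#' Food item shape specification
#'
#' Synthetic food items are solids with closed-form volumes, placed on the
#' plate at a given center and in-plane rotation. Depth units equal pixel
#' length units (1 depth unit = 1 px), so analytic volumes come out in
#' pixel^3 = arbitrary units, matching uncalibrated relative-depth reporting.
#'
#' Supported kinds and their parameters (all in pixels):
#' * `spherical_cap` — `radius` (sphere radius R), `height` (cap height h <= R)
#' * `cone` — `radius` (base radius), `height`
#' * `box` — `width`, `length`, `height`
#'
#' @param kind One of `"spherical_cap"`, `"cone"`, `"box"`.
#' @param label Item class label.
#' @param center Numeric `(x, y)` center in pixel coordinates.
#' @param rotation_deg In-plane rotation, degrees counter-clockwise.
#' @param ... Kind-specific dimensions (see above), all positive.
#' @return An object of class `trayvol_shape`.
#' @export
#' @examples
#' shape_spec("box", width = 2, length = 3, height = 4)
shape_spec <- function(kind = c("spherical_cap", "cone", "box"),
                       label = kind, center = c(0, 0), rotation_deg = 0, ...) {
  kind <- match.arg(kind)
  pars <- list(...)
  need <- switch(kind,
                 spherical_cap = c("radius", "height"),
                 cone = c("radius", "height"),
                 box = c("width", "length", "height"))
  missing <- setdiff(need, names(pars))
  if (length(missing)) {
    abort(sprintf("shape '%s' needs parameters: %s",
                  kind, paste(missing, collapse = ", ")))
  }
  vals <- unlist(pars[need])
  if (any(vals <= 0)) abort("shape dimensions must be positive.")
  if (kind == "spherical_cap" && pars$height > pars$radius) {
    abort("cap height cannot exceed the sphere radius.")
  }
  structure(
    c(list(kind = kind, label = label, center = as.numeric(center),
           rotation_deg = as.numeric(rotation_deg)),
      pars[need]),
    class = "trayvol_shape"
  )
}

#' Closed-form volume of a synthetic shape
#'
#' The analytic ground truth against which integrated volumes are validated:
#' spherical cap `pi * h^2 * (R - h/3)`, cone `(1/3) * pi * r^2 * h`,
#' box `w * l * h`.
#'
#' @param shape A [shape_spec()].
#' @return Volume in pixel^3 (arbitrary units).
#' @export
#' @examples
#' analytic_volume(shape_spec("cone", radius = 3, height = 3))  # 9 * pi
analytic_volume <- function(shape) {
  stopifnot(inherits(shape, "trayvol_shape"))
  switch(shape$kind,
    spherical_cap = pi * shape$height^2 * (shape$radius - shape$height / 3),
    cone = pi * shape$radius^2 * shape$height / 3,
    box = shape$width * shape$length * shape$height,
    abort(sprintf("unknown shape kind '%s'", shape$kind))
  )
}

# Elevation field of a shape over the pixel grid: height above the plate at
# each pixel center, 0 outside the footprint. Grids are (height x width).
shape_elevation <- function(shape, grid_h, grid_w) {
  x <- matrix(rep(seq_len(grid_w) - 1, each = grid_h), grid_h, grid_w)
  y <- matrix(rep(seq_len(grid_h) - 1, times = grid_w), grid_h, grid_w)
  dx <- x - shape$center[1]
  dy <- y - shape$center[2]
  switch(shape$kind,
    spherical_cap = {
      R <- shape$radius; h <- shape$height
      r2 <- dx^2 + dy^2
      foot2 <- h * (2 * R - h)  # footprint radius^2 = R^2 - (R - h)^2
      elev <- matrix(0, grid_h, grid_w)
      inside <- r2 < foot2
      elev[inside] <- sqrt(R^2 - r2[inside]) - (R - h)
      elev
    },
    cone = {
      d <- sqrt(dx^2 + dy^2)
      pmax(0, shape$height * (1 - d / shape$radius)) *
        (d < shape$radius)
    },
    box = {
      th <- shape$rotation_deg * pi / 180
      u <- cos(th) * dx + sin(th) * dy
      v <- -sin(th) * dx + cos(th) * dy
      # half-open [-w/2, w/2) x [-l/2, l/2): a box whose edges fall on pixel
      # centers keeps exactly one boundary row/column, matching its area
      (u >= -shape$width / 2) * (u < shape$width / 2) *
        (v >= -shape$length / 2) * (v < shape$length / 2) * shape$height
    },
    abort(sprintf("unknown shape kind '%s'", shape$kind))
  )
}

shape_footprint <- function(shape, grid_h, grid_w) {
  shape_elevation(shape, grid_h, grid_w) > 0
}

# Maximum distance from a reference point to any point of the footprint,
# used to check the item stays inside the plate's food region. Exact per
# kind (box uses its rotated corners), so a long item can fit at one
# orientation and legitimately fail at another.
shape_max_extent <- function(shape, from) {
  if (shape$kind == "box") {
    th <- shape$rotation_deg * pi / 180
    hw <- shape$width / 2; hl <- shape$length / 2
    corners <- rbind(c(hw, hl), c(hw, -hl), c(-hw, hl), c(-hw, -hl))
    rot <- cbind(cos(th) * corners[, 1] - sin(th) * corners[, 2],
                 sin(th) * corners[, 1] + cos(th) * corners[, 2])
    return(max(sqrt((shape$center[1] + rot[, 1] - from[1])^2 +
                      (shape$center[2] + rot[, 2] - from[2])^2)))
  }
  d_center <- sqrt(sum((shape$center - from)^2))
  reach <- switch(shape$kind,
    spherical_cap = sqrt(shape$height * (2 * shape$radius - shape$height)),
    cone = shape$radius
  )
  d_center + reach
}
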