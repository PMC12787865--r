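#' Synthetic overhead tray scene specification
#'
#' Emulates an overhead capture of a tray holding one flat plate and separated
#' food items, the way a cafeteria monitoring camera sees it, with ground
#' truth known in closed form. The rendered relative depth map is composed of:
#'
#' * a global planar tilt `a*x + b*y + c` over the whole tray — the
#'   perspective-induced slope artifact that monocular depth models produce
#'   and that base-plane correction must remove;
#' * the plate, flat at the tilt plane level (its rim is the fit support);
#' * per-item elevation fields with closed-form volumes;
#' * optional i.i.d. Gaussian depth noise (applied after composition, seeded).
#'
#' Items must lie fully inside the plate's inner disk (outer radius minus rim
#' width) so the rim band stays food-free, and may not overlap one another,
#' which keeps per-item ground truth unambiguous.
#'
#' @param grid `(height, width)` of the raster in pixels.
#' @param plane `(a, b, c)` true tilt coefficients.
#' @param plate_center `(x, y)` plate center in pixels; default grid center.
#' @param plate_radius Outer plate radius, pixels.
#' @param rim_width Width of the flat rim annulus, pixels.
#' @param items List of [shape_spec()] objects.
#' @param noise_sd Depth-noise standard deviation (depth units, where the
#'   relative-depth range is order 1); 0 disables noise.
#' @param seed Integer RNG seed for the noise field.
#' @return An object of class `trayvol_scene_spec`.
#' @export
scene_spec <- function(grid = c(512, 512), plane = c(0, 0, 0.2),
                       plate_center = NULL, plate_radius = NULL,
                       rim_width = 12, items = list(),
                       noise_sd = 0, seed = 0L) {
  grid <- as.integer(grid)
  plate_center <- plate_center %||% ((rev(grid) - 1) / 2)
  plate_radius <- plate_radius %||% (min(grid) * 0.42)
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  # plate must fit in the grid
  if (plate_center[1] - plate_radius < 0 ||
      plate_center[2] - plate_radius < 0 ||
      plate_center[1] + plate_radius > grid[2] - 1 ||
      plate_center[2] + plate_radius > grid[1] - 1) {
    abort("plate does not fit within the grid.")
  }
  inner <- plate_radius - rim_width
  for (it in items) {
    stopifnot(inherits(it, "trayvol_shape"))
    if (shape_max_extent(it, plate_center) > inner) {
      abort(sprintf("item '%s' extends into the plate rim or beyond.",
                    it$label))
    }
  }
  labels <- vapply(items, `[[`, "", "label")
  if (anyDuplicated(labels)) abort("item labels must be unique.")
  structure(
    list(grid = grid, plane = as.numeric(plane),
         plate_center = as.numeric(plate_center),
         plate_radius = as.numeric(plate_radius),
         rim_width = as.numeric(rim_width),
         items = items, noise_sd = as.numeric(noise_sd),
         seed = as.integer(seed)),
    class = "trayvol_scene_spec"
  )
}

#' Render a synthetic scene with ground truth
#'
#' Composes the depth raster (tilt plane + item elevations + seeded Gaussian
#' noise), rasterizes exact per-item footprint masks and the plate mask, and
#' records the ground truth: the true tilt plane and each item's closed-form
#' volume. Rendering is reproducible bit-for-bit given the spec (the noise
#' seed is part of the spec).
#'
#' @param spec A [scene_spec()].
#' @param frame_id Frame identifier stamped on masks and results.
#' @return An object of class `trayvol_scene`: fields `depth` ([depth_map()]),
#'   `plate_mask`, `item_masks` (named list), `truth` (list with `plane`,
#'   `item_volumes`), `spec`, `frame_id`.
#' @export
#' @examples
#' sc <- render_scene(scene_spec(grid = c(64, 64), items = list(
#'   shape_spec("cone", center = c(31.5, 31.5), radius = 8, height = 5))))
#' sc$truth$item_volumes
render_scene <- function(spec, frame_id = "frame") {
  stopifnot(inherits(spec, "trayvol_scene_spec"))
  h <- spec$grid[1]; w <- spec$grid[2]
  plane <- plane_model(spec$plane[1], spec$plane[2], spec$plane[3])
  vals <- eval_plane(plane, h, w)

  item_masks <- list()
  for (it in spec$items) {
    elev <- shape_elevation(it, h, w)
    foot <- elev > 0
    for (prev in item_masks) {
      if (any(foot & prev$values)) abort("item overlap")
    }
    item_masks[[it$label]] <- binary_mask(foot, label = it$label,
                                          frame_id = frame_id)
    vals <- vals + elev
  }

  if (spec$noise_sd > 0) {
    vals <- vals + withr::with_seed(
      spec$seed, matrix(rnorm(h * w, sd = spec$noise_sd), h, w))
  }

  x <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  y <- matrix(rep(seq_len(h) - 1, times = w), h, w)
  plate <- (x - spec$plate_center[1])^2 + (y - spec$plate_center[2])^2 <=
    spec$plate_radius^2

  structure(
    list(
      depth = depth_map(vals, pixel_area = 1,
                        polarity = "higher_is_elevated"),
      plate_mask = binary_mask(plate, label = "plate", frame_id = frame_id),
      item_masks = item_masks,
      truth = list(
        plane = plane,
        item_volumes = vapply(spec$items, analytic_volume, 0) |>
          setNames(vapply(spec$items, `[[`, "", "label"))
      ),
      spec = spec,
      frame_id = frame_id
    ),
    class = "trayvol_scene"
  )
}

#' @export
print.trayvol_scene <- function(x, ...) {
  cat(sprintf("<scene '%s'> %d x %d px, %d item(s), noise sd = %g\n",
              x$frame_id, x$spec$grid[1], x$spec$grid[2],
              length(x$item_masks), x$spec$noise_sd))
  invisible(x)
}

#' Rotation sequence of a scene
#'
#' Emulates repeated passes of the same plate under the camera with the food
#' repositioned between passes: for each angle, every item's center is
#' orbited around the plate center by that angle while the item keeps its
#' own orientation (so an elongated item tangential to the rim at one angle
#' can genuinely collide with the rim at another). Ground-truth volumes are
#' identical across the sequence; only the rasterized footprints change.
#'
#' @param spec A [scene_spec()].
#' @param angles Numeric vector of rotation angles in degrees.
#' @param frame_prefix Prefix for per-scene frame ids.
#' @return List of `trayvol_scene`, one per angle (empty list for no angles).
#'   Errors if any rotation pushes an item off the plate's food region.
#' @export
rotation_sequence <- function(spec, angles, frame_prefix = "rot") {
  stopifnot(inherits(spec, "trayvol_scene_spec"))
  purrr::imap(as.list(angles), function(angle, i) {
    th <- angle * pi / 180
    items <- purrr::map(spec$items, function(it) {
      d <- it$center - spec$plate_center
      it$center <- spec$plate_center + c(
        cos(th) * d[1] - sin(th) * d[2],
        sin(th) * d[1] + cos(th) * d[2])
      it
    })
    rotated <- tryCatch(
      scene_spec(grid = spec$grid, plane = spec$plane,
                 plate_center = spec$plate_center,
                 plate_radius = spec$plate_radius,
                 rim_width = spec$rim_width, items = items,
                 noise_sd = spec$noise_sd, seed = spec$seed + i - 1L),
      error = function(e) abort(sprintf(
        "rotation by %g deg pushes an item off the plate: %s",
        angle, conditionMessage(e)))
    )
    render_scene(rotated, frame_id = sprintf("%s%03d", frame_prefix, i))
  })
}

#' Write a scene to disk with a manifest
#'
#' Persists the depth raster (32-bit float TIFF + sidecar), plate and item
#' masks (8-bit PNG) and a JSON manifest listing files, detections (tight
#' bounding boxes derived from the masks, plus a full-frame tray box) and the
#' ground truth. The manifest is what the mock perception backend consumes.
#'
#' @param scene A rendered `trayvol_scene`.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest JSON, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "trayvol_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  depth_file <- file.path(dir, paste0(scene$frame_id, "_depth.tif"))
  write_depth_raster(scene$depth, depth_file)

  mask_entry <- function(mask) {
    f <- file.path(dir, sprintf("%s_mask_%s.png", scene$frame_id, mask$label))
    write_mask_png(mask, f)
    idx <- which(mask$values, arr.ind = TRUE)
    list(
      label = mask$label, file = basename(f),
      bbox = c(min(idx[, "col"]) - 1L, min(idx[, "row"]) - 1L,
               max(idx[, "col"]), max(idx[, "row"]))  # half-open [x0,x1)x[y0,y1)
    )
  }
  entries <- c(list(mask_entry(scene$plate_mask)),
               purrr::map(unname(scene$item_masks), mask_entry))

  h <- scene$spec$grid[1]; w <- scene$spec$grid[2]
  detections <- c(
    list(list(label = "tray", bbox = c(0L, 0L, w, h), confidence = 1.0)),
    purrr::map(entries, ~ list(label = .x$label, bbox = .x$bbox,
                               confidence = 1.0))
  )

  manifest <- list(
    schema_version = 1L,
    frame_id = scene$frame_id,
    grid = c(h, w),
    depth_file = basename(depth_file),
    masks = entries,
    detections = detections,
    ground_truth = list(
      plane = c(scene$truth$plane$a, scene$truth$plane$b,
                scene$truth$plane$c),
      item_volumes = as.list(scene$truth$item_volumes)
    )
  )
  path <- file.path(dir, paste0(scene$frame_id, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
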