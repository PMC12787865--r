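#' Perception backend contract
#'
#' The pipeline's three perception stages — tray/item detection, prompt-based
#' segmentation, and monocular depth estimation — are pluggable behind three
#' S3 generics. Adapters to real pretrained models can implement the same
#' generics; the package ships a deterministic [mock_backend()] driven by
#' synthetic-scene manifests, which is what the tests and validation runs use
#' (trained weights are not part of this package's contribution).
#'
#' @param backend A backend object.
#' @param frame_ref Frame reference the backend can resolve (for the mock
#'   backend: a manifest path or a frame id registered with it).
#' @param ... Passed to methods.
#' @return `detect()` returns a tibble of detections (`label`, `x0`, `y0`,
#'   `x1`, `y1`, `confidence`) with half-open pixel boxes; zero rows when
#'   nothing is found (never a silent failure — backend errors are raised).
#' @export
detect <- function(backend, frame_ref, ...) UseMethod("detect")

#' @rdname detect
#' @param prompt_bbox One-row detection tibble (or named list with `x0`, `y0`,
#'   `x1`, `y1`) prompting the segmentation, as a bounding-box prompt.
#' @return `segment_item()` returns a [binary_mask()] confined to the frame.
#' @export
segment_item <- function(backend, frame_ref, prompt_bbox, ...) {
  UseMethod("segment_item")
}

#' @rdname detect
#' @param roi A [roi_transform()] describing the crop and model-size chain;
#'   `NULL` for the full frame at native resolution.
#' @return `estimate_depth()` returns a [depth_map()] aligned to the crop at
#'   native crop resolution (depth inferred at model size is resampled back so
#'   masks stay at native resolution).
#' @export
estimate_depth <- function(backend, frame_ref, roi = NULL, ...) {
  UseMethod("estimate_depth")
}

#' Region-of-interest transform
#'
#' Affine mapping between frame coordinates and model-input coordinates: the
#' frame is cropped at `crop_origin` to `crop_size`, then resized to
#' `model_size` (the depth model's fixed input, conventionally 512 x 512).
#' `NULL` `model_size` means no resize (native-resolution inference).
#'
#' @param crop_origin `(x0, y0)` of the crop in frame pixels.
#' @param crop_size `(w, h)` of the crop.
#' @param model_size `(w, h)` of the model input, or `NULL`.
#' @return An object of class `trayvol_roi`.
#' @export
roi_transform <- function(crop_origin = c(0, 0), crop_size,
                          model_size = NULL) {
  if (any(crop_size <= 0)) abort("crop size must be positive.")
  ms <- model_size %||% crop_size
  structure(
    list(crop_origin = as.numeric(crop_origin),
         crop_size = as.numeric(crop_size),
         model_size = as.numeric(ms),
         scale = as.numeric(ms) / as.numeric(crop_size)),
    class = "trayvol_roi"
  )
}

#' Map points between frame and model coordinates
#'
#' Exact forward/inverse affine mapping through the crop-and-resize chain;
#' the round trip is the identity up to floating-point tolerance.
#'
#' @param point Numeric `(x, y)` or 2-column matrix of points.
#' @param transform A [roi_transform()].
#' @param direction `"frame_to_model"` or `"model_to_frame"`.
#' @return Mapped point(s), same shape as the input.
#' @export
map_roi_coordinates <- function(point, transform,
                                direction = c("frame_to_model",
                                              "model_to_frame")) {
  direction <- match.arg(direction)
  stopifnot(inherits(transform, "trayvol_roi"))
  p <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  out <- if (direction == "frame_to_model") {
    cbind((p[, 1] - transform$crop_origin[1]) * transform$scale[1],
          (p[, 2] - transform$crop_origin[2]) * transform$scale[2])
  } else {
    cbind(p[, 1] / transform$scale[1] + transform$crop_origin[1],
          p[, 2] / transform$scale[2] + transform$crop_origin[2])
  }
  if (is.matrix(point)) out else as.numeric(out)
}

#' Deterministic mock perception backend
#'
#' Serves detections, masks and depth from synthetic-scene manifests (see
#' [write_scene()]), bit-deterministically: no randomness at inference. It is
#' the reference backend for tests and validation; any result obtained
#' through it equals feeding the scene's rasters directly to the geometry
#' functions.
#'
#' @param manifests Character vector of manifest JSON paths, or a directory
#'   containing `*_manifest.json` files.
#' @return An object of class `trayvol_mock_backend`.
#' @export
mock_backend <- function(manifests) {
  if (length(manifests) == 1 && dir.exists(manifests)) {
    manifests <- list.files(manifests, pattern = "_manifest\\.json$",
                            full.names = TRUE)
  }
  entries <- purrr::map(manifests, function(p) {
    m <- jsonlite::read_json(p, simplifyVector = TRUE)
    m$dir <- dirname(p)
    m
  })
  names(entries) <- purrr::map_chr(entries, "frame_id")
  structure(list(frames = entries), class = "trayvol_mock_backend")
}

resolve_frame <- function(backend, frame_ref) {
  if (file.exists(frame_ref) && grepl("\\.json$", frame_ref)) {
    m <- jsonlite::read_json(frame_ref, simplifyVector = TRUE)
    m$dir <- dirname(frame_ref)
    return(m)
  }
  m <- backend$frames[[frame_ref]]
  if (is.null(m)) abort(sprintf("unknown frame '%s'", frame_ref))
  m
}

#' @export
detect.trayvol_mock_backend <- function(backend, frame_ref, ...) {
  m <- resolve_frame(backend, frame_ref)
  det <- m$detections
  if (is.null(det) || NROW(det) == 0) {
    return(tibble(label = character(), x0 = integer(), y0 = integer(),
                  x1 = integer(), y1 = integer(), confidence = double()))
  }
  bb <- do.call(rbind, det$bbox)
  tibble(label = det$label,
         x0 = bb[, 1], y0 = bb[, 2], x1 = bb[, 3], y1 = bb[, 4],
         confidence = det$confidence)
}

# intersection-over-union, so a prompt matches the item whose box it best
# fits rather than any larger box that merely contains it (e.g. the plate)
bbox_iou <- function(a, b) {
  inter <- max(0, min(a[3], b[3]) - max(a[1], b[1])) *
    max(0, min(a[4], b[4]) - max(a[2], b[2]))
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) -
    inter
  if (union <= 0) 0 else inter / union
}

#' @export
segment_item.trayvol_mock_backend <- function(backend, frame_ref, prompt_bbox,
                                              ...) {
  m <- resolve_frame(backend, frame_ref)
  pb <- c(prompt_bbox$x0, prompt_bbox$y0, prompt_bbox$x1, prompt_bbox$y1)
  h <- m$grid[1]; w <- m$grid[2]
  if (pb[3] <= 0 || pb[4] <= 0 || pb[1] >= w || pb[2] >= h) {
    abort("prompt bbox lies outside the frame.")
  }
  masks <- m$masks
  overlaps <- purrr::map_dbl(masks$bbox, ~ bbox_iou(.x, pb))
  if (all(overlaps == 0)) abort("prompt bbox matches no item.")
  best <- which.max(overlaps)
  read_mask_png(file.path(m$dir, masks$file[best]),
                label = masks$label[best], frame_id = m$frame_id)
}

#' @export
estimate_depth.trayvol_mock_backend <- function(backend, frame_ref,
                                                roi = NULL, ...) {
  m <- resolve_frame(backend, frame_ref)
  depth <- read_depth_raster(file.path(m$dir, m$depth_file))
  if (is.null(roi)) return(depth)
  stopifnot(inherits(roi, "trayvol_roi"))
  x0 <- roi$crop_origin[1]; y0 <- roi$crop_origin[2]
  w <- roi$crop_size[1]; h <- roi$crop_size[2]
  if (x0 < 0 || y0 < 0 || x0 + w > depth$width || y0 + h > depth$height) {
    abort("ROI extends beyond the frame.")
  }
  crop <- depth$values[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), drop = FALSE]
  # emulate fixed-size model inference, then bring depth back to the masks'
  # native crop resolution
  if (!identical(roi$model_size, roi$crop_size)) {
    crop <- resample_bilinear(crop, roi$model_size[2], roi$model_size[1])
    crop <- resample_bilinear(crop, h, w)
  }
  depth_map(crop, pixel_area = depth$pixel_area, polarity = depth$polarity)
}

#' Select the tray detection
#'
#' Applies the tray-selection rule: among detections labelled `"tray"`, take
#' the highest confidence; ties break to the largest box area. Returns `NULL`
#' when no tray was detected.
#'
#' @param detections Detection tibble from [detect()].
#' @return One-row tibble, or `NULL`.
#' @export
select_tray <- function(detections) {
  trays <- dplyr::filter(detections, .data$label == "tray")
  if (nrow(trays) == 0) return(NULL)
  trays <- mutate(trays,
                  .area = (.data$x1 - .data$x0) * (.data$y1 - .data$y0))
  trays <- arrange(trays, dplyr::desc(.data$confidence),
                   dplyr::desc(.data$.area))
  dplyr::select(trays[1, ], -".area")
}
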