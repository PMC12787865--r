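#' Pipeline configuration
#'
#' Bundles the tunable parameters of the frame-processing pipeline. Defaults
#' reflect the standard analysis: 5-px rim band, positive-part clipping,
#' unit pixel area, depth polarity `higher_is_elevated`, native-resolution
#' depth (no model-size resampling chain).
#'
#' @param band_width Rim band width in pixels.
#' @param clip Clip negative corrected depth to zero?
#' @param pixel_area Area per pixel, squared arbitrary length units.
#' @param polarity Depth polarity the backend delivers.
#' @param model_size `(w, h)` fixed depth-model input size, or `NULL` for
#'   native-resolution depth.
#' @param calibration Named list of density models (per food class), a path
#'   to a density-model JSON, or `NULL` for volume-only output.
#' @param seed Integer seed recorded in outputs (the pipeline itself is
#'   deterministic; the seed feeds synthetic-scene generation).
#' @return An object of class `trayvol_config`.
#' @export
pipeline_config <- function(band_width = 5, clip = TRUE, pixel_area = 1,
                            polarity = c("higher_is_elevated",
                                         "lower_is_elevated"),
                            model_size = NULL, calibration = NULL,
                            seed = 0L) {
  polarity <- match.arg(polarity)
  if (is.character(calibration)) calibration <- read_density_models(calibration)
  structure(
    list(band_width = as.integer(band_width), clip = isTRUE(clip),
         pixel_area = as.numeric(pixel_area), polarity = polarity,
         model_size = if (!is.null(model_size)) as.integer(model_size),
         calibration = calibration, seed = as.integer(seed),
         schema_version = 1L),
    class = "trayvol_config"
  )
}

#' Serialize / parse a pipeline configuration
#'
#' JSON round trip for configs; `parse -> serialize` is idempotent.
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` a
#'   config object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "trayvol_config"))
  x <- unclass(config)
  x$calibration <- NULL  # persisted separately as the conversion table
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  pipeline_config(band_width = x$band_width, clip = x$clip,
                  pixel_area = x$pixel_area, polarity = x$polarity,
                  model_size = x$model_size, seed = x$seed)
}

#' Process one frame through the full pipeline
#'
#' Runs the complete chain on a single overhead frame: detect and select the
#' tray, crop to it, segment the plate and each food item with bounding-box
#' prompts, estimate depth over the crop, normalize polarity, sample the
#' plate rim excluding food pixels, fit the base plane by least squares,
#' subtract it (clipping negatives), integrate each item's volume, and — if a
#' density model is loaded for the item's class — convert volume to weight.
#'
#' Failures are typed, never silent: a frame with no tray detection gets
#' `status = "no tray"`, an unusable rim `status = "rim unavailable"`; in
#' both cases no volumes are reported for that frame.
#'
#' @param backend A perception backend (e.g. [mock_backend()]).
#' @param frame_ref Frame reference resolvable by the backend.
#' @param config A [pipeline_config()].
#' @return An object of class `trayvol_frame_result`: `frame_id`, `status`
#'   (`"ok"` or failure reason), `tray` (one-row tibble or `NULL`), `plane`,
#'   `items` (tibble: `label`, `frame_id`, `volume`, `n_pixels`, and
#'   `weight_g` when calibrated), `warnings`.
#' @export
process_frame <- function(backend, frame_ref, config = pipeline_config()) {
  stopifnot(inherits(config, "trayvol_config"))
  detections <- detect(backend, frame_ref)
  frame_id <- if (nrow(detections) > 0 || is.character(frame_ref)) {
    tryCatch(resolve_frame(backend, frame_ref)$frame_id,
             error = function(e) as.character(frame_ref))
  } else as.character(frame_ref)

  fail <- function(status, tray = NULL) {
    structure(list(frame_id = frame_id, status = status, tray = tray,
                   plane = NULL, items = tibble(), warnings = character()),
              class = "trayvol_frame_result")
  }

  tray <- select_tray(detections)
  if (is.null(tray)) return(fail("no tray"))

  roi <- roi_transform(
    crop_origin = c(tray$x0, tray$y0),
    crop_size = c(tray$x1 - tray$x0, tray$y1 - tray$y0),
    model_size = config$model_size
  )

  crop_mask <- function(mask) {
    binary_mask(
      mask$values[(tray$y0 + 1):tray$y1, (tray$x0 + 1):tray$x1,
                  drop = FALSE],
      label = mask$label, frame_id = mask$frame_id)
  }

  plate_det <- dplyr::filter(detections, .data$label == "plate")
  if (nrow(plate_det) == 0) return(fail("rim unavailable", tray))
  plate_mask <- crop_mask(segment_item(backend, frame_ref, plate_det[1, ]))

  item_dets <- dplyr::filter(detections,
                             !.data$label %in% c("tray", "plate"))
  item_masks <- purrr::map(seq_len(nrow(item_dets)), function(i) {
    crop_mask(segment_item(backend, frame_ref, item_dets[i, ]))
  })

  depth <- estimate_depth(backend, frame_ref, roi = roi)
  depth <- depth_map(depth$values, pixel_area = config$pixel_area,
                     polarity = config$polarity)
  depth <- normalize_polarity(depth, "higher_is_elevated")

  rim <- tryCatch(
    sample_rim(plate_mask, band_width = config$band_width,
               exclusion_masks = item_masks),
    error = function(e) NULL
  )
  if (is.null(rim)) return(fail("rim unavailable", tray))

  rim$z <- depth$values[cbind(rim$y + 1L, rim$x + 1L)]
  plane <- tryCatch(fit_plane(rim), error = function(e) NULL)
  if (is.null(plane)) return(fail("degenerate plane fit", tray))

  corrected <- correct_depth(depth, plane, clip = config$clip)

  warnings <- character()
  items <- withCallingHandlers(
    purrr::map(item_masks, ~ integrate_volume(corrected, .x)) |> bind_rows(),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  if (nrow(items) > 0 && !is.null(config$calibration)) {
    items$weight_g <- purrr::map2_dbl(items$label, items$volume,
      function(lbl, v) {
        mdl <- config$calibration[[lbl]]
        if (is.null(mdl)) NA_real_ else estimate_weight(v, mdl)
      })
  }

  structure(
    list(frame_id = frame_id, status = "ok", tray = tray, plane = plane,
         items = items, warnings = warnings),
    class = "trayvol_frame_result"
  )
}

#' @export
print.trayvol_frame_result <- function(x, ...) {
  cat(sprintf("<frame result '%s'> status: %s\n", x$frame_id, x$status))
  if (x$status == "ok") print(x$items)
  invisible(x)
}

#' @method tidy trayvol_frame_result
#' @export
tidy.trayvol_frame_result <- function(x, ...) x$items

#' Process a sequence of frames grouped into rotation blocks
#'
#' Runs [process_frame()] over every frame of a sequence manifest, drops
#' failed frames (counting them in the report), groups frame-level volumes by
#' rotation block and computes per-block mean/SD/CV plus the pooled
#' frame-level CV for the requested food class.
#'
#' @param backend A perception backend.
#' @param sequence Data frame with columns `frame_ref` and `block_id` (one
#'   row per frame), or a list coercible to it.
#' @param config A [pipeline_config()].
#' @param label Food-class label to report on; default the first item label
#'   seen.
#' @return A [sequence_report()] with extra fields `n_failed` and
#'   `failures` (tibble of `frame_ref`, `status`), and `frame_results`.
#' @export
process_sequence <- function(backend, sequence,
                             config = pipeline_config(), label = NULL) {
  sequence <- as_tibble(sequence)
  stopifnot(all(c("frame_ref", "block_id") %in% names(sequence)))
  if (nrow(sequence) == 0) abort("empty sequence manifest.")

  results <- purrr::map(sequence$frame_ref,
                        ~ process_frame(backend, .x, config))
  ok <- purrr::map_lgl(results, ~ .x$status == "ok")

  failures <- tibble(
    frame_ref = as.character(sequence$frame_ref[!ok]),
    status = purrr::map_chr(results[!ok], "status")
  )

  frames <- purrr::map2(results[ok], sequence$block_id[ok], function(r, b) {
    if (nrow(r$items) == 0) return(NULL)
    mutate(r$items, block_id = b)
  }) |> bind_rows()

  if (nrow(frames) == 0) {
    report <- structure(
      list(blocks = tibble(), global_cv_percent = NA_real_,
           label = label %||% NA_character_, frames = tibble()),
      class = "trayvol_sequence_report")
  } else {
    report <- sequence_report(frames, label = label)
  }
  report$n_failed <- sum(!ok)
  report$failures <- failures
  report$frame_results <- results
  report
}

#' Write a sequence report to JSON and CSV
#'
#' Persists the per-block statistics table as CSV and the full report
#' (blocks, pooled CV, failure counts, schema version) as JSON. Output is a
#' pure function of the inputs, so re-running an identical analysis yields
#' byte-identical files.
#'
#' @param report A report from [process_sequence()] or [sequence_report()].
#' @param dir Output directory.
#' @param stem File name stem; default `"sequence"`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sequence_report <- function(report, dir, stem = "sequence") {
  stopifnot(inherits(report, "trayvol_sequence_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(stem, "_blocks.csv"))
  utils::write.csv(report$blocks, csv, row.names = FALSE)
  json <- file.path(dir, paste0(stem, "_report.json"))
  jsonlite::write_json(
    list(schema_version = 1L,
         label = report$label,
         blocks = report$blocks,
         global_cv_percent = report$global_cv_percent,
         n_failed = report$n_failed %||% 0L,
         failures = report$failures %||% tibble()),
    json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = csv, json = json))
}
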