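# Fixture: a three-item scene written to disk, served by the mock backend.
local_scene_backend <- function(n = 160, env = parent.frame()) {
  spec <- scene_spec(
    grid = c(n, n), plane = c(0.01, -0.005, 0.3),
    items = list(
      shape_spec("spherical_cap", label = "rice", center = c(n * 0.38, n * 0.42),
                 radius = n * 0.09, height = n * 0.05),
      shape_spec("cone", label = "peas", center = c(n * 0.62, n * 0.42),
                 radius = n * 0.07, height = n * 0.04),
      shape_spec("box", label = "chicken", center = c(n * 0.5, n * 0.66),
                 width = n * 0.14, length = n * 0.07, height = n * 0.05)
    ))
  scene <- render_scene(spec, frame_id = "fx")
  dir <- withr::local_tempdir(.local_envir = env)
  manifest <- write_scene(scene, dir)
  list(scene = scene, dir = dir, manifest = manifest,
       backend = mock_backend(dir))
}

test_that("mock detection passes the manifest boxes through", {
  fx <- local_scene_backend()
  det <- detect(fx$backend, "fx")
  expect_setequal(det$label, c("tray", "plate", "rice", "peas", "chicken"))
  expect_true(all(det$x0 < det$x1 & det$y0 < det$y1))
  expect_true(all(det$confidence >= 0 & det$confidence <= 1))
  # item boxes are the tight half-open boxes of the ground-truth masks
  rice <- det[det$label == "rice", ]
  idx <- which(fx$scene$item_masks$rice$values, arr.ind = TRUE)
  expect_equal(rice$x0, min(idx[, "col"]) - 1)
  expect_equal(rice$x1, max(idx[, "col"]))
})

test_that("tray selection prefers confidence, then box area", {
  det <- tibble::tibble(
    label = c("tray", "tray", "plate"),
    x0 = c(0, 10, 5), y0 = c(0, 10, 5),
    x1 = c(100, 300, 50), y1 = c(100, 300, 50),
    confidence = c(0.9, 0.7, 0.99))
  expect_equal(select_tray(det)$confidence, 0.9)

  tie <- tibble::tibble(label = c("tray", "tray"),
                        x0 = c(0, 0), y0 = c(0, 0),
                        x1 = c(50, 80), y1 = c(50, 80),
                        confidence = c(0.8, 0.8))
  expect_equal(select_tray(tie)$x1, 80)
  expect_null(select_tray(det[det$label == "plate", ]))
})

test_that("mock segmentation returns the ground-truth mask for its prompt", {
  fx <- local_scene_backend()
  det <- detect(fx$backend, "fx")
  m <- segment_item(fx$backend, "fx", det[det$label == "peas", ])
  expect_identical(m$values, fx$scene$item_masks$peas$values)
  expect_equal(m$label, "peas")

  # prompt fully outside the frame errors
  outside <- tibble::tibble(x0 = 500, y0 = 500, x1 = 600, y1 = 600)
  expect_error(segment_item(fx$backend, "fx", outside), "outside the frame")
})

test_that("a prompt spanning items resolves to the best-fitting box", {
  fx <- local_scene_backend()
  det <- detect(fx$backend, "fx")
  rice <- det[det$label == "rice", ]
  peas <- det[det$label == "peas", ]
  # prompt = union box of rice and peas; rice has the larger footprint, so
  # its box has the greater IoU with the union (computed by hand below)
  prompt <- tibble::tibble(x0 = min(rice$x0, peas$x0),
                           y0 = min(rice$y0, peas$y0),
                           x1 = max(rice$x1, peas$x1),
                           y1 = max(rice$y1, peas$y1))
  union_area <- (prompt$x1 - prompt$x0) * (prompt$y1 - prompt$y0)
  iou <- function(d) (d$x1 - d$x0) * (d$y1 - d$y0) / union_area
  expect_gt(iou(rice), iou(peas))
  got <- segment_item(fx$backend, "fx", prompt)
  expect_equal(got$label, "rice")
})

test_that("mock depth passes the scene raster through (full ROI)", {
  fx <- local_scene_backend()
  d <- estimate_depth(fx$backend, "fx")
  expect_lt(max(abs(d$values - fx$scene$depth$values)),
            diff(range(fx$scene$depth$values)) * 1e-6)
  expect_equal(d$polarity, "higher_is_elevated")
  expect_error(estimate_depth(fx$backend, "nope"), "unknown frame")
})

test_that("bilinear resampling preserves planar rasters through the chain", {
  pl <- outer(0:511, 0:511, function(y, x) 2e-4 * x - 1e-4 * y + 0.3)
  down <- resample_bilinear(pl, 256, 256)
  up <- resample_bilinear(down, 512, 512)
  expect_lt(max(abs(up - pl)), 1e-6)

  const <- resample_bilinear(resample_bilinear(matrix(0.7, 64, 64), 512, 512),
                             33, 47)
  expect_lt(max(abs(const - 0.7)), 1e-12)
})

test_that("ROI coordinate mapping is an exact invertible affine", {
  t1 <- roi_transform(crop_origin = c(0, 0), crop_size = c(64, 64))
  expect_equal(map_roi_coordinates(c(10, 20), t1), c(10, 20))

  t2 <- roi_transform(crop_origin = c(100, 50), crop_size = c(256, 256),
                      model_size = c(512, 512))
  expect_equal(map_roi_coordinates(c(110, 60), t2), c(20, 20))

  withr::with_seed(5, pts <- matrix(runif(2000, -100, 1000), ncol = 2))
  round_trip <- map_roi_coordinates(
    map_roi_coordinates(pts, t2, "frame_to_model"), t2, "model_to_frame")
  expect_lt(max(abs(round_trip - pts)), 1e-9)
})

test_that("mock pipeline equals direct geometry on the scene rasters", {
  fx <- local_scene_backend()
  res <- process_frame(fx$backend, "fx", pipeline_config())
  expect_equal(res$status, "ok")

  depth <- read_depth_raster(file.path(fx$dir, "fx_depth.tif"))
  plate <- read_mask_png(file.path(fx$dir, "fx_mask_plate.png"))
  items <- lapply(c("rice", "peas", "chicken"), function(l) {
    read_mask_png(file.path(fx$dir, sprintf("fx_mask_%s.png", l)))
  })
  rim <- sample_rim(plate, band_width = 5, exclusion_masks = items)
  rim$z <- depth$values[cbind(rim$y + 1L, rim$x + 1L)]
  corrected <- correct_depth(depth, fit_plane(rim))
  direct <- dplyr::bind_rows(lapply(items, integrate_volume,
                                    corrected = corrected))
  merged <- dplyr::left_join(res$items, direct, by = "label",
                             suffix = c("", ".direct"))
  expect_lt(max(abs(merged$volume - merged$volume.direct)), 1e-9)
})
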