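test_that("rim band equals mask minus its erosion, row-major ordered", {
  # filled disk: band of width 1 is exactly the 8-neighborhood boundary
  disk <- disk_mask(9, 4, 4, 4)
  pts <- sample_rim(binary_mask(disk, "plate"), band_width = 1)
  oracle <- which(brute_band(disk, 1), arr.ind = TRUE)
  expect_equal(nrow(pts), nrow(oracle))
  expect_setequal(paste(pts$x, pts$y),
                  paste(oracle[, "col"] - 1, oracle[, "row"] - 1))
  # deterministic row-major ordering
  expect_equal(order(pts$y, pts$x), seq_len(nrow(pts)))

  # filled 10x10 rectangle in a 20x20 grid, band 2: 100 - 36 interior = 64
  rect <- matrix(FALSE, 20, 20); rect[6:15, 6:15] <- TRUE
  expect_equal(nrow(sample_rim(binary_mask(rect, "plate"), band_width = 2)),
               64)
})

test_that("rim sampling excludes food pixels and errors when unusable", {
  plate <- disk_mask(31, 15, 15, 12)
  food_all <- binary_mask(plate, "stew")
  expect_error(
    sample_rim(binary_mask(plate, "plate"), exclusion_masks = list(food_all)),
    "rim unavailable")
  expect_error(sample_rim(binary_mask(matrix(FALSE, 5, 5), "plate")),
               "rim unavailable")

  # partial exclusion removes exactly the overlapping band pixels
  bare <- sample_rim(binary_mask(plate, "plate"), band_width = 2)
  blocker <- matrix(FALSE, 31, 31); blocker[1:31, 1:15] <- TRUE
  blocked <- sample_rim(binary_mask(plate, "plate"), band_width = 2,
                        exclusion_masks = list(binary_mask(blocker, "food")))
  expect_true(all(blocked$x >= 15))
  expect_equal(nrow(blocked), sum(bare$x >= 15))
})

test_that("rim subsampling uses a deterministic uniform stride", {
  plate <- disk_mask(301, 150, 150, 140)
  pts_all <- sample_rim(binary_mask(plate, "plate"), band_width = 6,
                        max_points = 1e6)
  pts_sub <- sample_rim(binary_mask(plate, "plate"), band_width = 6,
                        max_points = 500)
  expect_gt(nrow(pts_all), 500)
  expect_lte(nrow(pts_sub), 500)
  stride <- ceiling(nrow(pts_all) / 500)
  expect_equal(pts_sub, pts_all[seq(1, nrow(pts_all), by = stride), ])
})

test_that("plane fit recovers noiseless planar samples exactly", {
  pts <- expand.grid(x = seq(0, 40, by = 4), y = seq(0, 40, by = 5))
  pts$z <- 0.1 * pts$x - 0.05 * pts$y + 0.3
  pl <- fit_plane(pts)
  expect_equal(pl$a, 0.1, tolerance = 1e-9)
  expect_equal(pl$b, -0.05, tolerance = 1e-9)
  expect_equal(pl$c, 0.3, tolerance = 1e-9)
  expect_lt(pl$rms_residual, 1e-9)
  expect_equal(pl$n_points, nrow(pts))

  # horizontal plane
  flat <- data.frame(x = c(0, 7, 3, 9), y = c(0, 2, 8, 5), z = 0.42)
  pf <- fit_plane(flat)
  expect_equal(c(pf$a, pf$b, pf$c), c(0, 0, 0.42), tolerance = 1e-9)

  # property: random planes, random point clouds
  for (s in 1:10) {
    withr::with_seed(s, {
      abc <- runif(3, -0.2, 0.2)
      q <- data.frame(x = runif(30, 0, 100), y = runif(30, 0, 100))
      q$z <- abc[1] * q$x + abc[2] * q$y + abc[3]
      fit <- fit_plane(q)
      expect_equal(c(fit$a, fit$b, fit$c), abc, tolerance = 1e-9,
                   ignore_attr = TRUE)
    })
  }
})

test_that("degenerate plane fits are rejected", {
  expect_error(fit_plane(data.frame(x = 1:2, y = 1:2, z = 1:2)),
               "degenerate plane fit")
  collinear <- data.frame(x = 1:5, y = 2 * (1:5), z = rnorm(5))
  expect_error(fit_plane(collinear), "degenerate plane fit")
})

test_that("depth correction subtracts the plane with optional clipping", {
  d <- depth_map(matrix(0.5, 6, 8))
  ident <- correct_depth(d, plane_model(0, 0, 0), clip = FALSE)
  expect_equal(ident$values, d$values)
  expect_false(ident$clipped)

  zero <- correct_depth(d, plane_model(0, 0, 0.5), clip = FALSE)
  expect_equal(zero$values, matrix(0, 6, 8))

  d3 <- depth_map(matrix(0.3, 4, 4))
  expect_equal(correct_depth(d3, plane_model(0, 0, 0.5), clip = FALSE)$values,
               matrix(-0.2, 4, 4))
  clipped <- correct_depth(d3, plane_model(0, 0, 0.5), clip = TRUE)
  expect_equal(clipped$values, matrix(0, 4, 4))
  expect_true(clipped$clipped)

  # x is the column index: plane (1, 0, 0) increases along columns
  dm <- depth_map(matrix(0, 2, 3))
  corr <- correct_depth(dm, plane_model(1, 0, 0), clip = FALSE)
  expect_equal(corr$values, matrix(rep(c(0, -1, -2), each = 2), 2, 3))

  expect_error(
    correct_depth(depth_map(matrix(0.2, 3, 3),
                            polarity = "lower_is_elevated"),
                  plane_model(0, 0, 0)),
    "polarity")
})

test_that("volume integration follows the positive-part prism sum", {
  vals <- matrix(0, 4, 4); vals[1:2, 1:2] <- 2
  corr <- correct_depth(depth_map(vals), plane_model(0, 0, 0), clip = FALSE)
  m <- matrix(FALSE, 4, 4); m[1:2, 1:2] <- TRUE
  est <- integrate_volume(corr, binary_mask(m, "cube"))
  expect_equal(est$volume, 8)
  expect_equal(est$n_pixels, 4L)

  # all-negative region contributes nothing
  below <- correct_depth(depth_map(matrix(0.1, 4, 4)),
                         plane_model(0, 0, 0.5), clip = FALSE)
  est2 <- integrate_volume(below, binary_mask(!m, "shadow"))
  expect_equal(est2$volume, 0)
  expect_equal(est2$n_pixels, 0L)

  # empty mask: zero volume with a warning, not an error
  expect_warning(
    est3 <- integrate_volume(corr, binary_mask(matrix(FALSE, 4, 4), "gone")),
    "empty mask")
  expect_equal(est3$volume, 0)
})

test_that("integration matches a brute-force per-pixel loop exactly", {
  for (s in 1:5) {
    withr::with_seed(s, {
      n <- sample(16:64, 1)
      vals <- matrix(rnorm(n * n), n, n)
      maskv <- matrix(runif(n * n) < 0.4, n, n)
      s2 <- runif(1, 0.5, 2)
      corr <- correct_depth(depth_map(vals, pixel_area = s2),
                            plane_model(0, 0, 0), clip = FALSE)
      got <- integrate_volume(corr, binary_mask(maskv, "rand"))
      ref <- brute_volume(vals, maskv, s2)
      expect_equal(got$volume, ref$volume, tolerance = 1e-12)
      expect_identical(got$n_pixels, ref$n_pixels)
    })
  }
})

test_that("a rasterized spherical cap integrates to its closed-form volume", {
  # cap of height 20 cut from a sphere of radius 50, on a 512 x 512 grid
  cap <- shape_spec("spherical_cap", radius = 50, height = 20,
                    center = c(255.5, 255.5))
  analytic <- pi * 20^2 * (50 - 20 / 3)  # ~54,454
  elev <- trayvol:::shape_elevation(cap, 512, 512)
  corr <- correct_depth(depth_map(elev), plane_model(0, 0, 0))
  est <- integrate_volume(corr, binary_mask(elev > 0, "cap"))
  expect_lt(abs(est$volume / analytic - 1), 0.02)

  # cross-check with numerical integration on a 4x finer grid (s^2 = 1/16)
  cap4 <- shape_spec("spherical_cap", radius = 200, height = 80,
                     center = c(1023.5, 1023.5))
  elev4 <- trayvol:::shape_elevation(cap4, 2048, 2048) / 4
  fine <- sum(elev4) / 16
  expect_lt(abs(est$volume / fine - 1), 0.02)
  expect_lt(abs(fine / analytic - 1), 0.005)
})

test_that("doubling pixel area exactly doubles volumes", {
  withr::with_seed(7, {
    vals <- matrix(abs(rnorm(32 * 32)), 32, 32)
    maskv <- matrix(runif(32 * 32) < 0.5, 32, 32)
  })
  v1 <- integrate_volume(
    correct_depth(depth_map(vals, pixel_area = 1), plane_model(0, 0, 0)),
    binary_mask(maskv))$volume
  v2 <- integrate_volume(
    correct_depth(depth_map(vals, pixel_area = 2), plane_model(0, 0, 0)),
    binary_mask(maskv))$volume
  expect_identical(v2, 2 * v1)
})

test_that("raising depth inside the mask never lowers the volume", {
  withr::with_seed(11, {
    vals <- matrix(rnorm(24 * 24), 24, 24)
    maskv <- matrix(runif(24 * 24) < 0.5, 24, 24)
    base <- integrate_volume(
      correct_depth(depth_map(vals), plane_model(0, 0, 0), clip = FALSE),
      binary_mask(maskv))$volume
    for (i in 1:20) {
      v2 <- vals
      idx <- which(maskv)[sample(sum(maskv), 1)]
      v2[idx] <- v2[idx] + runif(1, 0, 3)
      bumped <- integrate_volume(
        correct_depth(depth_map(v2), plane_model(0, 0, 0), clip = FALSE),
        binary_mask(maskv))$volume
      expect_gte(bumped, base)
    }
  })
})

test_that("polarity normalization flips values about the maximum", {
  d <- depth_map(matrix(c(0.1, 0.9, 0.5, 0.3), 2, 2),
                 polarity = "lower_is_elevated")
  flipped <- normalize_polarity(d, "higher_is_elevated")
  expect_equal(flipped$values, matrix(c(0.8, 0.0, 0.4, 0.6), 2, 2))
  expect_equal(flipped$polarity, "higher_is_elevated")

  const <- normalize_polarity(
    depth_map(matrix(0.2, 3, 3), polarity = "lower_is_elevated"),
    "higher_is_elevated")
  expect_equal(const$values, matrix(0, 3, 3))

  # identity when already in the target polarity
  same <- normalize_polarity(d, "lower_is_elevated")
  expect_identical(same$values, d$values)
})

test_that("depth raster TIFF round trip preserves values and metadata", {
  withr::with_seed(3, vals <- matrix(runif(40 * 30, 0, 25), 40, 30))
  d <- depth_map(vals, pixel_area = 2.5, polarity = "lower_is_elevated")
  f <- withr::local_tempfile(fileext = ".tif")
  write_depth_raster(d, f)
  back <- read_depth_raster(f)
  # 32-bit float storage: relative precision ~1e-7 of the value range
  expect_lt(max(abs(back$values - vals)), 25 * 1e-6)
  expect_equal(back$pixel_area, 2.5)
  expect_equal(back$polarity, "lower_is_elevated")
})
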