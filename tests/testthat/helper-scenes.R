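# Shared fixtures and independent oracles, built in code at test time.

# Standard validation scene: one spherical cap ("rice") on a tilted plate,
# dimensions proportional to the grid so the same scene can be rendered at
# several resolutions.
cap_scene_spec <- function(n = 512, plane = c(0, 0, 0.2), noise_sd = 0,
                           seed = 0L, cap_r = 0.1, cap_h = 0.04) {
  scene_spec(
    grid = c(n, n), plane = plane,
    items = list(shape_spec("spherical_cap", label = "rice",
                            center = c(n * 0.40, n * 0.52),
                            radius = n * cap_r, height = n * cap_h)),
    noise_sd = noise_sd, seed = seed
  )
}

# Asymmetric box ("chicken") next to a cap, for rotation studies.
meal_scene_spec <- function(n = 512, plane = c(0.02, -0.01, 0.2),
                            noise_sd = 0, seed = 0L) {
  scene_spec(
    grid = c(n, n), plane = plane,
    items = list(
      shape_spec("spherical_cap", label = "rice",
                 center = c(n * 0.38, n * 0.50),
                 radius = n * 0.10, height = n * 0.045),
      shape_spec("box", label = "chicken",
                 center = c(n * 0.62, n * 0.50),
                 width = n * 0.14, length = n * 0.07, height = n * 0.05)
    ),
    noise_sd = noise_sd, seed = seed
  )
}

# Reference route: feed a rendered scene's rasters straight to the geometry
# functions (no perception backend involved).
run_scene_direct <- function(scene, band_width = 5, clip = TRUE) {
  rim <- sample_rim(scene$plate_mask, band_width = band_width,
                    exclusion_masks = scene$item_masks)
  rim$z <- scene$depth$values[cbind(rim$y + 1L, rim$x + 1L)]
  plane <- fit_plane(rim)
  corrected <- correct_depth(scene$depth, plane, clip = clip)
  list(
    plane = plane,
    volumes = dplyr::bind_rows(
      lapply(scene$item_masks, function(m) integrate_volume(corrected, m)))
  )
}

# Independent brute-force volume integration: explicit per-pixel double loop.
brute_volume <- function(values, mask_values, pixel_area = 1) {
  total <- 0
  n <- 0L
  for (i in seq_len(nrow(values))) {
    for (j in seq_len(ncol(values))) {
      if (mask_values[i, j] && values[i, j] > 0) {
        total <- total + values[i, j] * pixel_area
        n <- n + 1L
      }
    }
  }
  list(volume = total, n_pixels = n)
}

# Independent two-pass mean/SD/CV (n - 1 denominator).
brute_stats <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  s <- sqrt(ss / (n - 1))
  list(mean = m, sd = s, cv_percent = 100 * s / m)
}

# Independent boundary-band oracle: pixels of the mask whose (2k+1)^2
# neighborhood (out-of-image = outside) is not entirely inside the mask.
brute_band <- function(mask_values, k) {
  h <- nrow(mask_values); w <- ncol(mask_values)
  band <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!mask_values[i, j]) next
      interior <- TRUE
      for (di in -k:k) {
        for (dj in -k:k) {
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > h || jj < 1 || jj > w ||
              !mask_values[ii, jj]) {
            interior <- FALSE
          }
        }
      }
      band[i, j] <- !interior
    }
  }
  band
}

disk_mask <- function(n, cx, cy, r) {
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  y <- matrix(rep(0:(n - 1), times = n), n, n)
  (x - cx)^2 + (y - cy)^2 <= r^2
}
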