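#' Fit a per-food-class density model
#'
#' Maps integrated volume (arbitrary units) to weight (grams) for one food
#' class, from experimental calibration pairs. The default functional form is
#' proportional through the origin — weight = density x volume is the physical
#' premise — with the closed-form least-squares factor
#' `k = sum(w * V) / sum(V^2)`. Affine mode (`weight = k * V + intercept`)
#' fits ordinary least squares and needs at least two pairs.
#'
#' @param pairs Data frame with columns `food_class`, `volume` (> 0, a.u.) and
#'   `weight` (> 0, grams); all rows must share one food class.
#' @param mode `"proportional"` (default) or `"affine"`.
#' @return An object of class `trayvol_density_model` with fields
#'   `food_class`, `k` (g per a.u.), `intercept` (g), `n_pairs`,
#'   `rms_residual` (g).
#' @export
#' @examples
#' pairs <- tibble::tibble(food_class = "rice",
#'                         volume = c(10, 20), weight = c(20, 40))
#' calibrate_density(pairs)$k  # 2
calibrate_density <- function(pairs, mode = c("proportional", "affine")) {
  mode <- match.arg(mode)
  pairs <- as_tibble(pairs)
  stopifnot(all(c("food_class", "volume", "weight") %in% names(pairs)))
  if (length(unique(pairs$food_class)) > 1) {
    abort("calibration pairs must belong to a single food class.")
  }
  if (any(pairs$volume <= 0) || any(pairs$weight <= 0)) {
    abort("calibration volumes and weights must be positive.")
  }
  need <- if (mode == "proportional") 1L else 2L
  if (nrow(pairs) < need) {
    abort(sprintf("mode '%s' needs at least %d calibration pair(s).",
                  mode, need))
  }
  if (mode == "proportional") {
    k <- sum(pairs$weight * pairs$volume) / sum(pairs$volume^2)
    intercept <- 0
  } else {
    fit <- stats::lm(weight ~ volume, data = pairs)
    k <- unname(stats::coef(fit)["volume"])
    intercept <- unname(stats::coef(fit)["(Intercept)"])
    if (k <= 0) warn("affine fit produced a non-positive density factor.")
  }
  resid <- pairs$weight - (k * pairs$volume + intercept)
  structure(
    list(food_class = pairs$food_class[1], k = k, intercept = intercept,
         mode = mode, n_pairs = nrow(pairs),
         rms_residual = sqrt(mean(resid^2))),
    class = "trayvol_density_model"
  )
}

#' @export
print.trayvol_density_model <- function(x, ...) {
  cat(sprintf("<density model '%s'> weight = %.6g * V %+.6g g (%s, n = %d, rms = %.3g g)\n",
              x$food_class, x$k, x$intercept, x$mode, x$n_pairs,
              x$rms_residual))
  invisible(x)
}

#' @method tidy trayvol_density_model
#' @export
tidy.trayvol_density_model <- function(x, ...) {
  tibble(food_class = x$food_class,
         term = c("k", "intercept"),
         estimate = c(x$k, x$intercept))
}

#' @method glance trayvol_density_model
#' @export
glance.trayvol_density_model <- function(x, ...) {
  tibble(food_class = x$food_class, mode = x$mode, n_pairs = x$n_pairs,
         rms_residual = x$rms_residual)
}

#' Convert an integrated volume to a weight
#'
#' Applies the density model: `weight = k * volume + intercept`, floored at
#' zero grams (an affine intercept can otherwise predict negative weight for
#' tiny portions).
#'
#' @param volume Volume(s) in arbitrary units, >= 0.
#' @param model A [calibrate_density()] model.
#' @return Weight(s) in grams.
#' @export
estimate_weight <- function(volume, model) {
  stopifnot(inherits(model, "trayvol_density_model"))
  if (any(volume < 0)) abort("`volume` must be >= 0.")
  pmax(0, model$k * volume + model$intercept)
}

#' Absolute percent error of a weight estimate
#'
#' `100 * |estimated - reference| / reference`, the error margin metric used
#' to validate weight estimation against scale measurements.
#'
#' @param estimated,reference Weights in grams; `reference` must be > 0.
#' @return Percent error (vectorized).
#' @export
percent_error <- function(estimated, reference) {
  if (any(reference <= 0)) abort("`reference` must be positive.")
  100 * abs(estimated - reference) / reference
}

#' Simulate a calibration experiment for one food class
#'
#' Emulates how a volume-to-weight conversion table is built in practice: a
#' graded ladder of portions of the same food, evenly spaced from a base
#' portion volume up to `portion_span` times it, each weighed on a scale.
#' Volumes are the controlled quantity; measured weights carry multiplicative
#' log-normal noise (scale readout plus portioning variability), default 5%.
#'
#' @param n Number of calibration portions; default 20.
#' @param k True density factor, grams per arbitrary volume unit.
#' @param base_volume Volume of the smallest portion (a.u.).
#' @param portion_span Ratio of largest to smallest portion; default 3.
#' @param noise_sd Multiplicative noise standard deviation; default 0.05.
#' @param food_class Label stamped on the pairs.
#' @param seed Integer RNG seed.
#' @return Tibble with columns `food_class`, `volume`, `weight`.
#' @export
#' @examples
#' simulate_calibration_pairs(5, k = 5e-4, seed = 1)
simulate_calibration_pairs <- function(n = 20, k = 5e-4, base_volume = 5e5,
                                       portion_span = 3, noise_sd = 0.05,
                                       food_class = "food", seed = 0L) {
  stopifnot(n >= 1, k > 0, base_volume > 0, portion_span >= 1, noise_sd >= 0)
  volume <- seq(base_volume, base_volume * portion_span, length.out = n)
  weight <- withr::with_seed(
    seed, k * volume * exp(rnorm(n, 0, noise_sd)))
  tibble(food_class = food_class, volume = volume, weight = weight)
}

#' Read calibration pairs / persist density models
#'
#' Calibration pairs live in a CSV with columns `food_class,volume,weight`.
#' Fitted models are persisted as a JSON conversion table (one record per
#' food class), reloadable with [read_density_models()].
#'
#' @param path CSV or JSON file path.
#' @param models Named list of density models (or a single model).
#' @return A tibble of pairs, a named list of models, or `path` invisibly.
#' @export
read_calibration_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("calibration file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("food_class", "volume", "weight") %in% names(df)))
  as_tibble(df)
}

#' @rdname read_calibration_csv
#' @export
write_density_models <- function(models, path) {
  if (inherits(models, "trayvol_density_model")) models <- list(models)
  recs <- purrr::map(models, ~ .x[c("food_class", "k", "intercept", "mode",
                                    "n_pairs", "rms_residual")])
  names(recs) <- purrr::map_chr(recs, "food_class")
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname read_calibration_csv
#' @export
read_density_models <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  purrr::map(recs, ~ structure(.x, class = "trayvol_density_model"))
}
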