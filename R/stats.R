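#' Mean, SD and coefficient of variation of a rotation block
#'
#' One pass of a plate under the camera yields a block of frame-level volume
#' estimates; its robustness summary is the arithmetic mean, the sample
#' standard deviation (n - 1 denominator, appropriate for the small per-pass
#' frame counts) and the coefficient of variation `CV = 100 * SD / mean` in
#' percent — the relative-variability metric used to judge stability across
#' repeated presentations.
#'
#' @param volumes Numeric vector of frame-level volumes (at least 2; mean
#'   must be positive for the CV to be defined).
#' @return One-row tibble with `n`, `mean`, `sd`, `cv_percent`.
#' @export
#' @examples
#' block_stats(c(90, 100, 110))  # cv 10%
block_stats <- function(volumes) {
  if (length(volumes) < 2) abort("sd undefined: need at least 2 values.")
  m <- mean(volumes)
  if (m <= 0) abort("cv undefined: mean must be positive.")
  s <- sd(volumes)
  tibble(n = length(volumes), mean = m, sd = s, cv_percent = 100 * s / m)
}

#' Pooled frame-level coefficient of variation
#'
#' CV over the concatenation of all blocks' frame-level volumes (not over
#' block means): the frame-by-frame fluctuation of the estimator across the
#' whole experiment.
#'
#' @param blocks A list of numeric vectors, or a data frame with columns
#'   `block_id` and `volume`.
#' @return CV in percent.
#' @export
pooled_cv <- function(blocks) {
  pooled <- if (is.data.frame(blocks)) blocks$volume else unlist(blocks)
  block_stats(pooled)$cv_percent
}

#' Proportionality between two volume series
#'
#' Compares two paired series (e.g. the per-rotation mean volumes of two
#' portions of different size): reports the elementwise ratio `b / a` and a
#' sign-consistency fraction — the largest fraction of indices at which the
#' difference `b - a` keeps one sign (ties at zero count toward either sign,
#' so identical series score 1 by convention). Parallel progression of two
#' series, with the heavier portion consistently above, scores 1.
#'
#' @param series_a,series_b Equal-length numeric vectors (length >= 2);
#'   `series_a` must be nonzero everywhere.
#' @return A list with `ratio` (numeric vector) and `sign_consistency`
#'   (fraction in \[0, 1\]).
#' @export
#' @examples
#' proportionality_check(c(1, 2), c(2, 4))
proportionality_check <- function(series_a, series_b) {
  if (length(series_a) != length(series_b) || length(series_a) < 2) {
    abort("series must have equal length >= 2.")
  }
  if (any(series_a == 0)) abort("zero denominator in series_a.")
  d <- series_b - series_a
  n <- length(d)
  list(
    ratio = series_b / series_a,
    sign_consistency = max(sum(d >= 0), sum(d <= 0)) / n
  )
}

#' Build a sequence report from frame-level results
#'
#' Aggregates frame-level volume estimates grouped into rotation blocks into
#' per-block statistics plus the pooled frame-level CV.
#'
#' @param frames Data frame with columns `block_id`, `frame_id`, `label`,
#'   `volume` (one row per item per frame).
#' @param label Food-class label to summarise; default the first present.
#' @return An object of class `trayvol_sequence_report`: `blocks` tibble
#'   (`block_id`, `n_frames`, `mean`, `sd`, `cv_percent`),
#'   `global_cv_percent`, `label`, `frames`.
#' @export
sequence_report <- function(frames, label = NULL) {
  frames <- as_tibble(frames)
  stopifnot(all(c("block_id", "frame_id", "label", "volume") %in%
                  names(frames)))
  label <- label %||% frames$label[1]
  sel <- dplyr::filter(frames, .data$label == !!label)
  if (nrow(sel) == 0) abort(sprintf("no frames with label '%s'.", label))
  blocks <- sel |>
    group_by(.data$block_id) |>
    summarise(n_frames = dplyr::n(),
              mean = mean(.data$volume),
              sd = sd(.data$volume),
              cv_percent = 100 * sd(.data$volume) / mean(.data$volume),
              .groups = "drop")
  structure(
    list(blocks = blocks,
         global_cv_percent = pooled_cv(list(sel$volume)),
         label = label,
         frames = sel),
    class = "trayvol_sequence_report"
  )
}

#' @export
print.trayvol_sequence_report <- function(x, ...) {
  cat(sprintf("<sequence report '%s'> %d block(s), %d frame(s), pooled CV %.2f%%\n",
              x$label, nrow(x$blocks), nrow(x$frames), x$global_cv_percent))
  print(x$blocks)
  invisible(x)
}

#' @method tidy trayvol_sequence_report
#' @export
tidy.trayvol_sequence_report <- function(x, ...) x$blocks

#' @method glance trayvol_sequence_report
#' @export
glance.trayvol_sequence_report <- function(x, ...) {
  tibble(label = x$label, n_blocks = nrow(x$blocks),
         n_frames = nrow(x$frames),
         mean_block_cv_percent = mean(x$blocks$cv_percent),
         global_cv_percent = x$global_cv_percent)
}

#' Plot per-block mean volumes
#'
#' Line-and-point plot of the mean estimated volume per rotation block with
#' +-1 SD ribbons: the visual check that volume estimates stay level across
#' rotations of the same portion.
#'
#' @param object A [sequence_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trayvol_sequence_report
#' @export
autoplot.trayvol_sequence_report <- function(object, ...) {
  df <- object$blocks
  ggplot(df, aes(x = factor(.data$block_id), y = .data$mean, group = 1)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sd,
                    ymax = .data$mean + .data$sd),
                fill = "steelblue", alpha = 0.2) +
    geom_line(color = "steelblue") +
    geom_point(size = 2, color = "steelblue") +
    labs(x = "rotation block", y = "mean volume [a.u.]",
         title = sprintf("Per-rotation volume stability: %s (pooled CV %.1f%%)",
                         object$label, object$global_cv_percent)) +
    theme_minimal()
}
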