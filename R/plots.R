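#' Raster plot of a depth map or corrected depth map
#'
#' Quick visual check of a relative depth raster: image-convention axes
#' (origin top-left), viridis fill. Works for both raw and plane-corrected
#' maps.
#'
#' @param depth A [depth_map()] or the result of [correct_depth()].
#' @param downsample Plot every k-th pixel to keep large rasters light;
#'   default keeps the longer side near 256 px.
#' @return A ggplot object.
#' @export
plot_depth <- function(depth, downsample = NULL) {
  vals <- depth$values
  downsample <- downsample %||% max(1L, ceiling(max(dim(vals)) / 256))
  ri <- seq(1L, nrow(vals), by = downsample)
  ci <- seq(1L, ncol(vals), by = downsample)
  df <- tidyr::expand_grid(y = ri - 1L, x = ci - 1L)
  df$z <- as.vector(t(vals[ri, ci]))
  ggplot(df, aes(.data$x, .data$y, fill = .data$z)) +
    geom_raster() +
    scale_y_reverse() +
    scale_fill_viridis_c(name = "depth") +
    coord_fixed() +
    theme_minimal() +
    labs(x = "x [px]", y = "y [px]")
}
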