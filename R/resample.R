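#' Bilinear raster resampling (align-corners convention)
#'
#' Resamples a raster to a new size by bilinear interpolation with the
#' align-corners mapping `src = dst * (n_src - 1) / (n_dst - 1)`: source and
#' destination corner pixel centers coincide, and every sample position lies
#' inside the source grid. Under this convention a planar raster is resampled
#' exactly (bilinear interpolation is exact for affine fields and no border
#' extrapolation occurs), so base-plane correction commutes with resampling on
#' plane-only scenes.
#'
#' @param values Numeric matrix.
#' @param height,width Target size in pixels (>= 2 each).
#' @return Resampled numeric matrix of the requested size.
#' @export
#' @examples
#' pl <- outer(0:63, 0:63, function(y, x) 0.1 * x - 0.02 * y)
#' max(abs(resample_bilinear(resample_bilinear(pl, 32, 32), 64, 64) - pl))
resample_bilinear <- function(values, height, width) {
  stopifnot(is.matrix(values), height >= 2, width >= 2)
  h0 <- nrow(values); w0 <- ncol(values)
  if (h0 == height && w0 == width) return(values)
  ry <- (seq_len(height) - 1) * (h0 - 1) / (height - 1)
  rx <- (seq_len(width) - 1) * (w0 - 1) / (width - 1)
  y0 <- pmin(floor(ry), h0 - 2); fy <- ry - y0
  x0 <- pmin(floor(rx), w0 - 2); fx <- rx - x0
  i0 <- y0 + 1L; j0 <- x0 + 1L
  a <- values[i0, j0, drop = FALSE]
  b <- values[i0, j0 + 1L, drop = FALSE]
  c_ <- values[i0 + 1L, j0, drop = FALSE]
  d <- values[i0 + 1L, j0 + 1L, drop = FALSE]
  wfx <- matrix(fx, height, width, byrow = TRUE)
  wfy <- matrix(fy, height, width)
  (a * (1 - wfx) + b * wfx) * (1 - wfy) + (c_ * (1 - wfx) + d * wfx) * wfy
}
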