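#' 2D spot-intensity image
#'
#' The basic measurement container: a grid of non-negative intensities with a
#' physical pixel pitch. The matrix is indexed `values[ix, iy]` with the first
#' index along x and the second along y, both increasing; pixel centers sit at
#' `origin + (i - (n + 1)/2) * pixel_pitch` so an odd-sized grid has a pixel
#' exactly at the grid center.
#'
#' @param values Numeric matrix of intensities (device units or relative).
#' @param pixel_pitch Pixel pitch in mm (> 0).
#' @param origin `(x, y)` mm position of the grid center.
#' @param saturated_mask Logical matrix flagging clipped pixels (same shape as
#'   `values`); default all `FALSE`.
#' @param magnification Exposure magnification factor of this image.
#' @param labels Named list of free-form tags (device, energy, position, ...).
#' @return An object of class `"spot_image"`.
#' @export
spot_image <- function(values, pixel_pitch, origin = c(0, 0),
                       saturated_mask = NULL, magnification = 1,
                       labels = list()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!all(is.finite(values))) stop("`values` must be finite")
  if (any(values < 0)) stop("`values` must be non-negative")
  if (!(is.numeric(pixel_pitch) && length(pixel_pitch) == 1L && pixel_pitch > 0))
    stop("`pixel_pitch` must be a single positive number (mm)")
  if (is.null(saturated_mask))
    saturated_mask <- matrix(FALSE, nrow(values), ncol(values))
  if (!identical(dim(saturated_mask), dim(values)))
    stop("`saturated_mask` must have the same shape as `values`")
  structure(
    list(values = values, pixel_pitch = pixel_pitch,
         origin = as.numeric(origin),
         saturated_mask = saturated_mask,
         magnification = magnification, labels = labels),
    class = "spot_image")
}

# pixel-center coordinates of an image-like object (spot_image or composite)
image_axes <- function(img) {
  nx <- nrow(img$values); ny <- ncol(img$values)
  p <- img$pixel_pitch
  org <- if (is.null(img$origin)) c(0, 0) else img$origin
  list(x = org[1] + (seq_len(nx) - (nx + 1) / 2) * p,
       y = org[2] + (seq_len(ny) - (ny + 1) / 2) * p)
}

#' @export
print.spot_image <- function(x, ...) {
  cat(sprintf("Spot image: %d x %d pixels, pitch %.3g mm, magnification %g\n",
              nrow(x$values), ncol(x$values), x$pixel_pitch, x$magnification))
  cat(sprintf("  peak %.4g, %d saturated pixel(s)\n",
              max(x$values), sum(x$saturated_mask)))
  if (length(x$labels))
    cat("  labels:", paste(names(x$labels), unlist(lapply(x$labels, format)),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.spot_image <- function(x, log = TRUE, floor = 1e-5, ...) {
  ax <- image_axes(x)
  z <- x$values / max(x$values)
  if (log) z <- log10(pmax(z, floor))
  graphics::image(ax$x, ax$y, z, asp = 1, xlab = "x (mm)", ylab = "y (mm)",
                  useRaster = TRUE, ...)
  invisible(x)
}
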