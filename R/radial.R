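#' Locate the spot center of an image
#'
#' Sub-pixel peak position, computed as the intensity-weighted centroid of the
#' pixels within the top 5% of the intensity range (value >= 0.95 of the
#' peak). Used as the polar origin for radial averaging.
#'
#' @param image A [composite_profile] or [spot_image()].
#' @return `(x, y)` in mm.
#' @export
find_center <- function(image) {
  vals <- image$values
  valid <- if (!is.null(image$valid_mask)) image$valid_mask else
    matrix(TRUE, nrow(vals), ncol(vals))
  valid <- valid & is.finite(vals)
  if (!any(valid)) stop("image has no valid pixels")
  pk <- max(vals[valid])
  if (pk <= 0) stop("no peak: image is all zero")
  top <- valid & vals >= 0.95 * pk
  if (sum(top) > 0.2 * sum(valid))
    stop("no distinct peak: image is too flat for centering")
  ax <- image_axes(image)
  wsum <- sum(vals[top])
  ix <- row(vals)[top]; iy <- col(vals)[top]
  c(x = sum(ax$x[ix] * vals[top]) / wsum,
    y = sum(ax$y[iy] * vals[top]) / wsum)
}

# polar angle convention: 0 deg along +y (toward the scintillator camera
# neck, i.e. the over-response direction), increasing clockwise. The
# artifact-free quarter opposite the neck is then 135-225 deg.
polar_angle_deg <- function(dx, dy) (atan2(dx, dy) * 180 / pi) %% 360

#' Radially averaged profile of a spot image
#'
#' Converts the image to polar coordinates about `center` and averages the
#' intensity over the pixels whose polar angle falls in `angular_interval`,
#' in radial bins of width `bin_width`. Polar angle is measured from the +y
#' axis, increasing clockwise, so the conventional artifact-free interval for
#' scintillator-CCD images (whose over-response lies on the +y side) is
#' `c(135, 225)` -- the quarter opposite the camera neck. Film images use the
#' full circle `c(0, 360)`.
#'
#' The profile is renormalized so that the innermost region (bins within 1 mm
#' of the center, count-weighted) averages to 1, which is less sensitive to
#' single-pixel noise than dividing by the peak pixel. The exact center pixel
#' (radius 0, undefined angle) is excluded from the averaging.
#'
#' @param image A [composite_profile] or [spot_image()].
#' @param center `(x, y)` mm polar origin; default [find_center()].
#' @param angular_interval `(start, end)` degrees with `0 <= start < end <=
#'   360`; pixels with `start <= angle < end` contribute.
#' @param bin_width Radial bin width in mm (default 0.5).
#' @param max_radius Largest radius included; default the distance from the
#'   center to the nearest grid edge.
#' @return An object of class `"radial_profile"` with fields `bin_radii`
#'   (bin centers, mm), `mean_intensity`, `pixel_counts` and
#'   `angular_interval`.
#' @export
to_radial <- function(image, center = NULL, angular_interval = c(0, 360),
                      bin_width = 0.5, max_radius = NULL) {
  if (!(bin_width > 0)) stop("`bin_width` must be positive")
  a0 <- angular_interval[1]; a1 <- angular_interval[2]
  if (!(a0 >= 0 && a1 <= 360 && a0 < a1))
    stop("`angular_interval` must satisfy 0 <= start < end <= 360")
  if (is.null(center)) center <- find_center(image)
  ax <- image_axes(image)
  vals <- image$values
  valid <- if (!is.null(image$valid_mask)) image$valid_mask else
    matrix(TRUE, nrow(vals), ncol(vals))
  valid <- valid & is.finite(vals)
  dx <- ax$x - center[1]
  dy <- ax$y - center[2]
  rr <- sqrt(outer(dx^2, dy^2, `+`))
  if (is.null(max_radius))
    max_radius <- min(abs(c(ax$x[1] - center[1], ax$x[length(ax$x)] - center[1],
                            ax$y[1] - center[2], ax$y[length(ax$y)] - center[2])))
  theta <- polar_angle_deg(matrix(dx, length(dx), length(dy)),
                           matrix(dy, length(dx), length(dy), byrow = TRUE))
  # deterministic tie-break: pixels exactly on an interval boundary (e.g. the
  # 45-degree diagonals for quarter masks) belong to the interval they start
  theta <- round(theta, 9)
  keep <- valid & rr > 0 & rr < max_radius & theta >= a0 & theta < a1
  if (!any(keep)) stop("empty profile: no valid pixels in the angular interval")
  bin <- floor(rr[keep] / bin_width) + 1L
  nbin <- max(bin)
  sums <- rowsum(vals[keep], bin)
  cnts <- rowsum(rep(1, length(bin)), bin)
  mean_int <- rep(NA_real_, nbin)
  counts <- rep(0, nbin)
  idx <- as.integer(rownames(sums))
  mean_int[idx] <- sums[, 1] / cnts[, 1]
  counts[idx] <- cnts[, 1]
  radii <- (seq_len(nbin) - 0.5) * bin_width
  # peak normalization: count-weighted mean over the sub-1 mm region
  inner <- which(radii < 1 & counts > 0)
  if (!length(inner)) inner <- which(counts > 0)[1]
  pk <- sum(mean_int[inner] * counts[inner]) / sum(counts[inner])
  structure(
    list(bin_radii = radii, mean_intensity = mean_int / pk,
         pixel_counts = counts, angular_interval = c(a0, a1),
         bin_width = bin_width),
    class = "radial_profile")
}

#' Analytic Gaussian comparison profile
#'
#' `exp(-r^2 / 2 sigma^2)` sampled at the given radii, as a
#' `radial_profile`. Used as the single-Gaussian reference against which
#' measured (halo-bearing) profiles are compared.
#'
#' @param sigma Gaussian sigma, mm.
#' @param radii Radii (mm) at which to evaluate.
#' @return A `radial_profile` with peak 1.
#' @export
gaussian_reference_profile <- function(sigma, radii) {
  if (!(sigma > 0)) stop("`sigma` must be positive")
  structure(
    list(bin_radii = radii, mean_intensity = exp(-radii^2 / (2 * sigma^2)),
         pixel_counts = rep(1, length(radii)), angular_interval = c(0, 360),
         bin_width = if (length(radii) > 1) diff(radii[1:2]) else NA_real_),
    class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("Radial profile: %d bins to %.1f mm, angles [%g, %g) deg\n",
              length(x$bin_radii), max(x$bin_radii) + x$bin_width / 2,
              x$angular_interval[1], x$angular_interval[2]))
  invisible(x)
}

#' @export
plot.radial_profile <- function(x, add = FALSE, floor = 1e-6, ...) {
  ok <- is.finite(x$mean_intensity) & x$mean_intensity > floor
  if (add) graphics::lines(x$bin_radii[ok], x$mean_intensity[ok], ...)
  else graphics::plot(x$bin_radii[ok], x$mean_intensity[ok], type = "l",
                      log = "y", xlab = "radius (mm)",
                      ylab = "relative intensity", ...)
  invisible(x)
}

#' Full width of a radial profile at a fractional level
#'
#' Scans outward from the peak bin and locates the first radius where the
#' profile crosses `fraction` times its maximum, interpolating linearly
#' between adjacent bins; the full width is twice that radius.
#'
#' @param profile A `radial_profile`.
#' @param fraction Level in `(0, 1)` (0.5 for FWHM, 0.1 for FW10%, 0.01 for
#'   FW1%).
#' @return Full width in mm.
#' @examples
#' p <- gaussian_reference_profile(5, seq(0, 30, 0.05))
#' width_at_fraction(p, 0.5)  # 2 * 5 * sqrt(2 ln 2) = 11.77 mm
#' @export
width_at_fraction <- function(profile, fraction) {
  stopifnot(inherits(profile, "radial_profile"))
  if (!(fraction > 0 && fraction < 1))
    stop("`fraction` must be in (0, 1)")
  v <- profile$mean_intensity
  r <- profile$bin_radii
  ok <- is.finite(v)
  v <- v[ok]; r <- r[ok]
  if (length(v) < 2) stop("profile too short")
  lev <- fraction * max(v)
  i0 <- which.max(v)
  for (i in i0:(length(v) - 1)) {
    if (v[i] >= lev && v[i + 1] < lev) {
      f <- (v[i] - lev) / (v[i] - v[i + 1])
      return(2 * (r[i] + f * (r[i + 1] - r[i])))
    }
  }
  stop(sprintf("profile never drops below %.3g of its maximum (grid too small)",
               fraction))
}

#' Convert FWHM to Gaussian sigma
#'
#' `sigma = fwhm / (2 sqrt(2 ln 2)) = fwhm / 2.35482`.
#'
#' @param fwhm Full width at half maximum, mm (> 0).
#' @return Sigma in mm.
#' @examples
#' sigma_from_fwhm(1.0)  # 0.425, i.e. a 1 mm FWHM error is ~0.4 mm in sigma
#' @export
sigma_from_fwhm <- function(fwhm) {
  if (any(!is.finite(fwhm) | fwhm <= 0)) stop("`fwhm` must be positive")
  fwhm / (2 * sqrt(2 * log(2)))
}

#' Width summary of a spot image
#'
#' Runs the centering, radial averaging and width extraction chain and returns
#' one summary row: FWHM, FW10%, FW1% and the Gaussian-equivalent sigma
#' (from the FWHM).
#'
#' @inheritParams to_radial
#' @param labels Named list merged into the output row (energy, position,
#'   device, ...); defaults to the image's labels.
#' @return A one-row `data.frame` with columns `fwhm_mm`, `fw10_mm`, `fw1_mm`,
#'   `sigma_mm` plus any label columns.
#' @export
spot_width_summary <- function(image, angular_interval = c(0, 360),
                               bin_width = 0.5, labels = NULL) {
  prof <- to_radial(image, angular_interval = angular_interval,
                    bin_width = bin_width)
  if (is.null(labels)) labels <- image$labels
  lab <- labels[vapply(labels, function(l) length(l) == 1L, logical(1))]
  fwhm <- width_at_fraction(prof, 0.5)
  out <- data.frame(fwhm_mm = fwhm,
                    fw10_mm = width_at_fraction(prof, 0.1),
                    fw1_mm = width_at_fraction(prof, 0.01),
                    sigma_mm = sigma_from_fwhm(fwhm))
  if (length(lab)) out <- cbind(as.data.frame(lab, stringsAsFactors = FALSE), out)
  out
}

#' Device-vs-device width comparison table
#'
#' Builds the standard comparison of a width metric between two devices:
#' per-energy values, raw difference `a - b` (mm) and percent difference
#' `(a - b)/b * 100`, plus their arithmetic means. The second device is the
#' denominator of the percent difference.
#'
#' @param a,b Width summaries: data frames with an `energy_mev` (or `energy`)
#'   column and a `<metric>_mm` column, covering the same energies.
#' @param metric One of `"fwhm"`, `"fw10"`, `"fw1"`.
#' @param device_names Length-2 character vector naming the devices.
#' @return A `comparison_table` (data frame with columns `energy_mev`, the two
#'   device values, `raw_diff_mm`, `percent_diff`) with attributes
#'   `mean_raw_diff` and `mean_percent_diff`. The printed form appends the
#'   Mean row at one decimal.
#' @export
compare_devices <- function(a, b, metric = c("fwhm", "fw10", "fw1"),
                            device_names = c("a", "b")) {
  metric <- match.arg(metric)
  col <- paste0(metric, "_mm")
  getcols <- function(d) {
    if (!is.data.frame(d)) stop("width summaries must be data frames")
    en <- if ("energy_mev" %in% names(d)) d$energy_mev else d$energy
    if (is.null(en)) stop("width summary lacks an energy column")
    if (!col %in% names(d)) stop("width summary lacks column ", col)
    data.frame(energy_mev = en, value = d[[col]])
  }
  da <- getcols(a); db <- getcols(b)
  if (!identical(sort(da$energy_mev), sort(db$energy_mev)))
    stop("energy sets of the two summaries do not match")
  da <- da[order(da$energy_mev), ]
  db <- db[order(db$energy_mev), ]
  raw <- da$value - db$value
  pct <- raw / db$value * 100
  out <- data.frame(energy_mev = da$energy_mev, a = da$value, b = db$value,
                    raw_diff_mm = raw, percent_diff = pct)
  names(out)[2:3] <- device_names
  structure(out, metric = metric,
            mean_raw_diff = mean(raw), mean_percent_diff = mean(pct),
            class = c("comparison_table", "data.frame"))
}

#' @export
print.comparison_table <- function(x, digits = 1, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  shown <- df
  shown[num] <- lapply(df[num], round, digits)
  mean_row <- shown[1, ]
  mean_row[] <- NA
  mean_row$energy_mev <- "Mean"
  mean_row$raw_diff_mm <- round(attr(x, "mean_raw_diff"), digits)
  mean_row$percent_diff <- round(attr(x, "mean_percent_diff"), digits)
  shown$energy_mev <- as.character(shown$energy_mev)
  cat(sprintf("Width comparison (%s), mm and percent:\n", attr(x, "metric")))
  print.data.frame(rbind(shown, mean_row), row.names = FALSE)
  invisible(x)
}
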