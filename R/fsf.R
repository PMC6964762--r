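#' Spot kernel for field superposition
#'
#' Wraps either an analytic [spot_model()] (single or double Gaussian, closed
#' form) or a measured/composited 2D profile ([composite_profile] or
#' [spot_image()], bilinear interpolation) as a kernel that can be evaluated
#' at arbitrary `(x, y)` mm. Grid kernels are re-centered on their fitted peak
#' ([find_center()]), renormalized to 1 at the center, and treated as zero
#' outside `support_radius` (default: the distance from the center to the
#' nearest grid edge) and on invalid pixels.
#'
#' @param x A `spot_model`, `composite_profile` or `spot_image`.
#' @param support_radius Radius (mm) beyond which the kernel is zero;
#'   `Inf` for analytic kernels by default.
#' @return An object of class `"spot_kernel"`.
#' @export
spot_kernel <- function(x, support_radius = NULL) {
  if (inherits(x, "spot_model")) {
    return(structure(
      list(type = "analytic", model = x,
           support_radius = if (is.null(support_radius)) Inf else support_radius),
      class = "spot_kernel"))
  }
  if (!(inherits(x, "composite_profile") || inherits(x, "spot_image")))
    stop("`x` must be a spot_model, composite_profile or spot_image")
  ctr <- find_center(x)
  ax <- image_axes(x)
  vals <- x$values
  valid <- if (!is.null(x$valid_mask)) x$valid_mask else
    matrix(TRUE, nrow(vals), ncol(vals))
  vals[!valid | !is.finite(vals)] <- 0
  if (is.null(support_radius))
    support_radius <- min(abs(c(ax$x[1] - ctr[1], ax$x[length(ax$x)] - ctr[1],
                                ax$y[1] - ctr[2], ax$y[length(ax$y)] - ctr[2])))
  k <- structure(
    list(type = "grid", values = vals, xs = ax$x - ctr[1], ys = ax$y - ctr[2],
         pixel_pitch = x$pixel_pitch, support_radius = support_radius,
         peak = 1),
    class = "spot_kernel")
  pk <- kernel_value(k, 0, 0)
  if (!(pk > 0)) stop("grid kernel has no positive value at its center")
  k$peak <- pk
  k
}

#' Evaluate a spot kernel
#'
#' Vectorized relative intensity of a [spot_kernel()] at offsets `(x, y)` mm
#' from the spot center. Zero outside the support radius.
#'
#' @param kernel A `spot_kernel`.
#' @param x,y Equal-length numeric vectors of offsets in mm.
#' @return Numeric vector of relative intensities (1 at the center).
#' @export
kernel_value <- function(kernel, x, y) {
  stopifnot(inherits(kernel, "spot_kernel"))
  r2 <- x^2 + y^2
  if (kernel$type == "analytic") {
    v <- spot_profile(kernel$model, sqrt(r2))
    v[r2 > kernel$support_radius^2] <- 0
    return(v)
  }
  xs <- kernel$xs; ys <- kernel$ys
  p <- kernel$pixel_pitch
  out <- numeric(length(x))
  inside <- x >= xs[1] & x <= xs[length(xs)] &
            y >= ys[1] & y <= ys[length(ys)] &
            r2 <= kernel$support_radius^2
  if (any(inside)) {
    fx <- (x[inside] - xs[1]) / p
    fy <- (y[inside] - ys[1]) / p
    i0 <- pmin(pmax(floor(fx), 0), length(xs) - 2)
    j0 <- pmin(pmax(floor(fy), 0), length(ys) - 2)
    tx <- fx - i0; ty <- fy - j0
    v <- kernel$values
    n <- nrow(v)
    idx <- function(i, j) (j * n) + i + 1  # zero-based (i, j) to linear
    out[inside] <-
      (1 - tx) * (1 - ty) * v[idx(i0, j0)] +
      tx * (1 - ty) * v[idx(i0 + 1, j0)] +
      (1 - tx) * ty * v[idx(i0, j0 + 1)] +
      tx * ty * v[idx(i0 + 1, j0 + 1)]
  }
  out / kernel$peak
}

#' @export
print.spot_kernel <- function(x, ...) {
  if (x$type == "analytic") {
    cat("Analytic spot kernel\n"); print(x$model)
  } else {
    cat(sprintf("Grid spot kernel: %d x %d pixels, pitch %.3g mm, support %.1f mm\n",
                nrow(x$values), ncol(x$values), x$pixel_pitch,
                x$support_radius))
  }
  invisible(x)
}

#' Scan plan for square fields
#'
#' Field side lengths, spot spacing and the normalization field used for field
#' size factors. Defaults follow standard commissioning plans: sides 20, 32,
#' 40, 60, 100, 140, 200 mm at 2.5 mm spot spacing, normalized to the 100 mm
#' field.
#'
#' @param side_lengths Field side lengths in mm.
#' @param spot_spacing Center-to-center spot spacing in mm.
#' @param normalization_side Side length (mm) of the normalization field; must
#'   be one of `side_lengths`.
#' @return An object of class `"scan_plan"`.
#' @export
scan_plan <- function(side_lengths = c(20, 32, 40, 60, 100, 140, 200),
                      spot_spacing = 2.5, normalization_side = 100) {
  if (!(spot_spacing > 0)) stop("`spot_spacing` must be positive")
  if (!normalization_side %in% side_lengths)
    stop("`normalization_side` must be one of `side_lengths`")
  structure(list(side_lengths = side_lengths, spot_spacing = spot_spacing,
                 normalization_side = normalization_side),
            class = "scan_plan")
}

#' Spot lattice of a square field
#'
#' Square lattice of spot positions symmetric about the origin with
#' `round(side / spacing)` intervals per axis, so the delivered side is that
#' interval count times the spacing (e.g. a nominal 32 mm side at 2.5 mm
#' spacing is delivered as 13 intervals = 32.5 mm with 14 x 14 spots). A spot
#' lies exactly at the origin when the interval count is even.
#'
#' @param side Nominal field side length, mm.
#' @param spacing Spot spacing, mm.
#' @return A matrix of `(x, y)` positions in mm with attribute
#'   `delivered_side`.
#' @export
spot_positions <- function(side, spacing = 2.5) {
  if (!(side > 0) || !(spacing > 0)) stop("side and spacing must be positive")
  nint <- as.integer(round(side / spacing))
  u <- (0:nint - nint / 2) * spacing
  pos <- as.matrix(expand.grid(x = u, y = u, KEEP.OUT.ATTRS = FALSE))
  attr(pos, "delivered_side") <- nint * spacing
  pos
}

# deterministic quadrature nodes covering a disc: a Cartesian grid of pitch h
# clipped to radius <= R (midpoint rule; h defaults to R/10)
disc_samples <- function(radius, h = radius / 10) {
  u <- seq(-radius, radius, by = h)
  g <- expand.grid(x = u, y = u, KEEP.OUT.ATTRS = FALSE)
  g[g$x^2 + g$y^2 <= radius^2, , drop = FALSE]
}

#' Central dose of a scanned field
#'
#' Superimposes the spot kernel over the given spot lattice and evaluates the
#' relative dose at the field center, either as a point value or averaged over
#' a disc of `averaging_radius` (emulating the finite volume of an ion
#' chamber; the disc is sampled on a deterministic uniform grid).
#'
#' @param kernel A [spot_kernel()].
#' @param positions Spot positions, as from [spot_positions()].
#' @param averaging_radius Disc radius in mm, or `NULL` for a point dose.
#' @param point Evaluation point `(x, y)` mm (default the origin).
#' @return Relative dose (kernel-peak units).
#' @export
central_dose <- function(kernel, positions, averaging_radius = NULL,
                         point = c(0, 0)) {
  stopifnot(inherits(kernel, "spot_kernel"))
  if (is.null(dim(positions)) || ncol(positions) != 2 || nrow(positions) == 0)
    stop("`positions` must be a non-empty two-column matrix")
  px <- positions[, 1]; py <- positions[, 2]
  if (is.null(averaging_radius)) {
    d <- sum(kernel_value(kernel, point[1] - px, point[2] - py))
  } else {
    if (!(averaging_radius > 0)) stop("`averaging_radius` must be positive")
    s <- disc_samples(averaging_radius)
    dx <- outer(point[1] + s$x, px, `-`)
    dy <- outer(point[2] + s$y, py, `-`)
    vals <- kernel_value(kernel, as.vector(dx), as.vector(dy))
    d <- mean(rowSums(matrix(vals, nrow(s))))
  }
  if (d <= 0)
    warning("zero dose: field center outside the kernel support for all spots")
  d
}

#' Field size factor curve
#'
#' Computes the FSF for every side length of a [scan_plan()]:
#' `fsf(L) = central_dose(L) / central_dose(normalization_side)`, so the
#' normalization field has FSF exactly 1. For any non-negative kernel the FSF
#' is non-decreasing in side length.
#'
#' @inheritParams central_dose
#' @param plan A [scan_plan()].
#' @param warn_truncation Warn when a field extends beyond the kernel support
#'   radius, so halo tails are truncated (inherent to measured kernels of
#'   finite extent).
#' @return An `fsf_table`: data frame with columns `side_mm` and `fsf`.
#' @examples
#' k <- spot_kernel(spot_model(sigma_core = 3.7))
#' fsf_curve(k, scan_plan())
#' @export
fsf_curve <- function(kernel, plan = scan_plan(), averaging_radius = NULL,
                      warn_truncation = TRUE) {
  stopifnot(inherits(plan, "scan_plan"))
  if (warn_truncation && is.finite(kernel$support_radius)) {
    trunc <- plan$side_lengths[plan$side_lengths / 2 > kernel$support_radius]
    if (length(trunc))
      warning("kernel support (", round(kernel$support_radius, 1),
              " mm) truncates the halo tails of field side(s) ",
              paste(trunc, collapse = ", "), " mm")
  }
  doses <- vapply(plan$side_lengths, function(L)
    central_dose(kernel, spot_positions(L, plan$spot_spacing),
                 averaging_radius), numeric(1))
  ref <- doses[match(plan$normalization_side, plan$side_lengths)]
  structure(data.frame(side_mm = plan$side_lengths, fsf = doses / ref),
            plan = plan, class = c("fsf_table", "data.frame"))
}

#' Closed-form Gaussian field size factor
#'
#' Fine-spacing limit of the lattice superposition for a single-Gaussian spot
#' over a square field:
#' `fsf = erf(side / (2 sqrt(2) sigma))^2 / erf(norm_side / (2 sqrt(2) sigma))^2`.
#' Serves as the analytic oracle for the single-Gaussian surrogate. Note that
#' a lattice of `n + 1` spots at spacing `d` (spanning `n * d`) is the
#' midpoint rule for an integral over side `(n + 1) * d`, so lattice results
#' should be compared against this form evaluated at that effective side.
#'
#' @param sigma Gaussian sigma, mm.
#' @param side Field side, mm.
#' @param normalization_side Normalization field side, mm.
#' @return Dimensionless FSF.
#' @export
gaussian_fsf_closed_form <- function(sigma, side, normalization_side = 100) {
  if (!(sigma > 0)) stop("`sigma` must be positive")
  erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
  (erf(side / (2 * sqrt(2) * sigma)) /
     erf(normalization_side / (2 * sqrt(2) * sigma)))^2
}

#' Percent-error table between two FSF curves
#'
#' Per side length: `(model - reference) / reference * 100`, with the
#' arithmetic mean over sides as an attribute (shown as the Mean row when
#' printed).
#'
#' @param model,reference `fsf_table`s (or data frames with `side_mm` and
#'   `fsf`) covering the same side lengths.
#' @return An `fsf_comparison` data frame with columns `side_mm`, `fsf`,
#'   `reference`, `percent_error` and attribute `mean_error`.
#' @export
percent_error_table <- function(model, reference) {
  need <- function(d) {
    if (!all(c("side_mm", "fsf") %in% names(d)))
      stop("FSF tables need `side_mm` and `fsf` columns")
    d[order(d$side_mm), c("side_mm", "fsf")]
  }
  m <- need(model); r <- need(reference)
  if (!isTRUE(all.equal(m$side_mm, r$side_mm)))
    stop("side lengths of the two FSF tables do not match")
  pe <- (m$fsf - r$fsf) / r$fsf * 100
  structure(
    data.frame(side_mm = m$side_mm, fsf = m$fsf, reference = r$fsf,
               percent_error = pe),
    mean_error = mean(pe),
    class = c("fsf_comparison", "data.frame"))
}

#' @export
print.fsf_comparison <- function(x, digits = 1, ...) {
  df <- as.data.frame(x)
  df$percent_error <- round(df$percent_error, digits)
  df$fsf <- round(df$fsf, 4)
  df$reference <- round(df$reference, 4)
  cat("FSF percent error vs reference:\n")
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("Mean: %.*f%%\n", digits, attr(x, "mean_error")))
  invisible(x)
}

#' @export
print.fsf_table <- function(x, ...) {
  cat("Field size factors:\n")
  df <- as.data.frame(x)
  df$fsf <- round(df$fsf, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.fsf_table <- function(x, add = FALSE, ...) {
  if (add) graphics::lines(x$side_mm, x$fsf, ...)
  else graphics::plot(x$side_mm, x$fsf, type = "b", xlab = "field side (mm)",
                      ylab = "FSF", ...)
  invisible(x)
}
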