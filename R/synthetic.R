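#' Render the ground-truth spot image of a model
#'
#' Evaluates the closed-form two-Gaussian spot of a [spot_model()] on a square
#' pixel grid centered on the lab origin. The image is peak-normalized by
#' construction (value 1 at the model center) and carries no device effects:
#' no clipping, no noise, no artifact.
#'
#' @param model A `spot_model`.
#' @param grid_half_width Half the grid side in mm; must be at least
#'   `5 * sigma_halo` (or `5 * sigma_core` for a halo-free model) so the tails
#'   are contained. Default exactly that bound.
#' @param pixel_pitch Grid pitch in mm (default 0.5, the scintillator-CCD
#'   resolution, used for both devices).
#' @return A [spot_image()] with `magnification = 1` and no saturation flags.
#' @examples
#' img <- make_truth_image(spot_model(5), pixel_pitch = 0.5)
#' max(img$values)  # 1 at the center pixel
#' @export
make_truth_image <- function(model, grid_half_width = NULL, pixel_pitch = 0.5) {
  stopifnot(inherits(model, "spot_model"))
  if (!(pixel_pitch > 0)) stop("`pixel_pitch` must be positive")
  s_out <- if (model$halo_weight > 0) model$sigma_halo else model$sigma_core
  need <- 5 * s_out
  if (is.null(grid_half_width)) grid_half_width <- need
  if (grid_half_width < need - 1e-9)
    stop(sprintf("grid too small: grid_half_width must be at least %.3f mm", need))
  n <- 2L * as.integer(ceiling(grid_half_width / pixel_pitch)) + 1L
  u <- (seq_len(n) - (n + 1) / 2) * pixel_pitch
  dx2 <- (u - model$center[1])^2
  dy2 <- (u - model$center[2])^2
  r <- sqrt(outer(dx2, dy2, `+`))
  vals <- spot_profile(model, r)
  spot_image(vals, pixel_pitch,
             labels = list(device = "truth", energy = model$energy,
                           position = model$position))
}

#' Apply the scintillator-CCD over-response artifact
#'
#' Multiplies pixels on the +y side of the image by an over-response factor
#' that grows as the local relative intensity falls: the factor is 1 at or
#' above 10% of the image peak, `1 + max_fraction` at or below 1% of the peak,
#' and interpolates linearly in log10 relative intensity between those levels.
#' Pixels with y <= 0 are unchanged. This emulates the directional low-dose
#' over-response seen in scintillator-CCD beam imagers, where stray light from
#' the camera-neck side inflates faint signal.
#'
#' @param image A [spot_image()].
#' @param max_fraction Maximum fractional over-response in `[0, 1]`.
#' @return A `spot_image` with the artifact applied.
#' @export
apply_lynx_artifact <- function(image, max_fraction) {
  stopifnot(inherits(image, "spot_image"))
  if (max_fraction < 0 || max_fraction > 1)
    stop("`max_fraction` must be in [0, 1]")
  if (max_fraction == 0) return(image)
  peak <- max(image$values)
  if (peak <= 0) return(image)
  rel <- image$values / peak
  # ramp in log10(rel): 0 at rel >= 0.1, 1 at rel <= 0.01
  ramp <- -1 - log10(rel)
  ramp[ramp < 0 | image$values == 0] <- 0  # zero pixels stay zero regardless
  ramp[ramp > 1] <- 1
  ax <- image_axes(image)
  upper <- ax$y > 0
  fac <- 1 + max_fraction * ramp
  fac[, !upper] <- 1
  image$values <- image$values * fac
  image
}

#' Render one device exposure of a truth image
#'
#' Scales a truth image to a device exposure at the given magnification
#' (the magnification-1 exposure peaks at the device's `peak_scale`), applies
#' the lynx over-response artifact when applicable, adds seeded per-pixel
#' multiplicative Gaussian noise, and clips at the device saturation level,
#' flagging every clipped pixel.
#'
#' @param truth A [spot_image()] ground truth (relative intensities).
#' @param magnification Positive exposure magnification factor.
#' @param device A [device_model()].
#' @param seed Integer seed for the noise (reproducible).
#' @return A `spot_image` in device units with `saturated_mask` set exactly on
#'   pixels whose pre-clip value exceeded the saturation level.
#' @export
render_exposure <- function(truth, magnification, device, seed = 1L) {
  stopifnot(inherits(truth, "spot_image"), inherits(device, "device_model"))
  if (!(magnification > 0)) stop("`magnification` must be positive")
  scale <- device$peak_scale / max(truth$values)
  img <- spot_image(truth$values * magnification * scale, truth$pixel_pitch,
                    origin = truth$origin, magnification = magnification,
                    labels = utils::modifyList(truth$labels,
                                               list(device = device$kind)))
  if (device$kind == "lynx" && device$artifact_max_fraction > 0)
    img <- apply_lynx_artifact(img, device$artifact_max_fraction)
  if (device$noise_fraction > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    eps <- matrix(stats::rnorm(length(img$values), sd = device$noise_fraction),
                  nrow(img$values))
    img$values <- pmax(img$values * (1 + eps), 0)
  }
  sat <- img$values > device$saturation_level
  img$values[sat] <- device$saturation_level
  img$saturated_mask <- sat
  img
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}

#' Ordered multi-exposure set of one spot
#'
#' Low-level constructor. Exposures must share grid geometry; magnification
#' factors must be strictly increasing and start at 1.
#'
#' @param exposures List of [spot_image()]s, one per magnification.
#' @param magnifications Ascending factors, first equal to 1.
#' @param device The [device_model()] used to render them.
#' @param seed Base integer seed recorded for reproducibility.
#' @param truth Optional [spot_image()] ground truth (kept for validation).
#' @return An object of class `"exposure_set"`.
#' @export
exposure_set <- function(exposures, magnifications, device, seed = 1L,
                         truth = NULL) {
  if (!length(exposures)) stop("`exposures` must be non-empty")
  if (length(exposures) != length(magnifications))
    stop("one magnification per exposure required")
  if (magnifications[1] != 1)
    stop("first magnification must be 1")
  if (any(diff(magnifications) <= 0))
    stop("`magnifications` must be strictly increasing")
  dims <- vapply(exposures, function(e) dim(e$values), integer(2))
  if (any(dims != dims[, 1]))
    stop("all exposures must share the same grid shape")
  pitches <- vapply(exposures, `[[`, numeric(1), "pixel_pitch")
  if (any(abs(pitches - pitches[1]) > 1e-12))
    stop("all exposures must share the same pixel pitch")
  structure(
    list(exposures = exposures, magnifications = as.numeric(magnifications),
         device = device, seed = seed, truth = truth),
    class = "exposure_set")
}

#' Generate a seeded synthetic exposure series
#'
#' Renders the ground-truth image of `model` once and exposes it at each
#' magnification factor with the device's clipping, artifact and noise.
#' Exposure k uses seed `seed + k - 1`, so a fixed `seed` reproduces the set
#' bit-identically.
#'
#' @inheritParams make_truth_image
#' @param magnifications Ascending factors starting at 1 (default `c(1, 20,
#'   400)`, the standard pair-magnification series).
#' @param device A [device_model()].
#' @param seed Base integer seed.
#' @return An [exposure_set()] carrying the ground truth.
#' @examples
#' set <- make_exposure_set(spot_model(5, 0.05, 12), device = device_model("film"))
#' length(set$exposures)
#' @export
make_exposure_set <- function(model, magnifications = c(1, 20, 400),
                              device = device_model("film"), seed = 1L,
                              grid_half_width = NULL,
                              pixel_pitch = NULL) {
  stopifnot(inherits(device, "device_model"))
  if (is.null(pixel_pitch)) pixel_pitch <- device$pixel_pitch
  if (magnifications[1] != 1 || any(diff(magnifications) <= 0))
    stop("`magnifications` must be strictly increasing and start at 1")
  truth <- make_truth_image(model, grid_half_width, pixel_pitch)
  exposures <- lapply(seq_along(magnifications), function(k) {
    render_exposure(truth, magnifications[k], device,
                    seed = as.integer(seed) + k - 1L)
  })
  exposure_set(exposures, magnifications, device, seed = seed, truth = truth)
}

#' @export
print.exposure_set <- function(x, ...) {
  cat(sprintf("Exposure set: %d exposure(s), factors %s, device %s, seed %s\n",
              length(x$exposures),
              paste(x$magnifications, collapse = "/"),
              x$device$kind, format(x$seed)))
  nsat <- vapply(x$exposures, function(e) sum(e$saturated_mask), integer(1))
  cat("  saturated pixels per exposure:", paste(nsat, collapse = ", "), "\n")
  invisible(x)
}
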