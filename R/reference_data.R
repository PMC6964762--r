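#' Bundled reference spot-width measurements
#'
#' Published commissioning measurements of in-air spot widths for a clinical
#' proton pencil-beam-scanning system, measured with radiochromic film and a
#' scintillator-CCD imager via the pair-magnification technique: full widths
#' at 50%, 10% and 1% of maximum for beams of 70--242 MeV at the isocenter
#' (Z0) and 300 mm upstream (Z300). The `raw_diff_mm` and `percent_diff`
#' columns are the values printed alongside the measurements (computed from
#' unrounded underlying data, so they can differ from film − lynx of the
#' printed columns by up to the last printed digit).
#'
#' These tables serve two purposes: they are the calibration targets for the
#' synthetic spot models ([default_spot_models()]) and the reference against
#' which analysis output is compared.
#'
#' @param metric Optional filter: `"fwhm"`, `"fw10"` or `"fw1"`.
#' @param position Optional filter: `"Z0"` or `"Z300"`.
#' @return A data frame with columns `metric`, `position`, `energy_mev`,
#'   `film_mm`, `lynx_mm`, `raw_diff_mm`, `percent_diff`.
#' @export
reference_spot_widths <- function(metric = NULL, position = NULL) {
  path <- system.file("extdata", "spot_widths.csv", package = "pbshalo",
                      mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(metric)) d <- d[d$metric %in% metric, ]
  if (!is.null(position)) d <- d[d$position %in% position, ]
  rownames(d) <- NULL
  d
}

#' Bundled reference width summary for one device
#'
#' Pivots [reference_spot_widths()] into the width-summary layout used by
#' [compare_devices()]: one row per energy with `fwhm_mm`, `fw10_mm`,
#' `fw1_mm` and `sigma_mm` columns.
#'
#' @param device `"film"` or `"lynx"`.
#' @param position `"Z0"` or `"Z300"`.
#' @return A width-summary data frame.
#' @export
reference_width_summary <- function(device = c("film", "lynx"),
                                    position = "Z0") {
  device <- match.arg(device)
  col <- paste0(device, "_mm")
  d <- reference_spot_widths(position = position)
  wide <- Reduce(function(a, b) merge(a, b, by = "energy_mev"),
                 lapply(c("fwhm", "fw10", "fw1"), function(m) {
                   sub <- d[d$metric == m, c("energy_mev", col)]
                   names(sub)[2] <- paste0(m, "_mm")
                   sub
                 }))
  wide$sigma_mm <- sigma_from_fwhm(wide$fwhm_mm)
  wide$device <- device
  wide$position <- position
  wide[order(wide$energy_mev), ]
}

#' Bundled reference FSF percent errors at 70 MeV
#'
#' Published percent errors of field-size-factor predictions relative to
#' small-volume ion-chamber measurements at 70 MeV, for a single-Gaussian
#' treatment-planning model (`tps_pct`) and for superposition of measured
#' halo-bearing spot profiles from film and scintillator-CCD data
#' (`film_pct`, `lynx_pct`). The single-Gaussian model overestimates the
#' output of the 2 cm field by 6%.
#'
#' @return A data frame with columns `field_cm`, `tps_pct`, `film_pct`,
#'   `lynx_pct`.
#' @export
reference_fsf_percent_errors <- function() {
  path <- system.file("extdata", "fsf_percent_errors.csv", package = "pbshalo",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
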