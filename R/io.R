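#' Write a spot image to disk
#'
#' Two plain formats are supported, chosen by file extension:
#'
#' * **CSV** (`.csv`): header lines `pixel_pitch_mm`, `origin_x_mm`,
#'   `origin_y_mm`, `magnification` (one `name,value` pair per line, `#`
#'   prefixed), followed by the intensity grid written row-major (one line per
#'   x row) at 9 significant digits. If any pixel is saturated, the mask is
#'   written alongside as `<stem>_mask.csv` (0/1 grid, same header).
#' * **TIFF** (`.tif`/`.tiff`): 32-bit float TIFF. The storage library keeps
#'   samples in `[0, 1]`, so values are scaled by their maximum and the scale,
#'   pitch, origin, magnification and labels are recorded in a JSON sidecar
#'   `<file>.json`; the saturation mask goes to `<stem>_mask.tif` (8-bit).
#'
#' @param image A [spot_image()] (or [composite_profile], written the same
#'   way with invalid pixels as 0).
#' @param path Output path ending in `.csv`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @seealso [read_image()]
#' @export
write_image <- function(image, path) {
  vals <- image$values
  vals[!is.finite(vals)] <- 0
  mask <- if (!is.null(image$saturated_mask)) image$saturated_mask else
    matrix(FALSE, nrow(vals), ncol(vals))
  org <- if (is.null(image$origin)) c(0, 0) else image$origin
  mag <- if (is.null(image$magnification)) 1 else image$magnification
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    write_grid_csv(vals, path, image$pixel_pitch, org, mag)
    if (any(mask))
      write_grid_csv(mask + 0, mask_path(path, "csv"), image$pixel_pitch,
                     org, mag)
  } else if (ext %in% c("tif", "tiff")) {
    scale <- max(vals)
    if (scale <= 0) scale <- 1
    tiff::writeTIFF(t(vals / scale), path, bits.per.sample = 32L,
                    compression = "none")
    meta <- list(pixel_pitch_mm = image$pixel_pitch, origin_x_mm = org[1],
                 origin_y_mm = org[2], magnification = mag, scale = scale,
                 labels = image$labels)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    if (any(mask))
      tiff::writeTIFF(t(mask + 0), mask_path(path, "tif"),
                      bits.per.sample = 8L, compression = "none")
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

mask_path <- function(path, ext) {
  paste0(tools::file_path_sans_ext(path), "_mask.", ext)
}

write_grid_csv <- function(vals, path, pitch, org, mag) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pixel_pitch_mm,%.9g", pitch),
               sprintf("# origin_x_mm,%.9g", org[1]),
               sprintf("# origin_y_mm,%.9g", org[2]),
               sprintf("# magnification,%.9g", mag)), con)
  # one line per x row, 9 significant digits
  writeLines(apply(vals, 1, function(row)
    paste(sprintf("%.9g", row), collapse = ",")), con)
}

read_grid_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  kv <- do.call(rbind, strsplit(sub("^#\\s*", "", hdr), ","))
  meta <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  for (f in c("pixel_pitch_mm", "origin_x_mm", "origin_y_mm"))
    if (!f %in% names(meta))
      stop("format error: CSV grid is missing the `", f, "` header")
  vals <- do.call(rbind, lapply(strsplit(body, ","), as.numeric))
  list(values = vals, meta = meta)
}

#' Read a spot image from disk
#'
#' Reads the CSV-grid or float-TIFF formats written by [write_image()],
#' restoring pixel pitch, origin, magnification and (if a mask sidecar is
#' present) the saturation mask.
#'
#' @param path Path ending in `.csv`, `.tif` or `.tiff`.
#' @return A [spot_image()].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    g <- read_grid_csv(path)
    mask <- NULL
    mp <- mask_path(path, "csv")
    if (file.exists(mp)) mask <- read_grid_csv(mp)$values > 0.5
    return(spot_image(g$values, g$meta[["pixel_pitch_mm"]],
                      origin = c(g$meta[["origin_x_mm"]],
                                 g$meta[["origin_y_mm"]]),
                      saturated_mask = mask,
                      magnification = if ("magnification" %in% names(g$meta))
                        g$meta[["magnification"]] else 1))
  }
  if (!ext %in% c("tif", "tiff")) stop("unsupported image format: .", ext)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("format error: TIFF image is missing its `.json` metadata sidecar")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("pixel_pitch_mm", "origin_x_mm", "origin_y_mm"))
    if (is.null(meta[[f]]))
      stop("format error: TIFF metadata is missing the `", f, "` field")
  vals <- t(tiff::readTIFF(path)) * meta$scale
  mask <- NULL
  mp <- mask_path(path, "tif")
  if (file.exists(mp)) mask <- t(tiff::readTIFF(mp)) > 0.5
  labels <- if (is.null(meta$labels)) list() else as.list(meta$labels)
  spot_image(vals, meta$pixel_pitch_mm,
             origin = c(meta$origin_x_mm, meta$origin_y_mm),
             saturated_mask = mask,
             magnification = if (is.null(meta$magnification)) 1 else
               meta$magnification,
             labels = labels)
}
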