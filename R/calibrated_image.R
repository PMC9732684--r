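#' Calibrated RGB image
#'
#' A plain RGB raster bundled with its physical pixel size, the unit bridge
#' for all geometry in the pipeline. Pixel values are 8-bit (0..255); the
#' array is indexed `[y, x, channel]` with y downward and x rightward
#' (0-based pixel (x, y) maps to array element `[y + 1, x + 1, ]`).
#'
#' @param rgb numeric array height x width x 3, values in 0..255.
#' @param microns_per_pixel physical pixel size in micrometres per pixel.
#' @param id optional identifier string.
#' @return object of class `calibrated_image`.
#' @export
calibrated_image <- function(rgb, microns_per_pixel, id = "image") {
  if (!is.array(rgb) || length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("rgb must be a height x width x 3 array")
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1 ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0)
    stop("microns_per_pixel must be a single positive number")
  structure(
    list(rgb = rgb, microns_per_pixel = microns_per_pixel, id = id),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf(
    "<calibrated_image> '%s': %d x %d px at %.4g um/px (%.3g x %.3g mm)\n",
    x$id, d[2], d[1], x$microns_per_pixel,
    d[2] * x$microns_per_pixel / 1000, d[1] * x$microns_per_pixel / 1000
  ))
  invisible(x)
}

#' Write a calibrated image to PNG/TIFF plus a JSON sidecar
#'
#' The raster goes to `path` (format chosen by extension, `.png` or
#' `.tif`/`.tiff`); `microns_per_pixel` and the id go to `<path>.json`.
#'
#' @param image a [calibrated_image].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_calibrated_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  arr <- image$rgb / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(arr, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to write TIFF files")
    tiff::writeTIFF(arr, where = path)
  } else stop("unsupported image extension: ", ext)
  jsonlite::write_json(
    list(microns_per_pixel = image$microns_per_pixel, id = image$id),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a calibrated image written by [write_calibrated_image]
#'
#' @param path image file path; `<path>.json` must hold the pixel size.
#' @return a [calibrated_image].
#' @export
read_calibrated_image <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing microns_per_pixel sidecar for ", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF files")
    tiff::readTIFF(path)
  } else stop("unsupported image extension: ", ext)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  if (dim(arr)[3] > 3) arr <- arr[, , 1:3]
  calibrated_image(round(arr * 255), meta$microns_per_pixel,
                   id = meta$id %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
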