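#' Expand an epithelium mask by a physical distance
#'
#' Euclidean (disk) dilation: a pixel is in the output iff its Euclidean
#' distance to the epithelium set, converted to micrometres via the pixel
#' size, is at most `distance_um`. The threshold is applied on the
#' real-valued distance transform; the distance in pixels is never rounded
#' first, so the band width does not depend on the pixel size beyond
#' discretisation.
#'
#' @param epithelium a [binary_mask] (role epithelium).
#' @param distance_um expansion distance in micrometres (default 5, the
#'   conventional subepithelial zone width).
#' @return a [binary_mask] with role `"expanded_epithelium"`; always a
#'   superset of the input.
#' @export
expand_epithelium <- function(epithelium, distance_um = 5) {
  stopifnot(inherits(epithelium, "binary_mask"))
  if (!is.numeric(distance_um) || length(distance_um) != 1 || distance_um < 0)
    stop("distance_um must be a single non-negative number")
  m <- epithelium$mask
  if (distance_um == 0 || !any(m)) {
    return(binary_mask(m, epithelium$microns_per_pixel, "expanded_epithelium"))
  }
  # distance of every pixel to the epithelium = distance transform of the
  # complement (EBImage::distmap measures foreground-to-background distance)
  dist_px <- EBImage::distmap(matrix(1L - m * 1L, nrow(m), ncol(m)))
  r_px <- distance_um / epithelium$microns_per_pixel
  out <- matrix(as.numeric(dist_px) <= r_px, nrow(m), ncol(m))
  binary_mask(out, epithelium$microns_per_pixel, "expanded_epithelium")
}

#' Compartment label raster
#'
#' Exclusive labels: 0 background, 1 epithelium, 2 subepithelial band,
#' 3 lamina propria. The three tissue labels partition the tissue mask.
#'
#' @format list with `labels` (integer matrix), `microns_per_pixel`,
#'   `areas_mm2` (named numeric: epithelium, subepithelial, lamina_propria,
#'   tissue).
#' @name compartment_maps
NULL

#' Compartment label constants
#' @export
COMPARTMENT_LEVELS <- c(background = 0L, epithelium = 1L,
                        subepithelial = 2L, lamina_propria = 3L)

#' Build the three mucosal compartments
#'
#' The subepithelial band is the expanded epithelium minus the epithelium,
#' clipped to tissue; lamina propria is the tissue not covered by the
#' expanded epithelium. Labels are exclusive and exhaustive over tissue.
#'
#' @param tissue a [binary_mask] of the whole biopsy.
#' @param epithelium a [binary_mask]; must be a subset of tissue.
#' @param expanded optional precomputed expansion; defaults to
#'   [expand_epithelium] with `distance_um`.
#' @param distance_um expansion distance used when `expanded` is NULL.
#' @return object of class `compartment_maps`.
#' @export
build_compartments <- function(tissue, epithelium, expanded = NULL,
                               distance_um = 5) {
  stopifnot(inherits(tissue, "binary_mask"), inherits(epithelium, "binary_mask"))
  if (!all(dim(tissue$mask) == dim(epithelium$mask)))
    stop("tissue and epithelium rasters differ in size")
  if (any(epithelium$mask & !tissue$mask))
    stop("epithelium mask is not a subset of the tissue mask")
  if (is.null(expanded)) {
    expanded <- expand_epithelium(epithelium, distance_um)
  }
  stopifnot(inherits(expanded, "binary_mask"))
  if (!all(dim(expanded$mask) == dim(tissue$mask)))
    stop("expanded mask raster differs in size")
  if (any(epithelium$mask & !expanded$mask))
    stop("expanded mask must contain the epithelium")

  lab <- matrix(0L, nrow(tissue$mask), ncol(tissue$mask))
  lab[tissue$mask] <- COMPARTMENT_LEVELS[["lamina_propria"]]
  lab[expanded$mask & tissue$mask] <- COMPARTMENT_LEVELS[["subepithelial"]]
  lab[epithelium$mask] <- COMPARTMENT_LEVELS[["epithelium"]]

  px_mm2 <- (tissue$microns_per_pixel / 1000)^2
  tab <- tabulate(lab + 1L, nbins = 4L)
  areas <- c(
    epithelium = tab[2] * px_mm2,
    subepithelial = tab[3] * px_mm2,
    lamina_propria = tab[4] * px_mm2,
    tissue = sum(tab[2:4]) * px_mm2
  )
  structure(
    list(labels = lab, microns_per_pixel = tissue$microns_per_pixel,
         areas_mm2 = areas),
    class = "compartment_maps"
  )
}

#' @export
print.compartment_maps <- function(x, ...) {
  cat(sprintf(
    "<compartment_maps> %d x %d px at %.4g um/px\n  areas (mm2): epithelium %.4g, subepithelial %.4g, lamina propria %.4g\n",
    ncol(x$labels), nrow(x$labels), x$microns_per_pixel,
    x$areas_mm2[["epithelium"]], x$areas_mm2[["subepithelial"]],
    x$areas_mm2[["lamina_propria"]]
  ))
  invisible(x)
}

#' Write compartment labels as a PNG label image plus JSON areas
#' @param maps a `compartment_maps` object.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_compartments <- function(maps, path) {
  stopifnot(inherits(maps, "compartment_maps"))
  png::writePNG(maps$labels / 255, target = path)
  jsonlite::write_json(
    list(microns_per_pixel = maps$microns_per_pixel,
         areas_mm2 = as.list(maps$areas_mm2)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read compartment labels written by [write_compartments]
#' @param path PNG path with `<path>.json` sidecar.
#' @return a `compartment_maps` object.
#' @export
read_compartments <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  lab <- matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
  structure(
    list(labels = lab, microns_per_pixel = meta$microns_per_pixel,
         areas_mm2 = unlist(meta$areas_mm2)),
    class = "compartment_maps"
  )
}
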