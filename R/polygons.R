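#' Rasterise polygon rings into a logical mask
#'
#' Scanline even-odd fill at pixel centers: pixel (x, y) (0-based) is
#' inside iff its center (x + 0.5, y + 0.5) is inside the polygon under
#' the even-odd rule, with half-open handling of edges so shared
#' boundaries never double-fill. Holes are rings like any other: an even
#' crossing count excludes them.
#'
#' @param rings list of n x 2 numeric matrices (x, y vertices, pixel
#'   units, 0-based; rings need not be explicitly closed).
#' @param width,height raster dimensions in pixels.
#' @return logical matrix `[height, width]`.
#' @keywords internal
rasterize_rings <- function(rings, width, height) {
  m <- matrix(FALSE, height, width)
  edges <- do.call(rbind, lapply(rings, function(r) {
    r <- as.matrix(r)
    if (nrow(r) < 3) stop("ring with fewer than 3 vertices")
    if (any(r[1, ] != r[nrow(r), ])) r <- rbind(r, r[1, ])
    cbind(r[-nrow(r), 1], r[-nrow(r), 2], r[-1, 1], r[-1, 2])
  }))
  edges <- edges[edges[, 2] != edges[, 4], , drop = FALSE]
  if (is.null(edges) || nrow(edges) == 0) return(m)
  ylo <- pmin(edges[, 2], edges[, 4])
  yhi <- pmax(edges[, 2], edges[, 4])
  for (row in seq_len(height)) {
    yc <- row - 0.5
    hit <- which(ylo <= yc & yc < yhi)
    if (length(hit) == 0) next
    e <- edges[hit, , drop = FALSE]
    xs <- sort(e[, 1] + (yc - e[, 2]) * (e[, 3] - e[, 1]) / (e[, 4] - e[, 2]))
    for (k in seq(1, length(xs) - 1, by = 2)) {
      j0 <- ceiling(xs[k] - 0.5)
      j1 <- ceiling(xs[k + 1] - 0.5) - 1
      j0 <- max(j0, 0); j1 <- min(j1, width - 1)
      if (j0 <= j1) m[row, (j0 + 1):(j1 + 1)] <- TRUE
    }
  }
  m
}

#' Load polygon annotations (GeoJSON) as a binary mask
#'
#' Reads a GeoJSON FeatureCollection (or bare geometry) of Polygon /
#' MultiPolygon features in pixel coordinates of the target image and
#' rasterises it. Interior rings (holes) are honoured; overlapping
#' features are unioned.
#'
#' @param file path to a GeoJSON file.
#' @param width,height raster dimensions of the target image, pixels.
#' @param microns_per_pixel pixel size of the target image.
#' @param role mask role, default `"epithelium"`.
#' @return a [binary_mask].
#' @export
load_annotation_polygons <- function(file, width, height, microns_per_pixel,
                                     role = "epithelium") {
  gj <- jsonlite::read_json(file, simplifyVector = FALSE)
  geoms <- if (identical(gj$type, "FeatureCollection")) {
    lapply(gj$features, function(f) f$geometry)
  } else if (identical(gj$type, "Feature")) {
    list(gj$geometry)
  } else list(gj)

  ring_to_matrix <- function(ring, idx) {
    pts <- tryCatch(
      do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))[1:2])),
      error = function(e) NULL
    )
    if (is.null(pts) || any(!is.finite(pts)) || nrow(pts) < 3)
      stop("malformed geometry in polygon ", idx)
    pts
  }

  mask <- matrix(FALSE, height, width)
  for (i in seq_along(geoms)) {
    g <- geoms[[i]]
    if (is.null(g) || is.null(g$type)) next
    polys <- switch(g$type,
      Polygon = list(g$coordinates),
      MultiPolygon = g$coordinates,
      stop("unsupported geometry type '", g$type, "' in polygon ", i)
    )
    for (poly in polys) {
      rings <- lapply(poly, ring_to_matrix, idx = i)
      mask <- mask | rasterize_rings(rings, width, height)
    }
  }
  binary_mask(mask, microns_per_pixel, role)
}
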