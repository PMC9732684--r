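#' Nucleus detection settings
#'
#' Defaults mirror the conventional settings for nucleus detection on
#' H-DAB sections: a 0.225 um reference pixel size at which the
#' 125-3,000 px2 nucleus area bounds are defined, a low peak threshold of
#' 0.01 on the normalised hematoxylin landscape, and a 1.5 um cell
#' expansion around each nucleus. Nucleus areas are always evaluated at
#' the reference pixel size regardless of the native image resolution, so
#' the area bounds mean the same physical area everywhere.
#'
#' @param requested_pixel_size reference pixel size in um (area bounds are
#'   in px2 at this scale).
#' @param threshold peak threshold on the max-normalised smoothed
#'   hematoxylin OD map; peaks below it are discarded.
#' @param cell_expansion_um Euclidean expansion from nucleus to cell
#'   boundary, um.
#' @param min_nucleus_area,max_nucleus_area inclusive area bounds in px2
#'   at the reference pixel size.
#' @param min_peak_separation_um minimum distance between detected peaks.
#' @param nucleus_od_threshold smoothed hematoxylin OD above which a pixel
#'   can belong to a nucleus (foreground threshold).
#' @param smooth_sigma_um Gaussian smoothing scale before peak detection.
#' @return object of class `detection_settings`.
#' @export
detection_settings <- function(requested_pixel_size = 0.225,
                               threshold = 0.01,
                               cell_expansion_um = 1.5,
                               min_nucleus_area = 125,
                               max_nucleus_area = 3000,
                               min_peak_separation_um = 3,
                               nucleus_od_threshold = 0.35,
                               smooth_sigma_um = 1.0) {
  if (requested_pixel_size <= 0) stop("requested_pixel_size must be positive")
  if (min_nucleus_area <= 0 || min_nucleus_area >= max_nucleus_area)
    stop("area bounds must satisfy 0 < min < max")
  if (cell_expansion_um < 0) stop("cell expansion must be >= 0")
  structure(
    list(requested_pixel_size = requested_pixel_size, threshold = threshold,
         cell_expansion_um = cell_expansion_um,
         min_nucleus_area = min_nucleus_area,
         max_nucleus_area = max_nucleus_area,
         min_peak_separation_um = min_peak_separation_um,
         nucleus_od_threshold = nucleus_od_threshold,
         smooth_sigma_um = smooth_sigma_um),
    class = "detection_settings"
  )
}

#' Detect cell nuclei on the hematoxylin channel
#'
#' Smoothed-peak detection followed by seeded region growing: the
#' hematoxylin OD map is Gaussian-smoothed, local maxima above the
#' foreground and peak thresholds become markers, and nucleus regions are
#' grown from the markers over the foreground (a marker-based watershed on
#' the OD landscape). Fully deterministic.
#'
#' @param stains a `stain_maps` object.
#' @param settings a [detection_settings].
#' @return object of class `cell_detections`: list with `labels` (integer
#'   nucleus label matrix), `cell_labels` (NULL until [expand_cells]),
#'   `table` (one row per detection: id, x, y (0-based px), npx,
#'   area_um2, area_px2_ref) and calibration/settings.
#' @export
detect_nuclei <- function(stains, settings = detection_settings()) {
  stopifnot(inherits(stains, "stain_maps"),
            inherits(settings, "detection_settings"))
  mpp <- stains$microns_per_pixel
  od <- stains$hematoxylin
  h <- nrow(od); w <- ncol(od)

  sigma <- max(settings$smooth_sigma_um / mpp, 0.5)
  sm <- as.matrix(EBImage::gblur(od, sigma = sigma))
  fg <- sm > settings$nucleus_od_threshold

  empty <- function() {
    structure(list(
      labels = matrix(0L, h, w), cell_labels = NULL,
      table = data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                         npx = integer(0), area_um2 = numeric(0),
                         area_px2_ref = numeric(0)),
      microns_per_pixel = mpp, settings = settings), class = "cell_detections")
  }
  if (!any(fg)) return(empty())

  # local maxima within the minimum peak separation window
  win <- max(3L, 2L * floor(settings$min_peak_separation_um / mpp / 2) + 1L)
  brush <- EBImage::makeBrush(win, shape = "disc")
  mx <- as.matrix(EBImage::dilate(sm, brush))   # grayscale max filter
  peaks <- fg & (sm >= mx - 1e-12) &
    (sm / max(sm) >= settings$threshold)
  if (!any(peaks)) return(empty())

  # plateaus give multi-pixel maxima: one seed per connected peak component
  seed_lab <- EBImage::bwlabel(peaks * 1L)
  seeds <- matrix(0L, h, w)
  n_seeds <- max(seed_lab)
  idx <- which(seed_lab > 0)
  comp <- as.integer(seed_lab)[idx]
  ii <- ((idx - 1L) %% h) + 1L
  jj <- ((idx - 1L) %/% h) + 1L
  ci <- round(tapply(ii, comp, mean))
  cj <- round(tapply(jj, comp, mean))
  seeds[cbind(ci, cj)] <- seq_len(n_seeds)
  # a plateau centroid can fall outside a concave component; fall back to
  # the first plateau pixel
  missing <- setdiff(seq_len(n_seeds), unique(seeds[seeds > 0]))
  for (k in missing) {
    first <- idx[comp == k][1]
    seeds[((first - 1L) %% h) + 1L, ((first - 1L) %/% h) + 1L] <- k
  }

  lab <- EBImage::propagate(sm, seeds = seeds, mask = fg, lambda = 1e-4)
  lab <- matrix(as.integer(lab), h, w)

  npx <- tabulate(lab, nbins = max(lab))
  keep <- which(npx > 0)
  on <- which(lab > 0)
  li <- lab[on]
  yi <- ((on - 1L) %% h)       # 0-based row = y
  xi <- ((on - 1L) %/% h)      # 0-based col = x
  cx <- tapply(xi + 0.5, li, mean)
  cy <- tapply(yi + 0.5, li, mean)
  area_um2 <- npx[keep] * mpp^2
  tab <- data.frame(
    id = keep,
    x = as.numeric(cx[as.character(keep)]),
    y = as.numeric(cy[as.character(keep)]),
    npx = npx[keep],
    area_um2 = area_um2,
    area_px2_ref = area_um2 / settings$requested_pixel_size^2
  )
  rownames(tab) <- NULL
  structure(list(labels = lab, cell_labels = NULL, table = tab,
                 microns_per_pixel = mpp, settings = settings),
            class = "cell_detections")
}

#' @export
print.cell_detections <- function(x, ...) {
  cat(sprintf("<cell_detections> %d detections on %d x %d px at %.4g um/px\n",
              nrow(x$table), ncol(x$labels), nrow(x$labels),
              x$microns_per_pixel))
  if ("class" %in% names(x$table)) print(table(x$table$class))
  invisible(x)
}

#' Filter detections by nucleus area
#'
#' Retains detections whose nucleus area, expressed in px2 at the
#' reference pixel size, lies within the inclusive
#' `[min_nucleus_area, max_nucleus_area]` bounds. Pure and idempotent;
#' order preserved. Removed nuclei are also erased from the label raster.
#'
#' @param detections a `cell_detections`.
#' @param settings a [detection_settings] (defaults to the one stored in
#'   `detections`).
#' @return filtered `cell_detections`.
#' @export
filter_by_area <- function(detections, settings = detections$settings) {
  stopifnot(inherits(detections, "cell_detections"))
  tab <- detections$table
  # inclusive bounds, robust to floating-point noise in the um2 -> px2
  # conversion (areas are conceptually integer pixel counts)
  tol <- 1e-9 * settings$max_nucleus_area
  keep <- tab$area_px2_ref >= settings$min_nucleus_area - tol &
    tab$area_px2_ref <= settings$max_nucleus_area + tol
  dropped <- tab$id[!keep]
  lab <- detections$labels
  if (length(dropped)) lab[lab %in% dropped] <- 0L
  out <- detections
  out$labels <- lab
  out$table <- tab[keep, , drop = FALSE]
  rownames(out$table) <- NULL
  if (!is.null(out$cell_labels) && length(dropped)) {
    cl <- out$cell_labels
    cl[cl %in% dropped] <- 0L
    out$cell_labels <- cl
  }
  out
}

#' Expand nuclei to cell boundaries
#'
#' Each cell region is its nucleus dilated by the Euclidean cell
#' expansion distance; where expansions of neighbouring cells would
#' overlap, pixels go to the nearest nucleus (Voronoi split). Stain
#' features over nucleus and cell regions are measured here.
#'
#' @param detections a `cell_detections`.
#' @param stains the `stain_maps` the detections came from.
#' @param settings a [detection_settings].
#' @return `cell_detections` with `cell_labels` filled and feature columns
#'   (`nucleus_mean_dab`, `nucleus_max_dab`, `cell_mean_dab`,
#'   `cell_max_dab`, `nucleus_mean_hema`, `eccentricity`, `solidity`)
#'   added to the table.
#' @export
expand_cells <- function(detections, stains, settings = detections$settings) {
  stopifnot(inherits(detections, "cell_detections"),
            inherits(stains, "stain_maps"))
  lab <- detections$labels
  h <- nrow(lab); w <- ncol(lab)
  mpp <- detections$microns_per_pixel
  r_px <- settings$cell_expansion_um / mpp

  if (nrow(detections$table) == 0) {
    out <- detections
    out$cell_labels <- matrix(0L, h, w)
    return(out)
  }
  if (r_px > 0) {
    dist_out <- EBImage::distmap(matrix(1L - (lab > 0), h, w))
    within <- matrix(as.numeric(dist_out) <= r_px, h, w)
    # nearest-nucleus growth: with a flat landscape and a large lambda the
    # propagation metric reduces to Euclidean distance (Voronoi partition)
    cell_lab <- EBImage::propagate(matrix(0, h, w), seeds = lab,
                                   mask = within, lambda = 1e8)
    cell_lab <- matrix(as.integer(cell_lab), h, w)
  } else {
    cell_lab <- lab
  }

  tab <- detections$table
  feat <- region_stain_features(lab, cell_lab, tab$id, stains, mpp)
  out <- detections
  out$cell_labels <- cell_lab
  out$table <- cbind(tab, feat)
  out
}

# per-detection stain/shape features over nucleus and cell regions
region_stain_features <- function(nuc_lab, cell_lab, ids, stains, mpp) {
  dab <- as.numeric(stains$dab)
  hema <- as.numeric(stains$hematoxylin)
  h <- nrow(nuc_lab)

  stat_by <- function(labv, values, f, default = 0) {
    on <- which(labv > 0)
    if (!length(on)) return(stats::setNames(numeric(0), character(0)))
    tapply(values[on], labv[on], f)
  }
  nl <- as.integer(nuc_lab); cl <- as.integer(cell_lab)
  nmean <- stat_by(nl, dab, mean); nmax <- stat_by(nl, dab, max)
  cmean <- stat_by(cl, dab, mean); cmax <- stat_by(cl, dab, max)
  hmean <- stat_by(nl, hema, mean)

  key <- as.character(ids)
  pick <- function(s) {
    v <- as.numeric(s[key]); v[is.na(v)] <- 0; v
  }

  ecc <- sol <- numeric(length(ids))
  on <- which(nl > 0)
  li <- nl[on]
  yy <- ((on - 1L) %% h) + 0.5
  xx <- ((on - 1L) %/% h) + 0.5
  split_idx <- split(seq_along(on), li)
  for (k in seq_along(ids)) {
    s <- split_idx[[key[k]]]
    if (is.null(s) || length(s) < 3) { ecc[k] <- 0; sol[k] <- 1; next }
    px <- xx[s]; py <- yy[s]
    cv <- stats::cov(cbind(px, py))
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ecc[k] <- if (ev[1] <= 0) 0 else sqrt(max(0, 1 - ev[2] / ev[1]))
    hull <- grDevices::chull(px, py)
    hx <- px[hull]; hy <- py[hull]
    n <- length(hull)
    hull_area <- abs(sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)) / 2
    # pixel-center hull underestimates the pixelated area; half-perimeter
    # correction keeps solidity near 1 for convex blobs
    per <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
    hull_area <- hull_area + per / 2 + 1
    sol[k] <- min(1, length(s) / hull_area)
  }
  data.frame(
    nucleus_mean_dab = pick(nmean), nucleus_max_dab = pick(nmax),
    cell_mean_dab = pick(cmean), cell_max_dab = pick(cmax),
    nucleus_mean_hema = pick(hmean),
    eccentricity = ecc, solidity = sol
  )
}

#' Feature columns used by the cell classifier
#' @export
CELL_FEATURES <- c("nucleus_mean_dab", "nucleus_max_dab", "cell_mean_dab",
                   "cell_max_dab", "nucleus_mean_hema", "area_um2",
                   "eccentricity", "solidity")
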