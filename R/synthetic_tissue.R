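#' Specification for a synthetic stained-tissue tile
#'
#' Parameters of the ground-truthed H-DAB tile generator. The geometry is
#' deliberately schematic (sinusoidal crypt ribbons inside a rounded
#' biopsy blob): the generator's job is exact labels, not photorealism.
#' Densities are per mm2 of the compartment they name; stain levels are
#' optical densities fed to the Beer-Lambert renderer.
#'
#' @param width,height tile size in pixels.
#' @param microns_per_pixel physical pixel size (um/px).
#' @param n_crypts number of epithelial ribbons.
#' @param crypt_width_um ribbon width (um).
#' @param crypt_amplitude_um,crypt_wavelength_um ribbon sinusoid shape (um).
#' @param cell_density cells/mm2 per compartment, named numeric with
#'   entries `epithelium`, `subepithelial`, `lamina_propria`.
#' @param positive_fraction fraction of stain-positive cells per
#'   compartment (same names), each in \[0, 1\].
#' @param nucleus_radius_um length-2 range of nucleus radii (um).
#' @param artefact_density artefacts/mm2 of tissue; half are rendered as
#'   high-OD specks below the nucleus area filter and half as smears above
#'   it, so the filter's effect is observable.
#' @param hematoxylin_od nuclear hematoxylin optical density.
#' @param dab_od DAB optical density of positive cells.
#' @param epithelium_wash_od,stroma_wash_od faint background hematoxylin
#'   wash inside epithelium / rest of tissue (gives the pixel classifier
#'   texture and makes tissue separable from glass).
#' @param noise_sd Gaussian noise SD added to channel optical densities.
#' @param edge_blur_px Gaussian sigma (px) blurring rendered nuclei edges.
#' @param min_separation_um hard-core minimum distance between planted
#'   nucleus centers.
#' @param stain_matrix stain vectors used for rendering.
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @return object of class `tissue_spec`.
#' @export
tissue_spec <- function(width = 512, height = 512, microns_per_pixel = 0.5,
                        n_crypts = 4, crypt_width_um = 40,
                        crypt_amplitude_um = 15, crypt_wavelength_um = 180,
                        cell_density = c(epithelium = 6000,
                                         subepithelial = 2500,
                                         lamina_propria = 2500),
                        positive_fraction = c(epithelium = 0.10,
                                              subepithelial = 0.30,
                                              lamina_propria = 0.30),
                        nucleus_radius_um = c(2.2, 3.6),
                        artefact_density = 0,
                        hematoxylin_od = 0.8, dab_od = 0.6,
                        epithelium_wash_od = 0.15, stroma_wash_od = 0.05,
                        noise_sd = 0, edge_blur_px = 0.7,
                        min_separation_um = 7,
                        stain_matrix = hdab_stain_matrix(),
                        seed = 1L) {
  comp <- c("epithelium", "subepithelial", "lamina_propria")
  cell_density <- cell_density[comp]
  positive_fraction <- positive_fraction[comp]
  if (width <= 0 || height <= 0) stop("image size must be positive")
  if (microns_per_pixel <= 0) stop("microns_per_pixel must be positive")
  if (any(is.na(cell_density)) || any(cell_density < 0))
    stop("cell densities must be named, non-negative values")
  if (any(is.na(positive_fraction)) || any(positive_fraction < 0) ||
      any(positive_fraction > 1))
    stop("positive fractions must lie in [0, 1]")
  if (any(nucleus_radius_um <= 0)) stop("nucleus radii must be positive")
  structure(
    list(width = as.integer(width), height = as.integer(height),
         microns_per_pixel = microns_per_pixel, n_crypts = n_crypts,
         crypt_width_um = crypt_width_um,
         crypt_amplitude_um = crypt_amplitude_um,
         crypt_wavelength_um = crypt_wavelength_um,
         cell_density = cell_density, positive_fraction = positive_fraction,
         nucleus_radius_um = sort(nucleus_radius_um),
         artefact_density = artefact_density,
         hematoxylin_od = hematoxylin_od, dab_od = dab_od,
         epithelium_wash_od = epithelium_wash_od,
         stroma_wash_od = stroma_wash_od,
         noise_sd = noise_sd, edge_blur_px = edge_blur_px,
         min_separation_um = min_separation_um,
         stain_matrix = stain_matrix, seed = as.integer(seed)),
    class = "tissue_spec"
  )
}

# evaluate code with a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# additively burn an ellipse into a concentration matrix (max-composited)
stamp_ellipse <- function(conc, cx, cy, a_px, b_px, theta, od) {
  h <- nrow(conc); w <- ncol(conc)
  r <- max(a_px, b_px)
  j0 <- max(1L, floor(cx - r) + 1L); j1 <- min(w, ceiling(cx + r) + 1L)
  i0 <- max(1L, floor(cy - r) + 1L); i1 <- min(h, ceiling(cy + r) + 1L)
  if (j0 > j1 || i0 > i1) return(conc)
  jj <- j0:j1; ii <- i0:i1
  xs <- (jj - 0.5) - cx   # pixel-center coordinates, 0-based
  ys <- (ii - 0.5) - cy
  dx <- matrix(xs, length(ii), length(jj), byrow = TRUE)
  dy <- matrix(ys, length(ii), length(jj))
  u <- (dx * cos(theta) + dy * sin(theta)) / a_px
  v <- (-dx * sin(theta) + dy * cos(theta)) / b_px
  inside <- u * u + v * v <= 1
  sub <- conc[ii, jj, drop = FALSE]
  sub[inside] <- pmax(sub[inside], od)
  conc[ii, jj] <- sub
  conc
}

# hard-core sampling of n points among allowed pixels (0-based centers)
sample_points <- function(allowed_idx, h, n, min_sep_px, taken_x, taken_y,
                          max_tries = 100L) {
  xs <- numeric(0); ys <- numeric(0)
  if (n <= 0 || length(allowed_idx) == 0) {
    return(list(x = xs, y = ys))
  }
  ax <- taken_x; ay <- taken_y
  for (k in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      idx <- allowed_idx[sample.int(length(allowed_idx), 1L)]
      i <- ((idx - 1L) %% h) + 1L
      j <- ((idx - 1L) %/% h) + 1L
      px <- (j - 0.5) + stats::runif(1, -0.5, 0.5)
      py <- (i - 0.5) + stats::runif(1, -0.5, 0.5)
      if (length(ax) == 0 ||
          min((ax - px)^2 + (ay - py)^2) >= min_sep_px^2) {
        xs <- c(xs, px); ys <- c(ys, py)
        ax <- c(ax, px); ay <- c(ay, py)
        placed <- TRUE
        break
      }
    }
    if (!placed) break  # compartment saturated at this density
  }
  list(x = xs, y = ys)
}

#' Generate a ground-truthed synthetic H-DAB tissue tile
#'
#' Renders crypt-like epithelium ribbons inside a biopsy blob, plants
#' nuclei with known class and compartment, and produces the RGB image via
#' the Beer-Lambert forward model together with exact truth masks and a
#' cell table. Deterministic for a fixed seed.
#'
#' @param spec a [tissue_spec].
#' @return list with elements `image` (a [calibrated_image]) and `truth`
#'   (list: `cells` data.frame with columns x, y (0-based px), radius_um,
#'   area_um2, class, compartment; `tissue_mask`, `epithelium_mask`
#'   ([binary_mask]); `compartments` (`compartment_maps`)).
#' @export
generate_tissue_image <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    mpp <- spec$microns_per_pixel
    px_mm2 <- (mpp / 1000)^2

    # --- truth geometry -------------------------------------------------
    xs <- matrix((seq_len(w) - 0.5), h, w, byrow = TRUE)
    ys <- matrix((seq_len(h) - 0.5), h, w)
    cx <- w / 2; cy <- h / 2
    rx <- 0.47 * w; ry <- 0.47 * h
    tissue <- (abs((xs - cx) / rx))^4 + (abs((ys - cy) / ry))^4 <= 1

    epi <- matrix(FALSE, h, w)
    if (spec$n_crypts > 0) {
      half_w_px <- (spec$crypt_width_um / 2) / mpp
      amp_px <- spec$crypt_amplitude_um / mpp
      lam_px <- spec$crypt_wavelength_um / mpp
      offsets <- (seq_len(spec$n_crypts) - 0.5) / spec$n_crypts * h
      phases <- stats::runif(spec$n_crypts, 0, 2 * pi)
      for (k in seq_len(spec$n_crypts)) {
        yc <- offsets[k] + amp_px * sin(2 * pi * xs[1, ] / lam_px + phases[k])
        band <- abs(ys - matrix(yc, h, w, byrow = TRUE)) <= half_w_px
        epi <- epi | band
      }
      epi <- epi & tissue
    }
    tissue_mask <- binary_mask(tissue, mpp, "tissue")
    epi_mask <- binary_mask(epi, mpp, "epithelium")
    maps <- build_compartments(tissue_mask, epi_mask, distance_um = 5)

    # --- plant cells ----------------------------------------------------
    min_sep_px <- spec$min_separation_um / mpp
    margin_px <- 2  # keep planted centroids clearly inside their compartment
    cells <- list()
    taken_x <- numeric(0); taken_y <- numeric(0)
    for (comp in c("epithelium", "subepithelial", "lamina_propria")) {
      code <- COMPARTMENT_LEVELS[[comp]]
      region <- maps$labels == code
      n_target <- round(spec$cell_density[[comp]] * sum(region) * px_mm2)
      if (n_target == 0 || !any(region)) next
      interior <- EBImage::distmap(region * 1L)
      allowed <- which(as.numeric(interior) >= margin_px)
      pts <- sample_points(allowed, h, n_target, min_sep_px, taken_x, taken_y)
      n <- length(pts$x)
      if (n == 0) next
      taken_x <- c(taken_x, pts$x); taken_y <- c(taken_y, pts$y)
      r_um <- stats::runif(n, spec$nucleus_radius_um[1], spec$nucleus_radius_um[2])
      elong <- stats::runif(n, 1.0, 1.3)
      cls <- ifelse(stats::runif(n) < spec$positive_fraction[[comp]],
                    "positive", "negative")
      cells[[comp]] <- data.frame(
        x = pts$x, y = pts$y, radius_um = r_um, elong = elong,
        theta = stats::runif(n, 0, pi),
        area_um2 = pi * r_um^2,
        class = cls, compartment = comp,
        stringsAsFactors = FALSE
      )
    }

    # --- artefacts: specks below and smears above the area filter -------
    n_art <- round(spec$artefact_density * sum(tissue) * px_mm2)
    if (n_art > 0) {
      interior <- EBImage::distmap(tissue * 1L)
      allowed <- which(as.numeric(interior) >= margin_px)
      pts <- sample_points(allowed, h, n_art, min_sep_px, taken_x, taken_y)
      n <- length(pts$x)
      if (n > 0) {
        small <- stats::runif(n) < 0.5
        r_um <- ifelse(small, stats::runif(n, 0.5, 0.9),
                       stats::runif(n, 8, 12))
        lab <- c("epithelium", "subepithelial", "lamina_propria", "background")
        at <- maps$labels[cbind(pmin(pmax(round(pts$y + 0.5), 1), h),
                                pmin(pmax(round(pts$x + 0.5), 1), w))]
        cells[["artefact"]] <- data.frame(
          x = pts$x, y = pts$y, radius_um = r_um, elong = 1,
          theta = 0, area_um2 = pi * r_um^2,
          class = "artefact",
          compartment = ifelse(at == 0, "background",
                               names(COMPARTMENT_LEVELS)[at + 1L]),
          stringsAsFactors = FALSE
        )
      }
    }
    cells <- if (length(cells)) do.call(rbind, cells) else
      data.frame(x = numeric(0), y = numeric(0), radius_um = numeric(0),
                 elong = numeric(0), theta = numeric(0),
                 area_um2 = numeric(0), class = character(0),
                 compartment = character(0), stringsAsFactors = FALSE)
    rownames(cells) <- NULL

    # --- render ---------------------------------------------------------
    hema <- matrix(0, h, w)
    hema[tissue] <- spec$stroma_wash_od
    hema[epi] <- spec$epithelium_wash_od
    dab <- matrix(0, h, w)
    if (nrow(cells) > 0) {
      for (i in seq_len(nrow(cells))) {
        r_px <- cells$radius_um[i] / mpp
        a <- r_px * cells$elong[i]; b <- r_px^2 / a
        is_art <- cells$class[i] == "artefact"
        hema <- stamp_ellipse(hema, cells$x[i], cells$y[i], a, b,
                              cells$theta[i],
                              if (is_art) 1.2 else spec$hematoxylin_od)
        if (cells$class[i] == "positive") {
          dab <- stamp_ellipse(dab, cells$x[i], cells$y[i], a, b,
                               cells$theta[i], spec$dab_od)
        } else if (is_art) {
          dab <- stamp_ellipse(dab, cells$x[i], cells$y[i], a, b,
                               cells$theta[i], 0.8)
        }
      }
    }
    if (spec$edge_blur_px > 0) {
      hema <- as.matrix(EBImage::gblur(hema, sigma = spec$edge_blur_px))
      dab <- as.matrix(EBImage::gblur(dab, sigma = spec$edge_blur_px))
      hema[hema < 0] <- 0; dab[dab < 0] <- 0
    }
    rgb <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      od_ch <- spec$stain_matrix[ch, 1] * hema + spec$stain_matrix[ch, 2] * dab
      if (spec$noise_sd > 0) {
        od_ch <- od_ch + stats::rnorm(h * w, 0, spec$noise_sd)
        od_ch[od_ch < 0] <- 0
      }
      rgb[, , ch] <- od_to_intensity(od_ch)
    }

    cells$elong <- NULL; cells$theta <- NULL
    list(
      image = calibrated_image(rgb, mpp, id = sprintf("synthetic-%d", spec$seed)),
      truth = list(cells = cells, tissue_mask = tissue_mask,
                   epithelium_mask = epi_mask, compartments = maps)
    )
  })
}

#' Write synthetic ground truth to plain-text files
#'
#' Cells as CSV (one row per planted cell), masks as 0/255 PNG label
#' images with JSON sidecars.
#'
#' @param truth the `truth` element returned by [generate_tissue_image].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisible vector of written paths.
#' @export
write_ground_truth <- function(truth, dir, prefix = "tile") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    cells = file.path(dir, paste0(prefix, "_cells.csv")),
    tissue = file.path(dir, paste0(prefix, "_tissue.png")),
    epithelium = file.path(dir, paste0(prefix, "_epithelium.png"))
  )
  utils::write.csv(truth$cells, paths["cells"], row.names = FALSE)
  write_mask(truth$tissue_mask, paths["tissue"])
  write_mask(truth$epithelium_mask, paths["epithelium"])
  invisible(paths)
}
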