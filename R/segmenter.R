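#' Per-pixel features for epithelium segmentation
#'
#' Local features computed from the deconvolved stain maps: raw
#' hematoxylin and DAB optical densities, Gaussian-smoothed versions at
#' several physical scales, and local standard deviation (texture) of the
#' hematoxylin channel at the same scales.
#'
#' @param stains a `stain_maps` object.
#' @param scales_um smoothing scales in micrometres.
#' @return numeric matrix, one row per pixel (column-major raster order),
#'   named feature columns.
#' @export
pixel_features <- function(stains, scales_um = c(1, 3, 6)) {
  stopifnot(inherits(stains, "stain_maps"))
  mpp <- stains$microns_per_pixel
  h <- nrow(stains$hematoxylin); w <- ncol(stains$hematoxylin)
  cols <- list(hema = as.numeric(stains$hematoxylin),
               dab = as.numeric(stains$dab))
  for (s in scales_um) {
    sigma <- max(s / mpp, 0.5)
    sm <- as.matrix(EBImage::gblur(stains$hematoxylin, sigma = sigma))
    sm2 <- as.matrix(EBImage::gblur(stains$hematoxylin^2, sigma = sigma))
    local_var <- pmax(sm2 - sm^2, 0)
    smd <- as.matrix(EBImage::gblur(stains$dab, sigma = sigma))
    cols[[sprintf("hema_s%g", s)]] <- as.numeric(sm)
    cols[[sprintf("hema_sd%g", s)]] <- as.numeric(sqrt(local_var))
    cols[[sprintf("dab_s%g", s)]] <- as.numeric(smd)
  }
  do.call(cbind, cols)
}

#' Train the epithelium pixel classifier
#'
#' A seeded random-forest classifier over [pixel_features], trained on
#' images with matching epithelium annotation masks. This fills the same
#' input/output contract as a trained segmentation network: images in,
#' epithelium probability mask out.
#'
#' @param images list of [calibrated_image].
#' @param epithelium_masks list of [binary_mask], aligned with `images`.
#' @param stain_matrix deconvolution matrix used for features.
#' @param scales_um feature scales (um).
#' @param n_pixels_per_image training pixels sampled per image (balanced
#'   between classes where possible).
#' @param num_trees random-forest size.
#' @param seed RNG seed controlling sampling and forest growth.
#' @return object of class `epithelium_segmenter`.
#' @export
train_epithelium_segmenter <- function(images, epithelium_masks,
                                       stain_matrix = hdab_stain_matrix(),
                                       scales_um = c(1, 3, 6),
                                       n_pixels_per_image = 4000,
                                       num_trees = 100, seed = 1L) {
  if (length(images) < 1) stop("at least one annotated image is required")
  if (length(images) != length(epithelium_masks))
    stop("images and masks differ in number")
  feats <- list(); labs <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]; msk <- epithelium_masks[[i]]
    stopifnot(inherits(img, "calibrated_image"), inherits(msk, "binary_mask"))
    if (!all(dim(msk$mask) == dim(img$rgb)[1:2]))
      stop("annotation mask ", i, " does not align with its image")
    st <- separate_stains(img, stain_matrix)
    f <- pixel_features(st, scales_um)
    y <- as.numeric(msk$mask)
    idx <- with_seed(seed + i, {
      pos <- which(y == 1); neg <- which(y == 0)
      n_half <- ceiling(n_pixels_per_image / 2)
      c(if (length(pos)) sample(pos, min(n_half, length(pos))),
        if (length(neg)) sample(neg, min(n_half, length(neg))))
    })
    feats[[i]] <- f[idx, , drop = FALSE]
    labs[[i]] <- y[idx]
  }
  x <- do.call(rbind, feats)
  y <- factor(unlist(labs), levels = c(0, 1))
  if (length(unique(y[!is.na(y)])) < 2)
    stop("degenerate training set: annotations contain a single class")
  df <- data.frame(x, .class = y)
  rf <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = num_trees, probability = TRUE,
    seed = seed, num.threads = 1
  )
  structure(
    list(format_version = 1L, forest = rf,
         stain_matrix = stain_matrix, scales_um = scales_um,
         feature_names = colnames(x), seed = seed),
    class = "epithelium_segmenter"
  )
}

#' Predict an epithelium mask
#'
#' Applies the trained pixel classifier, thresholds the epithelium
#' probability at 0.5, restricts the result to the tissue mask, and
#' post-processes (hole filling, removal of components below
#' `min_area_mm2`).
#'
#' @param image a [calibrated_image].
#' @param model an `epithelium_segmenter`.
#' @param tissue optional [binary_mask]; computed with [segment_tissue]
#'   when NULL.
#' @param min_area_mm2 minimum connected-component area kept.
#' @return a [binary_mask] with role `"epithelium"`.
#' @export
predict_epithelium <- function(image, model, tissue = NULL,
                               min_area_mm2 = 0.0005) {
  stopifnot(inherits(image, "calibrated_image"))
  if (!inherits(model, "epithelium_segmenter") || is.null(model$forest))
    stop("model is not a trained epithelium segmenter")
  st <- separate_stains(image, model$stain_matrix)
  f <- pixel_features(st, model$scales_um)
  if (!identical(colnames(f), model$feature_names))
    stop("feature schema mismatch between model and image")
  pr <- predict(model$forest, data = data.frame(f), num.threads = 1)$predictions
  d <- dim(image$rgb)
  m <- matrix(pr[, "1"] >= 0.5, d[1], d[2])
  if (is.null(tissue)) tissue <- segment_tissue(st)
  m <- m & tissue$mask
  out <- clean_mask(binary_mask(m, image$microns_per_pixel, "epithelium"),
                    min_area_mm2 = min_area_mm2)
  binary_mask(out$mask, image$microns_per_pixel, "epithelium")
}

#' Save / load a trained segmenter
#'
#' Serialised with a format-version field; reloading reproduces identical
#' predictions.
#'
#' @param model an `epithelium_segmenter`.
#' @param path file path (.rds).
#' @return `path` / the reloaded model.
#' @export
save_segmenter <- function(model, path) {
  stopifnot(inherits(model, "epithelium_segmenter"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "epithelium_segmenter") ||
      is.null(model$format_version))
    stop("file does not contain a serialised epithelium segmenter")
  model
}
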