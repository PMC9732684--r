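#' Standard H-DAB stain matrix
#'
#' Returns the widely used hematoxylin / DAB reference stain vectors in
#' RGB optical-density space (unit column vectors). Staining protocols vary,
#' so deconvolution vectors are always a parameter; these defaults are the
#' published reference values for the H-DAB combination.
#'
#' @param third how to complete the third column when only two stains are
#'   present: `"cross"` (normalised cross product of the first two, the
#'   standard complement) or `"none"` to return a 3 x 2 matrix.
#' @return a 3 x 3 (or 3 x 2) matrix with unit-norm columns named
#'   `hematoxylin`, `dab` (and `residual`).
#' @export
hdab_stain_matrix <- function(third = c("cross", "none")) {
  third <- match.arg(third)
  m <- cbind(
    hematoxylin = c(0.65, 0.70, 0.29),
    dab         = c(0.27, 0.57, 0.78)
  )
  m <- apply(m, 2, function(v) v / sqrt(sum(v^2)))
  if (third == "cross") m <- complete_stain_matrix(m)
  m
}

#' Complete a two-stain matrix with a residual third vector
#'
#' The third column is the normalised cross product of the two stain
#' vectors, orthogonal to both, so that the 3 x 3 system is invertible and
#' the residual channel absorbs colour not explained by either stain.
#'
#' @param m 3 x 2 matrix of unit stain vectors.
#' @return 3 x 3 matrix with the added `residual` column.
#' @export
complete_stain_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == 3, ncol(m) == 2)
  a <- m[, 1]; b <- m[, 2]
  cr <- c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
  n <- sqrt(sum(cr^2))
  if (n < 1e-8) stop("stain vectors are collinear; cannot complete the matrix")
  out <- cbind(m, residual = cr / n)
  colnames(out) <- c(colnames(m)[1:2], "residual")
  out
}

#' Convert 8-bit intensities to optical density
#'
#' OD = -log10(max(I, 1) / 255) per channel. The floor of 1 avoids log(0)
#' for fully saturated dark pixels.
#'
#' @param x numeric vector/array of intensities in 0..255.
#' @return optical densities (same shape), all >= 0.
#' @export
intensity_to_od <- function(x) {
  -log10(pmax(x, 1) / 255)
}

#' Convert optical density to 8-bit transmitted intensity
#'
#' The Beer-Lambert forward model: I = 255 * 10^(-OD), rounded to the
#' nearest 8-bit level.
#'
#' @param od numeric vector/array of optical densities (>= 0).
#' @param quantize round to integer 8-bit levels (default TRUE).
#' @return intensities in 0..255.
#' @export
od_to_intensity <- function(od, quantize = TRUE) {
  i <- 255 * 10^(-od)
  if (quantize) i <- round(i)
  pmin(pmax(i, 0), 255)
}

#' Render per-stain concentration maps to an RGB image
#'
#' Forward Beer-Lambert model used by the synthetic-tissue generator:
#' per-pixel channel OD is the stain matrix times the stain concentration
#' vector, and transmitted intensity is 255 * 10^(-OD).
#'
#' @param concentrations list of numeric matrices (one per stain, equal
#'   dims), in OD units.
#' @param stain_matrix matrix with one unit column per element of
#'   `concentrations` (a third residual column is ignored if unused).
#' @param quantize round intensities to 8-bit levels.
#' @return numeric array height x width x 3 with values in 0..255.
#' @export
render_stains <- function(concentrations, stain_matrix, quantize = TRUE) {
  stopifnot(is.list(concentrations), length(concentrations) >= 1)
  d <- dim(concentrations[[1]])
  rgb <- array(0, dim = c(d[1], d[2], 3))
  for (k in seq_along(concentrations)) {
    ck <- concentrations[[k]]
    stopifnot(all(dim(ck) == d))
    for (ch in 1:3) rgb[, , ch] <- rgb[, , ch] + stain_matrix[ch, k] * ck
  }
  for (ch in 1:3) rgb[, , ch] <- od_to_intensity(rgb[, , ch], quantize = quantize)
  rgb
}

#' Separate stains by colour deconvolution
#'
#' Converts the RGB image to optical density (`intensity_to_od`) and solves
#' the linear unmixing problem per pixel with the pseudo-inverse of the
#' stain matrix. Negative concentrations (pixels outside the stain gamut)
#' are clamped to zero.
#'
#' @param image a [calibrated_image].
#' @param stain_matrix 3 x 2 or 3 x 3 matrix of unit stain column vectors;
#'   a 3 x 2 matrix is completed with [complete_stain_matrix].
#' @return an object of class `stain_maps`: list with `hematoxylin` and
#'   `dab` OD matrices, the `residual` matrix, the `stain_matrix` used and
#'   `microns_per_pixel`.
#' @export
separate_stains <- function(image, stain_matrix = hdab_stain_matrix()) {
  stopifnot(inherits(image, "calibrated_image"))
  if (ncol(stain_matrix) == 2) stain_matrix <- complete_stain_matrix(stain_matrix)
  stopifnot(nrow(stain_matrix) == 3, ncol(stain_matrix) == 3)
  norms <- sqrt(colSums(stain_matrix^2))
  if (any(abs(norms - 1) > 1e-6)) stop("stain matrix columns must have unit norm")
  if (abs(det(stain_matrix)) < 1e-8) stop("stain vectors are collinear (singular stain matrix)")

  d <- dim(image$rgb)
  od <- matrix(intensity_to_od(image$rgb), nrow = d[1] * d[2], ncol = 3)
  conc <- od %*% t(solve(stain_matrix))
  conc[conc < 0] <- 0
  out <- list(
    hematoxylin = matrix(conc[, 1], d[1], d[2]),
    dab = matrix(conc[, 2], d[1], d[2]),
    residual = matrix(conc[, 3], d[1], d[2]),
    stain_matrix = stain_matrix,
    microns_per_pixel = image$microns_per_pixel
  )
  class(out) <- "stain_maps"
  out
}

#' @export
print.stain_maps <- function(x, ...) {
  cat(sprintf(
    "<stain_maps> %d x %d px, %.4g um/px; mean OD hematoxylin %.3f, DAB %.3f\n",
    nrow(x$hematoxylin), ncol(x$hematoxylin), x$microns_per_pixel,
    mean(x$hematoxylin), mean(x$dab)
  ))
  invisible(x)
}
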