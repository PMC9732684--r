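#' Assign detections to mucosal compartments
#'
#' Each detection takes the compartment label of the compartment map at
#' its nucleus centroid pixel (a single label per cell; cells straddling
#' the basement membrane get the centroid's label). Detections whose
#' centroid falls on background are labelled `"background"` and are
#' excluded from all counts.
#'
#' @param detections a `cell_detections`.
#' @param maps a `compartment_maps` with the same raster.
#' @return `cell_detections` with a `compartment` column.
#' @export
assign_compartment <- function(detections, maps) {
  stopifnot(inherits(detections, "cell_detections"),
            inherits(maps, "compartment_maps"))
  tab <- detections$table
  h <- nrow(maps$labels); w <- ncol(maps$labels)
  out <- detections
  if (nrow(tab) == 0) {
    out$table$compartment <- character(0)
    return(out)
  }
  i <- floor(tab$y) + 1L
  j <- floor(tab$x) + 1L
  if (any(i < 1 | i > h | j < 1 | j > w))
    stop("detection centroid outside the raster")
  code <- maps$labels[cbind(i, j)]
  out$table$compartment <- names(COMPARTMENT_LEVELS)[match(code, COMPARTMENT_LEVELS)]
  out
}

#' Per-biopsy, per-stain quantification
#'
#' Tallies classified detections into the three compartments. Artefacts
#' and background-centroid detections are excluded. Counts obey the
#' conservation identity: epithelial + subepithelial + lamina propria
#' positives equal whole-mucosa positives exactly, because the
#' compartments partition the tissue.
#'
#' @param detections classified `cell_detections` with compartments
#'   assigned.
#' @param maps the `compartment_maps` used for assignment (provides
#'   areas).
#' @param stain `"CD3"` or `"TCRdelta"`.
#' @param biopsy_id identifier for the section.
#' @return object of class `biopsy_quant` (a one-row data.frame with raw
#'   counts, denominators and normalised measures).
#' @export
tabulate_biopsy <- function(detections, maps, stain, biopsy_id = "biopsy") {
  stopifnot(inherits(detections, "cell_detections"),
            inherits(maps, "compartment_maps"))
  tab <- detections$table
  if (nrow(tab) > 0 && !("class" %in% names(tab)))
    stop("detections must be classified before tabulation")
  if (nrow(tab) > 0 && !("compartment" %in% names(tab)))
    stop("detections must have compartments assigned before tabulation")
  cells <- if (nrow(tab) == 0) {
    data.frame(class = character(0), compartment = character(0))
  } else {
    tab[tab$class != "artefact" & tab$compartment != "background", ,
        drop = FALSE]
  }
  cnt <- function(comp, cls = NULL) {
    sel <- cells$compartment == comp
    if (!is.null(cls)) sel <- sel & cells$class == cls
    sum(sel)
  }
  q <- data.frame(
    biopsy_id = biopsy_id, stain = stain,
    epithelial_positive = cnt("epithelium", "positive"),
    epithelial_total = cnt("epithelium"),
    subepithelial_positive = cnt("subepithelial", "positive"),
    lamina_positive = cnt("lamina_propria", "positive"),
    mucosa_positive = sum(cells$class == "positive"),
    mucosa_area_mm2 = unname(maps$areas_mm2[["tissue"]]),
    stringsAsFactors = FALSE
  )
  class(q) <- c("biopsy_quant", class(q))
  normalize_counts(q)
}

#' Derived normalised measures for a biopsy
#'
#' Intraepithelial and subepithelial positives per 100 epithelial cells;
#' lamina propria positives per mm2 of mucosa. A zero denominator flags
#' the measure as missing (NA), never as 0.
#'
#' @param q a `biopsy_quant` row (or data.frame of them).
#' @return `q` with columns `iel_per100`, `sub_per100`, `lp_per_mm2`.
#' @export
normalize_counts <- function(q) {
  stopifnot(all(c("epithelial_positive", "epithelial_total",
                  "subepithelial_positive", "lamina_positive",
                  "mucosa_area_mm2") %in% names(q)))
  q$iel_per100 <- ifelse(q$epithelial_total > 0,
                         100 * q$epithelial_positive / q$epithelial_total, NA_real_)
  q$sub_per100 <- ifelse(q$epithelial_total > 0,
                         100 * q$subepithelial_positive / q$epithelial_total, NA_real_)
  q$lp_per_mm2 <- ifelse(q$mucosa_area_mm2 > 0,
                         q$lamina_positive / q$mucosa_area_mm2, NA_real_)
  q
}

#' Gamma-delta / CD3 ratio per compartment
#'
#' Ratio (in percent) of the TCRdelta to CD3 normalised measures of the
#' same biopsy, computed compartment-wise on matching normalisations. The
#' two stains come from parallel sections, so ratios are taken on the
#' normalised measures rather than raw counts. Missing when the CD3
#' measure is zero or missing.
#'
#' @param gd `biopsy_quant` for the TCRdelta stain.
#' @param cd3 `biopsy_quant` for the CD3 stain of the same biopsy.
#' @return data.frame with `biopsy_id`, `compartment`, `ratio_pct`.
#' @export
compute_gd_cd3_ratio <- function(gd, cd3) {
  if (!identical(gd$biopsy_id, cd3$biopsy_id))
    stop("biopsy id mismatch between the two stains")
  ratio1 <- function(num, den) {
    if (is.na(den) || den == 0 || is.na(num)) NA_real_ else 100 * num / den
  }
  data.frame(
    biopsy_id = gd$biopsy_id,
    compartment = COMPARTMENTS,
    ratio_pct = c(ratio1(gd$iel_per100, cd3$iel_per100),
                  ratio1(gd$sub_per100, cd3$sub_per100),
                  ratio1(gd$lp_per_mm2, cd3$lp_per_mm2)),
    stringsAsFactors = FALSE
  )
}

#' Quantify one stained image end to end
#'
#' Orchestrates the per-image pipeline: stain separation, tissue mask,
#' epithelium mask (trained segmenter or supplied annotation), the 5 um
#' compartment construction, nucleus detection, area filtering, cell
#' expansion, classification, compartment assignment and tabulation.
#'
#' @param image a [calibrated_image].
#' @param classifier a trained cell classifier.
#' @param segmenter a trained epithelium segmenter, or NULL when
#'   `epithelium` is given.
#' @param epithelium optional [binary_mask] annotation to use instead of
#'   the segmenter.
#' @param stain stain name recorded in the output.
#' @param biopsy_id identifier recorded in the output.
#' @param settings a [detection_settings].
#' @param stain_matrix deconvolution matrix.
#' @param expansion_um subepithelial band width, um.
#' @return list with `quant` (`biopsy_quant` row), `detections`, `maps`,
#'   `tissue`, `epithelium`.
#' @export
quantify_image <- function(image, classifier, segmenter = NULL,
                           epithelium = NULL, stain = "CD3",
                           biopsy_id = image$id,
                           settings = detection_settings(),
                           stain_matrix = hdab_stain_matrix(),
                           expansion_um = 5) {
  stopifnot(inherits(image, "calibrated_image"))
  st <- separate_stains(image, stain_matrix)
  tissue <- segment_tissue(st)
  if (is.null(epithelium)) {
    if (is.null(segmenter)) stop("either a segmenter or an epithelium mask is required")
    epithelium <- predict_epithelium(image, segmenter, tissue = tissue)
  }
  epithelium$mask <- epithelium$mask & tissue$mask
  maps <- build_compartments(tissue, epithelium, distance_um = expansion_um)
  det <- detect_nuclei(st, settings)
  det <- filter_by_area(det, settings)
  det <- expand_cells(det, st, settings)
  det <- classify_cells(det, classifier)
  det <- assign_compartment(det, maps)
  quant <- tabulate_biopsy(det, maps, stain = stain, biopsy_id = biopsy_id)
  list(quant = quant, detections = det, maps = maps,
       tissue = tissue, epithelium = epithelium)
}
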