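#' Train the three-class cell classifier
#'
#' A seeded random-forest ("random trees") object classifier over the
#' detection feature vector, separating IHC positive cells, IHC negative
#' cells and artefacts/false detections.
#'
#' @param features data.frame containing the [CELL_FEATURES] columns and a
#'   `class` column with values among `"positive"`, `"negative"`,
#'   `"artefact"`.
#' @param num_trees forest size.
#' @param seed RNG seed; retraining with the same seed and data gives
#'   identical predictions.
#' @return object of class `cell_classifier`.
#' @export
train_cell_classifier <- function(features, num_trees = 200, seed = 1L) {
  need <- c(CELL_FEATURES, "class")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cls <- factor(features$class, levels = c("positive", "negative", "artefact"))
  if (any(is.na(cls))) stop("unknown class labels in training data")
  if (length(unique(cls)) < 2)
    stop("degenerate training set: a single class is present")
  x <- features[, CELL_FEATURES, drop = FALSE]
  if (!all(vapply(x, function(v) all(is.finite(v)), logical(1))))
    stop("non-finite feature values in training data")
  df <- data.frame(x, .class = droplevels(cls))
  rf <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = num_trees, seed = seed, num.threads = 1
  )
  structure(
    list(format_version = 1L, forest = rf, feature_names = CELL_FEATURES,
         classes = levels(droplevels(cls)), seed = seed),
    class = "cell_classifier"
  )
}

#' Classify detections as positive / negative / artefact
#'
#' Every detection gets exactly one class. Artefacts are retained in the
#' table (for inspection) but are excluded from all downstream counts by
#' the quantification step.
#'
#' @param detections a `cell_detections` with feature columns (run
#'   [expand_cells] first).
#' @param classifier a trained [train_cell_classifier] model.
#' @return `cell_detections` with a `class` column.
#' @export
classify_cells <- function(detections, classifier) {
  stopifnot(inherits(detections, "cell_detections"))
  if (!inherits(classifier, "cell_classifier"))
    stop("classifier is not a trained cell classifier")
  tab <- detections$table
  miss <- setdiff(classifier$feature_names, names(tab))
  if (length(miss))
    stop("feature schema mismatch; missing: ", paste(miss, collapse = ", "))
  out <- detections
  if (nrow(tab) == 0) {
    out$table$class <- character(0)
    return(out)
  }
  pr <- predict(classifier$forest,
                data = tab[, classifier$feature_names, drop = FALSE],
                num.threads = 1)$predictions
  out$table$class <- as.character(pr)
  out
}

#' Save / load a trained cell classifier
#' @param classifier a `cell_classifier`.
#' @param path file path (.rds).
#' @return `path` / the reloaded classifier.
#' @export
save_cell_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "cell_classifier"))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname save_cell_classifier
#' @export
load_cell_classifier <- function(path) {
  classifier <- readRDS(path)
  if (!inherits(classifier, "cell_classifier") ||
      is.null(classifier$format_version))
    stop("file does not contain a serialised cell classifier")
  classifier
}
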