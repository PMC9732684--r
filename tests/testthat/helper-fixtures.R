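# shared fixtures and brute-force oracles

iou <- function(a, b) sum(a & b) / sum(a | b)

# a small, quick tile spec used across tests
small_spec <- function(seed = 1, ...) {
  args <- list(width = 256, height = 256, microns_per_pixel = 0.5,
               n_crypts = 2, seed = seed)
  do.call(tissue_spec, utils::modifyList(args, list(...)))
}

# exact Euclidean distance of every pixel to the TRUE set (O(n * m) oracle)
brute_force_distance <- function(m) {
  on <- which(m, arr.ind = TRUE)
  out <- matrix(Inf, nrow(m), ncol(m))
  if (nrow(on) == 0) return(out)
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      out[i, j] <- sqrt(min((on[, 1] - i)^2 + (on[, 2] - j)^2))
    }
  }
  out
}

# greedy nearest-neighbour matching of detections to planted centroids;
# returns c(precision, recall, f1) at the given pixel tolerance
match_detections <- function(det_xy, true_xy, tol = 2) {
  if (nrow(det_xy) == 0 || nrow(true_xy) == 0) return(c(0, 0, 0))
  d2 <- outer(true_xy[, 1], det_xy[, 1], "-")^2 +
    outer(true_xy[, 2], det_xy[, 2], "-")^2
  used <- rep(FALSE, nrow(det_xy))
  tp <- 0
  for (i in order(apply(d2, 1, min))) {
    cand <- which(!used & d2[i, ] <= tol^2)
    if (length(cand)) {
      used[cand[which.min(d2[i, cand])]] <- TRUE
      tp <- tp + 1
    }
  }
  prec <- tp / nrow(det_xy)
  rec <- tp / nrow(true_xy)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(precision = prec, recall = rec, f1 = f1)
}

# build a cell_detections object directly from a truth cell table (an
# idealised detector, for testing tabulation against planted tallies)
detections_from_truth <- function(cells, h, w, mpp,
                                  settings = detection_settings()) {
  lab <- matrix(0L, h, w)
  n <- nrow(cells)
  if (n) lab[cbind(floor(cells$y) + 1L, floor(cells$x) + 1L)] <- seq_len(n)
  tab <- data.frame(
    id = seq_len(n), x = cells$x, y = cells$y, npx = 1L,
    area_um2 = cells$area_um2,
    area_px2_ref = cells$area_um2 / settings$requested_pixel_size^2
  )
  tab$class <- cells$class
  structure(list(labels = lab, cell_labels = NULL, table = tab,
                 microns_per_pixel = mpp, settings = settings),
            class = "cell_detections")
}

# assign nearest planted truth class to each detection (training labels)
label_by_truth <- function(det, truth_cells, max_dist = 4) {
  d2 <- outer(det$table$x, truth_cells$x, "-")^2 +
    outer(det$table$y, truth_cells$y, "-")^2
  nn <- apply(d2, 1, which.min)
  cls <- truth_cells$class[nn]
  cls[sqrt(apply(d2, 1, min)) > max_dist] <- "artefact"
  cls
}

# brute-force Spearman rho: Pearson product-moment formula on mid-ranks
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# brute-force tie-corrected Kruskal-Wallis H from the rank-sum formula
oracle_kruskal_H <- function(groups) {
  vals <- unlist(groups)
  n <- length(vals)
  r <- rank(vals)
  sizes <- vapply(groups, length, integer(1))
  idx <- rep(seq_along(groups), sizes)
  rs <- tapply(r, idx, sum)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)
  ties <- table(vals)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / corr
}

# closed-form OLS: beta = (X'X)^-1 X'y
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# all permutations of a vector, one per row
all_permutations <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- list()
  for (i in seq_along(v)) {
    rest <- all_permutations(v[-i])
    out[[i]] <- cbind(v[i], rest)
  }
  do.call(rbind, out)
}
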