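#' Study groups, stains, compartments
#'
#' The five study groups cross diagnosis with histological activity
#' (activity = presence of neutrophils, i.e. Nancy grade 2-4).
#' @export
STUDY_GROUPS <- c("HC", "UC_inactive", "CD_inactive", "UC_active", "CD_active")

#' @rdname STUDY_GROUPS
#' @export
STAINS <- c("CD3", "TCRdelta")

#' @rdname STUDY_GROUPS
#' @export
COMPARTMENTS <- c("epithelium", "subepithelial", "lamina_propria")

#' Design of a synthetic patient cohort
#'
#' Defines the generative model for cohort count tables: per-group subject
#' counts, baseline geometric means of the normalised measures, planted
#' fold changes on the natural-log scale, a subject random intercept and a
#' residual (biopsy) error, plus clinical covariates. Counts are drawn as
#' `round(exp(mu + b_subject + eps))` where `mu` encodes the baseline,
#' the planted fold changes and the biopsy denominator, so log counts are
#' normal by construction.
#'
#' Baseline units: `epithelium` and `subepithelial` baselines are positive
#' cells per 100 epithelial cells; `lamina_propria` baselines are positive
#' cells per mm2 of mucosa.
#'
#' @param n_subjects named integer vector of subjects per group (names
#'   from [STUDY_GROUPS]).
#' @param biopsies_per_subject biopsies per subject; locations alternate
#'   proximal / distal.
#' @param baseline matrix `[stain, compartment]` of geometric-mean
#'   normalised measures in the reference (HC, distal) condition.
#' @param fold_change 3-d array `[group, stain, compartment]` of planted
#'   multiplicative effects relative to HC (HC slice must be 1).
#' @param location_fc multiplicative effect of proximal vs distal location
#'   (applies to all stains/compartments).
#' @param sigma_subject between-subject SD on the natural-log scale.
#' @param sigma_resid residual (between-biopsy) SD on the natural-log scale.
#' @param steroid_fc multiplier applied to TCRdelta counts of subjects on
#'   oral corticosteroids.
#' @param steroid_prob named probability of oral corticosteroid use per
#'   group (HC is forced to 0).
#' @param epithelial_cells_mean,epithelial_cells_sd_log geometric mean and
#'   log-SD of the per-biopsy epithelial cell total.
#' @param area_mean_mm2,area_sd_log geometric mean and log-SD of the
#'   per-biopsy mucosa area (mm2).
#' @param blood_ratio_median,blood_ratio_sd_log blood gamma-delta/CD3
#'   ratio distribution (percent, log-normal).
#' @param seed RNG seed.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = c(HC = 33, UC_inactive = 30,
                                         CD_inactive = 25, UC_active = 28,
                                         CD_active = 22),
                          biopsies_per_subject = 2,
                          baseline = default_baseline(),
                          fold_change = neutral_fold_changes(),
                          location_fc = 1,
                          sigma_subject = 0.3, sigma_resid = 0.4,
                          steroid_fc = 1,
                          steroid_prob = c(HC = 0, UC_inactive = 0.2,
                                           CD_inactive = 0.3, UC_active = 0.3,
                                           CD_active = 0.4),
                          epithelial_cells_mean = 2000,
                          epithelial_cells_sd_log = 0,
                          area_mean_mm2 = 1.2, area_sd_log = 0,
                          blood_ratio_median = 3, blood_ratio_sd_log = 0.5,
                          seed = 1L) {
  if (length(n_subjects) == 0) stop("empty group list")
  if (is.null(names(n_subjects)) || !all(names(n_subjects) %in% STUDY_GROUPS))
    stop("n_subjects must be named with groups among: ",
         paste(STUDY_GROUPS, collapse = ", "))
  if (any(n_subjects < 1)) stop("subject counts must be >= 1")
  if (sigma_subject < 0 || sigma_resid < 0) stop("SDs must be >= 0")
  if (any(fold_change <= 0)) stop("fold changes must be > 0")
  if (any(baseline <= 0)) stop("baselines must be > 0")
  structure(
    list(n_subjects = n_subjects,
         biopsies_per_subject = as.integer(biopsies_per_subject),
         baseline = baseline, fold_change = fold_change,
         location_fc = location_fc,
         sigma_subject = sigma_subject, sigma_resid = sigma_resid,
         steroid_fc = steroid_fc, steroid_prob = steroid_prob,
         epithelial_cells_mean = epithelial_cells_mean,
         epithelial_cells_sd_log = epithelial_cells_sd_log,
         area_mean_mm2 = area_mean_mm2, area_sd_log = area_sd_log,
         blood_ratio_median = blood_ratio_median,
         blood_ratio_sd_log = blood_ratio_sd_log,
         seed = as.integer(seed)),
    class = "cohort_design"
  )
}

#' Default baseline normalised measures
#'
#' Geometric means for the healthy reference condition, chosen to be of
#' the same order as densities reported for normal colon mucosa: a few
#' CD3 IELs per 100 epithelial cells, an order of magnitude fewer
#' gamma-delta IELs, and a few hundred CD3 cells per mm2 of lamina
#' propria. These are simulation parameters, not measurements.
#'
#' @return matrix `[stain, compartment]`.
#' @export
default_baseline <- function() {
  matrix(c(
    # epithelium, subepithelial, lamina_propria
    2.8, 3.5, 600,   # CD3: per-100, per-100, per-mm2
    0.6, 0.8, 60     # TCRdelta
  ), nrow = 2, byrow = TRUE,
  dimnames = list(STAINS, COMPARTMENTS))
}

#' Fold-change array with no planted effects
#' @return array `[group, stain, compartment]` of ones.
#' @export
neutral_fold_changes <- function() {
  array(1, dim = c(length(STUDY_GROUPS), length(STAINS), length(COMPARTMENTS)),
        dimnames = list(STUDY_GROUPS, STAINS, COMPARTMENTS))
}

#' Cohort design planting the qualitative IBD pattern
#'
#' Encodes, as multiplicative effects relative to healthy controls, the
#' compartment pattern this pipeline is built to detect: fewer
#' gamma-delta IELs in inactive Crohn's disease than in inactive
#' ulcerative colitis; a marked loss of gamma-delta IELs with activity in
#' UC but not in CD; increasing CD3 numbers in the subepithelial band and
#' lamina propria with activity; and an intraepithelial CD3 count that
#' stays essentially constant regardless of activity.
#'
#' @param ... overrides passed on to [cohort_design].
#' @return a `cohort_design`.
#' @export
ibd_pattern_design <- function(...) {
  fc <- neutral_fold_changes()
  # CD3: constant IELs, graded increase below the basement membrane
  fc[, "CD3", "epithelium"] <- c(1, 1.2, 1.4, 1.3, 1.7)
  fc[, "CD3", "subepithelial"] <- c(1, 1.2, 1.6, 1.8, 2.3)
  fc[, "CD3", "lamina_propria"] <- c(1, 1.2, 1.5, 2.3, 2.7)
  # TCRdelta: low in CD throughout; collapse with activity in UC only
  fc[, "TCRdelta", "epithelium"] <- c(1, 1.4, 0.7, 0.42, 0.7)
  fc[, "TCRdelta", "subepithelial"] <- c(1, 1.3, 1.0, 1.1, 1.2)
  fc[, "TCRdelta", "lamina_propria"] <- c(1, 1.0, 1.3, 1.4, 1.4)
  cohort_design(fold_change = fc, location_fc = 1.35, steroid_fc = 0.7, ...)
}

#' Generate a synthetic cohort count table
#'
#' One row per (subject, biopsy, stain, compartment). Counts are drawn by
#' the log-normal model of [cohort_design] and rounded to integers (zeros
#' are possible and intentionally stress the log-zero handling of the
#' statistics module). Deterministic for a fixed seed.
#'
#' @param design a [cohort_design].
#' @return data.frame with columns subject_id, group, diagnosis,
#'   nancy_grade, location, biopsy_id, stain, compartment, count,
#'   epithelial_cells, area_mm2, age, gender, duration_months,
#'   oral_steroids, blood_gd_cd3_ratio.
#' @export
generate_cohort_counts <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(design$seed, {
    groups <- names(design$n_subjects)
    n_subj <- sum(design$n_subjects)
    nb <- design$biopsies_per_subject
    ns <- length(STAINS); nc <- length(COMPARTMENTS)

    # subject level
    subj <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n_subj)),
      group = rep(groups, design$n_subjects),
      stringsAsFactors = FALSE
    )
    subj$diagnosis <- ifelse(subj$group == "HC", "HC", substr(subj$group, 1, 2))
    subj$active <- grepl("_active$", subj$group)
    subj$age <- round(stats::runif(n_subj, 18, 75))
    subj$gender <- sample(c("F", "M"), n_subj, replace = TRUE)
    subj$duration_months <- ifelse(subj$diagnosis == "HC", 0,
                                   round(stats::runif(n_subj, 2, 480)))
    sp <- unlist(design$steroid_prob[subj$group])
    sp[is.na(sp)] <- 0
    subj$oral_steroids <- stats::runif(n_subj) < sp
    subj$blood_gd_cd3_ratio <- exp(log(design$blood_ratio_median) +
                                     stats::rnorm(n_subj, 0, design$blood_ratio_sd_log))
    # one random intercept per (subject, stain, compartment) series
    b <- array(stats::rnorm(n_subj * ns * nc, 0, design$sigma_subject),
               dim = c(n_subj, ns, nc),
               dimnames = list(NULL, STAINS, COMPARTMENTS))

    # biopsy level
    bio <- subj[rep(seq_len(n_subj), each = nb), ]
    bio$bi <- rep(seq_len(nb), times = n_subj)
    bio$subj_idx <- rep(seq_len(n_subj), each = nb)
    bio$biopsy_id <- sprintf("%s_B%d", bio$subject_id, bio$bi)
    bio$location <- ifelse(bio$bi %% 2 == 1, "proximal", "distal")
    n_bio <- nrow(bio)
    bio$nancy_grade <- ifelse(
      bio$diagnosis == "HC",
      sample(0:1, n_bio, replace = TRUE, prob = c(0.8, 0.2)),
      ifelse(bio$active,
             sample(2:4, n_bio, replace = TRUE),
             sample(0:1, n_bio, replace = TRUE, prob = c(0.7, 0.3)))
    )
    bio$epithelial_cells <- round(exp(log(design$epithelial_cells_mean) +
                                        stats::rnorm(n_bio, 0, design$epithelial_cells_sd_log)))
    bio$area_mm2 <- exp(log(design$area_mean_mm2) +
                          stats::rnorm(n_bio, 0, design$area_sd_log))

    # measurement level: biopsies x stains x compartments
    idx <- expand.grid(series = seq_len(ns * nc), bio = seq_len(n_bio))
    out <- bio[idx$bio, ]
    series <- expand.grid(stain = STAINS, compartment = COMPARTMENTS,
                          stringsAsFactors = FALSE)
    out$stain <- series$stain[idx$series]
    out$compartment <- series$compartment[idx$series]
    denom <- ifelse(out$compartment == "lamina_propria",
                    out$area_mm2, out$epithelial_cells / 100)
    mu <- log(design$baseline[cbind(out$stain, out$compartment)] * denom) +
      log(design$fold_change[cbind(out$group, out$stain, out$compartment)]) +
      (out$location == "proximal") * log(design$location_fc) +
      (out$oral_steroids & out$stain == "TCRdelta") * log(design$steroid_fc)
    b_val <- b[cbind(out$subj_idx, match(out$stain, STAINS),
                     match(out$compartment, COMPARTMENTS))]
    eps <- stats::rnorm(nrow(out), 0, design$sigma_resid)
    out$count <- round(exp(mu + b_val + eps))

    out <- out[order(out$subj_idx, out$bi, match(out$stain, STAINS),
                     match(out$compartment, COMPARTMENTS)), ]
    out <- out[, c("subject_id", "group", "diagnosis", "nancy_grade",
                   "location", "biopsy_id", "stain", "compartment", "count",
                   "epithelial_cells", "area_mm2", "age", "gender",
                   "duration_months", "oral_steroids", "blood_gd_cd3_ratio")]
    rownames(out) <- NULL
    out
  })
}
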