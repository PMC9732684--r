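#' Validate a cohort count table
#'
#' Checks the schema produced by [generate_cohort_counts] (and by the
#' image pipeline's tabulation): required columns present, counts
#' non-negative integers, Nancy grades in 0..4, known stains, compartments
#' and locations. Violations are reported with their row numbers.
#'
#' @param cohort data.frame.
#' @return the validated table, invisibly.
#' @export
validate_cohort <- function(cohort) {
  required <- c("subject_id", "diagnosis", "nancy_grade", "location",
                "biopsy_id", "stain", "compartment", "count",
                "epithelial_cells", "area_mm2")
  miss <- setdiff(required, names(cohort))
  if (length(miss))
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "))
  bad <- function(cond) which(cond)
  problems <- c(
    sprintf("row %d: negative or missing count",
            bad(!is.finite(cohort$count) | cohort$count < 0)),
    sprintf("row %d: Nancy grade outside 0..4",
            bad(!(cohort$nancy_grade %in% 0:4))),
    sprintf("row %d: unknown stain",
            bad(!(cohort$stain %in% STAINS))),
    sprintf("row %d: unknown compartment",
            bad(!(cohort$compartment %in% COMPARTMENTS))),
    sprintf("row %d: unknown location",
            bad(!(cohort$location %in% c("proximal", "distal")))),
    sprintf("row %d: non-positive denominator",
            bad(!is.finite(cohort$epithelial_cells) | cohort$epithelial_cells <= 0 |
                  !is.finite(cohort$area_mm2) | cohort$area_mm2 <= 0))
  )
  if (length(problems))
    stop("invalid cohort table:\n  ", paste(problems, collapse = "\n  "))
  invisible(cohort)
}

# normalised measure for a cohort row: per-100 epithelial cells in the
# epithelial compartments, per mm2 in lamina propria
measure_denominator <- function(cohort) {
  ifelse(cohort$compartment == "lamina_propria",
         cohort$area_mm2, cohort$epithelial_cells / 100)
}

# the comparisons reported for inactive and active mucosa
table_contrasts <- function() {
  list(
    inactive = c("CD_inactive vs HC", "UC_inactive vs HC",
                 "CD_inactive vs UC_inactive"),
    active = c("CD_active vs HC", "UC_active vs HC",
               "CD_active vs CD_inactive", "UC_active vs UC_inactive",
               "CD_active vs UC_active")
  )
}

#' Run the full study analysis on a cohort table
#'
#' For every stain and compartment, fits the random-intercept model on
#' log-transformed normalised counts with study group (diagnosis crossed
#' with dichotomised Nancy activity) and colon location as fixed factors
#' and subject as random factor, and emits all pairwise LSD group
#' contrasts as back-transformed fold changes with confidence intervals.
#' Adds: the same models for the gamma-delta/CD3 ratio, separate
#' covariate-adjusted refits (oral corticosteroids, age, gender, disease
#' duration), a group-by-location interaction check, Spearman
#' correlations between blood and mucosal gamma-delta/CD3 ratios, and
#' proximal-versus-distal Kruskal-Wallis comparisons in histologically
#' inactive mucosa.
#'
#' @param cohort cohort count table (schema of [generate_cohort_counts]).
#' @param offset count offset before the log transform (0.5; see
#'   [fit_lmm]).
#' @param ci_level confidence level.
#' @return object of class `study_results`: list of data.frames
#'   `contrasts`, `varcomp`, `means`, `covariates`, `interactions`,
#'   `spearman`, `kruskal`.
#' @export
run_study_analysis <- function(cohort, offset = 0.5, ci_level = 0.95) {
  validate_cohort(cohort)
  cohort$activity <- dichotomize_nancy(cohort$nancy_grade)
  cohort$group <- factor(
    ifelse(cohort$diagnosis == "HC", "HC",
           paste(cohort$diagnosis, cohort$activity, sep = "_")),
    levels = STUDY_GROUPS
  )
  cohort$group <- droplevels(cohort$group)
  cohort$denom <- measure_denominator(cohort)
  cohort$measure <- cohort$count / cohort$denom
  blocks <- table_contrasts()

  contrasts <- varcomp <- means <- covariates <- interactions <- list()
  units <- c(epithelium = "per 100 epithelial cells",
             subepithelial = "per 100 epithelial cells",
             lamina_propria = "per mm2")

  analyses <- expand.grid(stain = STAINS, compartment = COMPARTMENTS,
                          stringsAsFactors = FALSE)
  for (k in seq_len(nrow(analyses))) {
    st <- analyses$stain[k]; comp <- analyses$compartment[k]
    d <- cohort[cohort$stain == st & cohort$compartment == comp, ]
    if (nrow(d) == 0) next
    fit <- fit_lmm(d, fixed = ~ group + location, response_col = "count",
                   denom_col = "denom", offset = offset,
                   ci_level = ci_level)
    ct <- pairwise_contrasts(fit, "group")
    ct <- normalize_contrast_orientation(ct, c(blocks$inactive, blocks$active))
    ct$block <- ifelse(ct$contrast %in% blocks$inactive, "inactive",
                       ifelse(ct$contrast %in% blocks$active, "active",
                              "other"))
    ct <- data.frame(stain = st, compartment = comp,
                     measure = units[[comp]], ct)
    contrasts[[length(contrasts) + 1L]] <- ct
    varcomp[[length(varcomp) + 1L]] <- data.frame(
      stain = st, compartment = comp,
      sigma2_subject = fit$varcomp[["subject"]],
      sigma2_residual = fit$varcomp[["residual"]],
      icc = fit$icc, residual_skewness = fit$residual_skewness,
      converged = fit$converged
    )
    mn <- group_means(fit, "group", observed = d$measure, groups = d$group)
    means[[length(means) + 1L]] <- data.frame(stain = st, compartment = comp,
                                              measure = units[[comp]], mn)

    for (covar in c("oral_steroids", "age", "gender", "duration_months")) {
      if (!covar %in% names(cohort)) next
      if (length(unique(d[[covar]])) < 2) next
      fit_c <- fit_lmm(d, fixed = stats::reformulate(c("group", "location", covar)),
                       response_col = "count", denom_col = "denom",
                       offset = offset, ci_level = ci_level)
      an <- stats::anova(fit_c$fit)
      covariates[[length(covariates) + 1L]] <- data.frame(
        stain = st, compartment = comp, covariate = covar,
        p = an[covar, "Pr(>F)"],
        stringsAsFactors = FALSE
      )
    }
    fit_i <- fit_lmm(d, fixed = ~ group * location, response_col = "count",
                     denom_col = "denom", offset = offset,
                     ci_level = ci_level)
    an_i <- stats::anova(fit_i$fit)
    interactions[[length(interactions) + 1L]] <- data.frame(
      stain = st, compartment = comp, term = "group:location",
      p = an_i["group:location", "Pr(>F)"]
    )
  }

  # gamma-delta / CD3 ratio analyses (parallel sections; ratio of
  # offset-stabilised normalised measures)
  for (comp in COMPARTMENTS) {
    gd <- cohort[cohort$stain == "TCRdelta" & cohort$compartment == comp, ]
    cd <- cohort[cohort$stain == "CD3" & cohort$compartment == comp, ]
    m <- merge(gd, cd, by = "biopsy_id", suffixes = c("_gd", "_cd3"))
    if (nrow(m) == 0) next
    m$ratio_pct <- 100 * ((m$count_gd + offset) / m$denom_gd) /
      ((m$count_cd3 + offset) / m$denom_cd3)
    m$subject_id <- m$subject_id_gd
    m$group <- m$group_gd
    m$location <- m$location_gd
    fit <- fit_lmm(m, fixed = ~ group + location, response_col = "ratio_pct",
                   offset = 0, ci_level = ci_level)
    ct <- pairwise_contrasts(fit, "group")
    ct <- normalize_contrast_orientation(ct, c(blocks$inactive, blocks$active))
    ct$block <- ifelse(ct$contrast %in% blocks$inactive, "inactive",
                       ifelse(ct$contrast %in% blocks$active, "active",
                              "other"))
    contrasts[[length(contrasts) + 1L]] <- data.frame(
      stain = "gd_cd3_ratio", compartment = comp, measure = "ratio (%)", ct)
    varcomp[[length(varcomp) + 1L]] <- data.frame(
      stain = "gd_cd3_ratio", compartment = comp,
      sigma2_subject = fit$varcomp[["subject"]],
      sigma2_residual = fit$varcomp[["residual"]],
      icc = fit$icc, residual_skewness = fit$residual_skewness,
      converged = fit$converged
    )
    mn <- group_means(fit, "group", observed = m$ratio_pct, groups = m$group)
    means[[length(means) + 1L]] <- data.frame(stain = "gd_cd3_ratio",
                                              compartment = comp,
                                              measure = "ratio (%)", mn)
  }

  # Spearman: blood vs mucosal gamma-delta/CD3 ratio, per compartment and
  # diagnosis, at subject level
  spearman <- list()
  if ("blood_gd_cd3_ratio" %in% names(cohort)) {
    for (comp in COMPARTMENTS) {
      gd <- cohort[cohort$stain == "TCRdelta" & cohort$compartment == comp, ]
      cd <- cohort[cohort$stain == "CD3" & cohort$compartment == comp, ]
      m <- merge(gd, cd, by = "biopsy_id", suffixes = c("_gd", "_cd3"))
      m$ratio <- 100 * ((m$count_gd + offset) / m$denom_gd) /
        ((m$count_cd3 + offset) / m$denom_cd3)
      agg <- stats::aggregate(
        cbind(ratio, blood = blood_gd_cd3_ratio_gd) ~ subject_id_gd + diagnosis_gd,
        data = m, FUN = mean
      )
      for (dg in unique(agg$diagnosis_gd)) {
        a <- agg[agg$diagnosis_gd == dg, ]
        if (nrow(a) < 3) next
        sc <- spearman_corr(a$blood, a$ratio)
        spearman[[length(spearman) + 1L]] <- data.frame(
          compartment = comp, diagnosis = dg, n = sc$n,
          rho = sc$rho, p = sc$p
        )
      }
    }
  }

  # proximal vs distal in histologically inactive mucosa (HC + inactive IBD)
  kruskal <- list()
  inactive <- cohort[cohort$activity == "inactive", ]
  for (k in seq_len(nrow(analyses))) {
    st <- analyses$stain[k]; comp <- analyses$compartment[k]
    d <- inactive[inactive$stain == st & inactive$compartment == comp, ]
    if (length(unique(d$location)) < 2) next
    kw <- kruskal_wallis(d$measure, d$location)
    gm <- tapply(d$measure, d$location, function(v) exp(mean(log(v + 1e-9))))
    kruskal[[length(kruskal) + 1L]] <- data.frame(
      stain = st, compartment = comp, H = kw$H, p = kw$p,
      fc_proximal_vs_distal = unname(gm["proximal"] / gm["distal"])
    )
  }

  bindr <- function(x) if (length(x)) do.call(rbind, x) else NULL
  structure(
    list(contrasts = bindr(contrasts), varcomp = bindr(varcomp),
         means = bindr(means), covariates = bindr(covariates),
         interactions = bindr(interactions), spearman = bindr(spearman),
         kruskal = bindr(kruskal)),
    class = "study_results"
  )
}

# orient emmeans pairwise contrasts to match the requested "A vs B" labels
normalize_contrast_orientation <- function(ct, wanted) {
  for (wc in wanted) {
    if (wc %in% ct$contrast) next
    parts <- strsplit(wc, " vs ", fixed = TRUE)[[1]]
    flipped <- paste(rev(parts), collapse = " vs ")
    i <- match(flipped, ct$contrast)
    if (!is.na(i)) {
      ct[i, c("fc", "ci_low", "ci_high")] <-
        list(1 / ct$fc[i], 1 / ct$ci_high[i], 1 / ct$ci_low[i])
      ct$log_estimate[i] <- -ct$log_estimate[i]
      ct$contrast[i] <- wc
    }
  }
  ct
}

#' Write study results as CSV files
#' @param results a `study_results`.
#' @param dir output directory.
#' @return invisible vector of written paths.
#' @export
write_study_results <- function(results, dir) {
  stopifnot(inherits(results, "study_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    if (is.null(results[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(results[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Human-readable study report
#' @param results a `study_results`.
#' @return character vector of report lines, invisibly; printed unless
#'   `quiet`.
#' @param quiet suppress printing.
#' @export
report_study <- function(results, quiet = FALSE) {
  stopifnot(inherits(results, "study_results"))
  ln <- c("Compartmental T-cell quantification: group contrasts",
          strrep("=", 52))
  ct <- results$contrasts
  for (st in unique(ct$stain)) {
    ln <- c(ln, "", sprintf("-- %s --", st))
    for (comp in unique(ct$compartment)) {
      sub <- ct[ct$stain == st & ct$compartment == comp &
                  ct$block != "other", ]
      if (nrow(sub) == 0) next
      ln <- c(ln, sprintf("  %s [%s]", comp, sub$measure[1]))
      ln <- c(ln, sprintf("    %-28s FC %5.2f (%4.2f-%5.2f)  p=%.4g%s",
                          sub$contrast, sub$fc, sub$ci_low, sub$ci_high,
                          sub$p, ifelse(sub$p < 0.05, " *", "")))
    }
  }
  if (!is.null(results$kruskal)) {
    ln <- c(ln, "", "Proximal vs distal (inactive mucosa, Kruskal-Wallis):")
    ln <- c(ln, sprintf("  %-10s %-15s FC %4.2f  H=%5.2f  p=%.4g",
                        results$kruskal$stain, results$kruskal$compartment,
                        results$kruskal$fc_proximal_vs_distal,
                        results$kruskal$H, results$kruskal$p))
  }
  if (!quiet) cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}
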