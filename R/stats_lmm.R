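#' Dichotomise the Nancy histological index
#'
#' Grades 0-1 (no neutrophils) are histologically inactive; grades 2-4
#' (neutrophils present) are active.
#'
#' @param grade integer vector of Nancy grades in 0..4.
#' @return factor with levels `inactive`, `active`.
#' @export
dichotomize_nancy <- function(grade) {
  if (any(is.na(grade)) || any(!(grade %in% 0:4)))
    stop("Nancy grades must be integers in 0..4")
  factor(ifelse(grade <= 1, "inactive", "active"),
         levels = c("inactive", "active"))
}

#' Fit a random-intercept model on log-transformed counts
#'
#' REML fit of `log((count + offset)/denominator) = X beta + b_subject +
#' eps`, the workhorse behind all group comparisons: counts are
#' log-normal, subjects contribute several biopsies (hence the random
#' intercept), and back-transformed contrasts of the fixed effects are
#' fold changes.
#'
#' @param data data.frame with the response, fixed-effect columns and the
#'   subject column.
#' @param fixed one-sided formula of fixed effects, e.g. `~ group +
#'   location`.
#' @param response_col column holding the count.
#' @param denom_col optional column holding the denominator (epithelial
#'   cells / 100, or mm2); NULL models the raw count.
#' @param subject_col grouping column for the random intercept.
#' @param offset added to the count before the natural log; 0.5 by
#'   default, with 1 as the conventional sensitivity alternative.
#' @param ci_level confidence level for intervals.
#' @return object of class `lmm_result`: the `lmerTest` fit plus the
#'   fixed-effect table (Satterthwaite df), variance components, ICC,
#'   residual skewness and a convergence flag.
#' @export
fit_lmm <- function(data, fixed = ~ group, response_col = "count",
                    denom_col = NULL, subject_col = "subject_id",
                    offset = 0.5, ci_level = 0.95) {
  stopifnot(is.data.frame(data))
  if (!(subject_col %in% names(data)))
    stop("subject column '", subject_col, "' not found")
  if (length(unique(data[[subject_col]])) < 2)
    stop("at least 2 subjects are required")
  y <- data[[response_col]] + offset
  if (any(!is.finite(y)) || any(y <= 0))
    stop("response must be finite and positive after the offset")
  d <- data
  d$.y <- log(y)
  if (!is.null(denom_col)) d$.y <- d$.y - log(d[[denom_col]])

  fixed_terms <- attr(stats::terms(fixed), "term.labels")
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  # detect aliased fixed-effect columns before lmer silently drops them
  X <- stats::model.matrix(stats::reformulate(rhs), d)
  if (qr(X)$rank < ncol(X)) {
    qq <- qr(X)
    aliased <- colnames(X)[qq$pivot[seq(qq$rank + 1, ncol(X))]]
    stop("singular fixed-effect design; aliased: ",
         paste(aliased, collapse = ", "))
  }
  form <- stats::as.formula(paste(".y ~", rhs, "+ (1 |", subject_col, ")"))

  # allow boundary designs (one biopsy per subject) so that the model
  # degrades gracefully to OLS when the subject variance is unidentifiable
  ctl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                           check.nobs.vs.rankZ = "ignore",
                           check.nobs.vs.nRE = "ignore")
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(form, data = d, REML = TRUE, control = ctl)
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_subject <- vc$vcov[vc$grp == subject_col]
  sigma2_resid <- vc$vcov[vc$grp == "Residual"]
  coefs <- stats::coef(summary(fit))
  res <- stats::residuals(fit)
  skew <- if (stats::sd(res) > 0) {
    mean((res - mean(res))^3) / stats::sd(res)^3
  } else 0
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  structure(
    list(fit = fit,
         fixed_effects = data.frame(
           term = rownames(coefs), estimate = coefs[, "Estimate"],
           se = coefs[, "Std. Error"], df = coefs[, "df"],
           t = coefs[, "t value"], p = coefs[, "Pr(>|t|)"],
           row.names = NULL),
         varcomp = c(subject = sigma2_subject, residual = sigma2_resid),
         icc = icc_from_components(sigma2_subject, sigma2_resid),
         residual_skewness = skew,
         converged = conv,
         ci_level = ci_level,
         offset = offset,
         formula = form),
    class = "lmm_result"
  )
}

icc_from_components <- function(s2_subject, s2_resid) {
  tot <- s2_subject + s2_resid
  if (tot <= 0) return(0)
  s2_subject / tot
}

#' Intraclass correlation of a fitted model
#'
#' The fraction of total variance attributable to between-subject
#' variation: `sigma2_subject / (sigma2_subject + sigma2_residual)`.
#'
#' @param result an `lmm_result`.
#' @return value in \[0, 1\].
#' @export
icc <- function(result) {
  stopifnot(inherits(result, "lmm_result"))
  unname(result$icc)
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("<lmm_result>", deparse(x$formula), "\n")
  cat(sprintf("  varcomp: subject %.4g, residual %.4g (ICC %.3f)%s\n",
              x$varcomp[["subject"]], x$varcomp[["residual"]], x$icc,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$fixed_effects, digits = 3)
  invisible(x)
}

#' Unadjusted (LSD) pairwise contrasts as fold changes
#'
#' Pairwise comparisons of estimated marginal means on the log scale, with
#' Satterthwaite degrees of freedom, back-transformed to fold changes with
#' confidence intervals. Deliberately no multiplicity correction: these
#' are least-significant-difference post hoc tests.
#'
#' @param result an `lmm_result`.
#' @param factor_name name of the fitted factor to compare.
#' @param pairs optional character vector of contrasts to keep, each
#'   `"A vs B"`; NULL keeps all pairs.
#' @param reverse if TRUE contrasts are `later - earlier` level; default
#'   FALSE matches emmeans (`earlier - later`).
#' @return data.frame: contrast, fc, ci_low, ci_high, p, log_estimate,
#'   se, df.
#' @export
pairwise_contrasts <- function(result, factor_name = "group", pairs = NULL,
                               reverse = FALSE) {
  stopifnot(inherits(result, "lmm_result"))
  em <- emmeans::emmeans(result$fit, stats::reformulate(factor_name),
                         lmer.df = "satterthwaite")
  ct <- summary(emmeans::contrast(em, method = "pairwise", adjust = "none",
                                  reverse = reverse),
                infer = TRUE, level = result$ci_level)
  out <- data.frame(
    contrast = gsub(" - ", " vs ", as.character(ct$contrast)),
    fc = exp(ct$estimate),
    ci_low = exp(ct$lower.CL),
    ci_high = exp(ct$upper.CL),
    p = ct$p.value,
    log_estimate = ct$estimate,
    se = ct$SE,
    df = ct$df,
    stringsAsFactors = FALSE
  )
  if (!is.null(pairs)) {
    flip <- function(s) {
      parts <- strsplit(s, " vs ", fixed = TRUE)[[1]]
      paste(rev(parts), collapse = " vs ")
    }
    # a level contrasted with itself is the null contrast by definition
    self <- vapply(pairs, function(s) {
      parts <- strsplit(s, " vs ", fixed = TRUE)[[1]]
      length(parts) == 2 && parts[1] == parts[2]
    }, logical(1))
    if (any(self)) {
      lv <- unique(unlist(strsplit(out$contrast, " vs ")))
      bad <- vapply(pairs[self], function(s)
        !(strsplit(s, " vs ")[[1]][1] %in% lv), logical(1))
      if (any(bad))
        stop("unknown contrast level(s): ",
             paste(pairs[self][bad], collapse = ", "))
      selfrows <- data.frame(
        contrast = pairs[self], fc = 1, ci_low = 1, ci_high = 1, p = 1,
        log_estimate = 0, se = 0, df = NA_real_, stringsAsFactors = FALSE)
      rest <- if (all(self)) NULL else
        pairwise_contrasts(result, factor_name, pairs[!self], reverse)
      out <- rbind(selfrows, rest)
      return(out[match(pairs, out$contrast), , drop = FALSE])
    }
    keep <- match(pairs, out$contrast)
    for (k in which(is.na(keep))) {
      alt <- match(flip(pairs[k]), out$contrast)
      if (!is.na(alt)) {
        out[alt, c("fc", "ci_low", "ci_high")] <-
          list(1 / out$fc[alt], 1 / out$ci_high[alt], 1 / out$ci_low[alt])
        out$log_estimate[alt] <- -out$log_estimate[alt]
        out$contrast[alt] <- pairs[k]
        keep[k] <- alt
      }
    }
    if (any(is.na(keep)))
      stop("unknown contrast level(s): ",
           paste(pairs[is.na(keep)], collapse = ", "))
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Group summaries: model-based geometric means and sample medians
#'
#' Back-transformed estimated marginal means (geometric means under the
#' log-normal model) with confidence intervals, alongside plain sample
#' medians of the observed measure — both labelled, since they answer
#' subtly different questions.
#'
#' @param result an `lmm_result`.
#' @param factor_name fitted factor to summarise.
#' @param observed optional numeric vector of observed (untransformed)
#'   measures, with `groups` giving each value's level, for the medians.
#' @param groups see `observed`.
#' @return data.frame with level, geo_mean, ci_low, ci_high, median.
#' @export
group_means <- function(result, factor_name = "group", observed = NULL,
                        groups = NULL) {
  stopifnot(inherits(result, "lmm_result"))
  em <- summary(emmeans::emmeans(result$fit, stats::reformulate(factor_name),
                                 lmer.df = "satterthwaite"),
                infer = TRUE, level = result$ci_level)
  out <- data.frame(
    level = as.character(em[[factor_name]]),
    geo_mean = exp(em$emmean),
    ci_low = exp(em$lower.CL),
    ci_high = exp(em$upper.CL),
    stringsAsFactors = FALSE
  )
  out$median <- if (!is.null(observed)) {
    vapply(out$level, function(l) stats::median(observed[groups == l],
                                                na.rm = TRUE), numeric(1))
  } else NA_real_
  out
}
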