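test_that("the Nancy dichotomy splits at grade 2", {
  expect_equal(as.character(dichotomize_nancy(c(0, 1))),
               c("inactive", "inactive"))
  expect_equal(as.character(dichotomize_nancy(c(2, 3, 4))),
               c("active", "active", "active"))
  expect_error(dichotomize_nancy(5), "0..4")
  expect_error(dichotomize_nancy(NA), "0..4")
})

test_that("identical groups give a fold change of exactly 1", {
  y <- c(3, 5, 8, 13, 21, 34)
  d <- data.frame(
    subject_id = sprintf("s%d", 1:12),
    group = factor(rep(c("A", "B"), each = 6)),
    count = c(y, y)
  )
  fit <- fit_lmm(d, fixed = ~ group, offset = 0.5)
  ct <- pairwise_contrasts(fit, "group")
  expect_equal(ct$fc, 1, tolerance = 1e-12)
  expect_true(ct$ci_low <= 1 && ct$ci_high >= 1)
  expect_equal(ct$p, 1, tolerance = 1e-9)
})

test_that("with zero subject variance the fit equals closed-form OLS", {
  set.seed(31)
  d <- data.frame(
    subject_id = sprintf("s%d", 1:60),
    group = factor(rep(c("A", "B", "C"), each = 20)),
    count = exp(rnorm(60, 3, 0.4))
  )
  fit <- fit_lmm(d, fixed = ~ group, offset = 0.5)
  X <- model.matrix(~ group, d)
  beta <- oracle_ols(X, log(d$count + 0.5))
  expect_equal(unname(fit$fixed_effects$estimate), unname(beta),
               tolerance = 1e-8)
  expect_equal(unname(fit$varcomp[["subject"]]), 0, tolerance = 1e-8)
})

test_that("LSD contrasts reduce to pooled-variance t-tests without subject variance", {
  set.seed(32)
  d <- data.frame(
    subject_id = sprintf("s%d", 1:60),
    group = factor(rep(c("A", "B", "C"), each = 20)),
    count = exp(rnorm(60, 3, 0.4) + rep(c(0, 0.3, 0.6), each = 20))
  )
  fit <- fit_lmm(d, fixed = ~ group, offset = 0.5)
  ct <- pairwise_contrasts(fit, "group")
  # LSD closed form: pooled MSE from the OLS fit, df = N - k
  y <- log(d$count + 0.5)
  ols <- lm(y ~ group, d)
  mse <- sum(resid(ols)^2) / ols$df.residual
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    diff <- mean(y[d$group == pair[1]]) - mean(y[d$group == pair[2]])
    tstat <- diff / sqrt(mse * (1 / 20 + 1 / 20))
    p_lsd <- 2 * pt(-abs(tstat), ols$df.residual)
    row <- ct[ct$contrast == paste(pair, collapse = " vs "), ]
    expect_equal(row$p, p_lsd, tolerance = 1e-6)
    expect_equal(row$log_estimate, diff, tolerance = 1e-8)
  }
})

test_that("a planted fold change of 2 is estimated accurately", {
  fc <- neutral_fold_changes()
  fc["UC_inactive", , ] <- 2
  design <- cohort_design(
    n_subjects = c(HC = 50, UC_inactive = 50), fold_change = fc,
    sigma_subject = 0.3, sigma_resid = 0.4, seed = 101
  )
  tab <- generate_cohort_counts(design)
  sub <- tab[tab$stain == "CD3" & tab$compartment == "lamina_propria", ]
  sub$denom <- sub$area_mm2
  fit <- fit_lmm(sub, fixed = ~ group, denom_col = "denom", offset = 0.5)
  ct <- pairwise_contrasts(fit, "group", pairs = "UC_inactive vs HC")
  expect_gt(ct$fc, 1.7)
  expect_lt(ct$fc, 2.35)
  expect_true(ct$ci_low < 2 && ct$ci_high > 2)
})

test_that("a level contrasted with itself is the null contrast", {
  d <- data.frame(subject_id = sprintf("s%d", 1:20),
                  group = factor(rep(c("A", "B"), each = 10)),
                  count = exp(rnorm(20, 2, 0.3)))
  fit <- fit_lmm(d, fixed = ~ group)
  ct <- pairwise_contrasts(fit, "group", pairs = "A vs A")
  expect_equal(ct$fc, 1)
  expect_equal(ct$p, 1)
  expect_error(pairwise_contrasts(fit, "group", pairs = "A vs Z"), "unknown")
})

test_that("the ICC follows the variance components", {
  expect_equal(icc(structure(list(icc = 0), class = "lmm_result")), 0)
  d <- cohort_design(n_subjects = c(HC = 200), biopsies_per_subject = 2,
                     sigma_subject = 0.5, sigma_resid = 0.5, seed = 7)
  tab <- generate_cohort_counts(d)
  sub <- tab[tab$stain == "CD3" & tab$compartment == "lamina_propria", ]
  fit <- fit_lmm(sub, fixed = ~ 1, offset = 0.5)
  expect_gt(icc(fit), 0.4)
  expect_lt(icc(fit), 0.6)
  # no subject effect: ICC collapses to zero
  set.seed(8)
  d0 <- data.frame(subject_id = rep(sprintf("s%d", 1:50), each = 2),
                   count = exp(rnorm(100, 3, 0.3)))
  fit0 <- fit_lmm(d0, fixed = ~ 1)
  expect_lt(icc(fit0), 0.15)
})

test_that("aliased fixed effects are reported by name", {
  d <- data.frame(subject_id = sprintf("s%d", 1:20),
                  group = factor(rep(c("A", "B"), each = 10)),
                  dup = factor(rep(c("A", "B"), each = 10)),
                  count = exp(rnorm(20, 2, 0.3)))
  expect_error(fit_lmm(d, fixed = ~ group + dup), "aliased.*dup")
})

test_that("Spearman matches the brute-force mid-rank oracle", {
  expect_equal(spearman_corr(1:7, (1:7)^2)$rho, 1)
  expect_equal(spearman_corr(1:7, rev(1:7))$rho, -1)
  x <- c(1, 2, 2, 3, 5, 6)   # one tie
  y <- c(2, 1, 4, 4, 6, 5)
  expect_equal(spearman_corr(x, y)$rho, oracle_spearman_rho(x, y),
               tolerance = 1e-12)
  set.seed(33)
  for (n in 3:8) {
    xx <- sample(1:4, n, replace = TRUE)
    yy <- sample(1:4, n, replace = TRUE)
    if (sd(xx) == 0 || sd(yy) == 0) next
    expect_equal(spearman_corr(xx, yy)$rho, oracle_spearman_rho(xx, yy),
                 tolerance = 1e-12)
  }
  expect_error(spearman_corr(1:2, 1:2), "3")
})

test_that("Kruskal-Wallis matches the brute-force rank-sum oracle", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  kw <- kruskal_wallis(g)
  expect_equal(kw$H, oracle_kruskal_H(g), tolerance = 1e-12)
  expect_equal(kw$H, 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7,
               tolerance = 1e-12)
  # all groups identical constant
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$H, 0)
  set.seed(34)
  for (rep in 1:20) {
    sizes <- sample(2:4, sample(2:3, 1), replace = TRUE)
    g <- lapply(sizes, function(n) sample(1:5, n, replace = TRUE))
    if (length(unique(unlist(g))) == 1) next
    expect_equal(kruskal_wallis(g)$H, oracle_kruskal_H(g), tolerance = 1e-12)
  }
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("Kruskal-Wallis holds its nominal type-I error under the null", {
  set.seed(35)
  rej <- mean(replicate(2000, {
    kruskal_wallis(list(rnorm(12), rnorm(12)))$p < 0.05
  }))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})

test_that("back-transform consistency: fc is exactly exp(log estimate)", {
  tab <- generate_cohort_counts(ibd_pattern_design(seed = 21))
  sub <- tab[tab$stain == "TCRdelta" & tab$compartment == "epithelium", ]
  sub$denom <- sub$epithelial_cells / 100
  fit <- fit_lmm(sub, fixed = ~ group + location, denom_col = "denom")
  ct <- pairwise_contrasts(fit, "group")
  expect_equal(ct$fc, exp(ct$log_estimate), tolerance = 1e-15)
  expect_true(all(ct$ci_low < ct$fc & ct$fc < ct$ci_high))
})
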