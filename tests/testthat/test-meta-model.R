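test_that("with variance components pinned at zero the fit is the
           (weighted) least-squares solution", {
  set.seed(10)
  eff <- simulate_effects(k = 12, n_studies = 4)
  # equal variances: plain arithmetic mean, SE = sqrt(v/k)
  eq <- dplyr::mutate(eff, variance = 0.04)
  fit_eq <- fit_meta(eq, vcv = diag(eq$variance), sigma2 = c(0, 0))
  expect_equal(unname(fit_eq$beta), mean(eq$value), tolerance = 1e-12)
  expect_equal(sqrt(fit_eq$vb[1, 1]), sqrt(0.04 / 12), tolerance = 1e-12)
  # unequal variances: inverse-variance-weighted mean
  fit_iv <- fit_meta(eff, vcv = diag(eff$variance), sigma2 = c(0, 0))
  w <- 1 / eff$variance
  expect_equal(unname(fit_iv$beta), sum(w * eff$value) / sum(w),
               tolerance = 1e-12)
  expect_equal(fit_iv$vb[1, 1], 1 / sum(w), tolerance = 1e-12)
})

test_that("the REML optimum beats a refined grid search over the
           variance components", {
  set.seed(21)
  eff <- simulate_effects(k = 8, n_studies = 3, tau2_study = 0.3,
                          tau2_obs = 0.2)
  V <- diag(eff$variance)
  fit <- fit_meta(eff, vcv = V)
  oracle <- grid_reml(eff, V, refine = 3)
  expect_gte(fit$logLik_reml, oracle$loglik - 1e-8)
  expect_lt(max(abs(unname(fit$sigma2) - oracle$par)), 1e-3)
})

test_that("coefficients, SEs and variance components agree with an
           independent multilevel meta-analysis implementation", {
  skip_if_not_installed("metafor")
  cells <- generate_dataset(synthetic_config(n_studies = 10, seed = 3))
  nbe <- build_effect_table(cells, "nbe")
  V <- unclass(build_vcv(nbe))
  fit <- fit_meta(nbe, vcv = V, moderators = ~ condition + richness)
  dat <- data.frame(yi = nbe$value, study = nbe$study_id,
                    obs = seq_len(nrow(nbe)), condition = nbe$condition,
                    richness = nbe$richness - mean(nbe$richness))
  ref <- metafor::rma.mv(yi, V = V, mods = ~ condition + richness,
                         random = ~ 1 | study / obs, data = dat,
                         method = "REML")
  expect_equal(unname(fit$beta), as.vector(ref$beta), tolerance = 1e-4)
  expect_equal(unname(sqrt(diag(fit$vb))), as.vector(ref$se),
               tolerance = 1e-4)
  expect_equal(unname(fit$sigma2), ref$sigma2, tolerance = 1e-3)
})

test_that("rank-deficient designs and too-small samples are rejected with
           named errors", {
  set.seed(5)
  eff <- simulate_effects(k = 10, n_studies = 3)
  eff$dup <- eff$richness  # perfectly collinear copy
  expect_error(fit_meta(eff, vcv = diag(eff$variance),
                        moderators = ~ richness + dup),
               "rank deficient.*dup")
  expect_error(fit_meta(eff[1:2, ], vcv = diag(eff$variance[1:2])),
               "at least p \\+ 2")
})

test_that("Q_M is the Wald chi-square of the coefficient subset", {
  set.seed(6)
  eff <- simulate_effects(k = 20, n_studies = 5)
  fit <- fit_meta(eff, vcv = diag(eff$variance), sigma2 = c(0, 0))
  # force the textbook case: beta = 2, SE = 1
  fit$beta[1] <- 2
  fit$vb[1, 1] <- 1
  qm <- qm_test(fit, "(Intercept)")
  expect_equal(qm$QM, 4, tolerance = 1e-12)
  expect_equal(qm$df, 1)
  expect_equal(qm$p.value, stats::pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(qm$p.value, 4), 0.0455)

  fit$beta[1] <- 0
  expect_equal(qm_test(fit, "(Intercept)")$QM, 0)
  expect_equal(qm_test(fit, "(Intercept)")$p.value, 1)
  expect_error(qm_test(fit, "nope"), "unknown coefficient")
  expect_error(qm_test(fit, character(0)), "empty")
})

test_that("Q_M on a categorical moderator is invariant to the reference
           level chosen", {
  cells <- generate_dataset(synthetic_config(n_studies = 8, seed = 12))
  nbe <- build_effect_table(cells, "nbe")
  V <- build_vcv(nbe)
  fit1 <- fit_meta(nbe, vcv = V, moderators = ~ condition)
  nbe2 <- dplyr::mutate(nbe, condition = factor(
    condition, levels = c("manipulated", "ambient")))
  fit2 <- fit_meta(nbe2, vcv = V, moderators = ~ condition)
  q1 <- qm_test(fit1, grep("condition", names(fit1$beta), value = TRUE))
  q2 <- qm_test(fit2, grep("condition", names(fit2$beta), value = TRUE))
  expect_equal(q1$QM, q2$QM, tolerance = 1e-8)
})

test_that("marginal means reduce to the GLS stratum mean in a factor-only
           model and widen monotonically with the Bonferroni family", {
  cells <- generate_dataset(synthetic_config(n_studies = 8, seed = 30))
  nbe <- build_effect_table(cells, "nbe")
  fit <- fit_meta(nbe, vcv = diag(nbe$variance), moderators = ~ condition,
                  sigma2 = c(0, 0))
  mm <- marginal_means(fit, "condition")
  for (cond in c("ambient", "manipulated")) {
    sub <- nbe$condition == cond
    w <- 1 / nbe$variance[sub]
    # GLS with a diagonal covariance and a saturated factor decouples strata
    expect_equal(mm$estimate[mm$level == cond],
                 sum(w * nbe$value[sub]) / sum(w), tolerance = 1e-10)
  }
  mm1 <- marginal_means(fit, "condition", k = 1)
  mm5 <- marginal_means(fit, "condition", k = 5)
  expect_equal(mm1$estimate, mm5$estimate)
  expect_true(all(mm5$conf.high - mm5$conf.low >
                    mm1$conf.high - mm1$conf.low))
  expect_error(marginal_means(fit, "richness"), "not a categorical")
})

test_that("pairwise contrasts enumerate all level pairs and detect only the
           separated level", {
  set.seed(77)
  k <- 60
  lev <- rep(c("a", "b", "c"), each = k / 3)
  truth <- c(a = 0, b = 0, c = 0.8)
  eff <- simulate_effects(k = k, n_studies = 12, mu = 0,
                          tau2_study = 0.001, tau2_obs = 0.001,
                          v_range = c(0.01, 0.02))
  eff$invader_type <- lev
  eff$value <- eff$value + truth[lev]
  fit <- fit_meta(eff, vcv = diag(eff$variance),
                  moderators = ~ invader_type)
  pc <- pairwise_contrasts(fit, "invader_type")
  expect_equal(nrow(pc), 3)
  involving_c <- grepl("c", pc$pair)
  expect_true(all(pc$p.adjusted[involving_c] < 0.05))
  expect_true(all(pc$p.adjusted[!involving_c] > 0.05))

  fit1 <- fit_meta(eff, vcv = diag(eff$variance))
  expect_error(pairwise_contrasts(fit1, "invader_type"),
               "not a categorical")
})

test_that("moderator slopes are scale-equivariant and Q_M scale-invariant", {
  cells <- generate_dataset(synthetic_config(n_studies = 10, seed = 8))
  nbe <- build_effect_table(cells, "nbe")
  s1 <- meta_regress_slope(nbe, moderator = "richness",
                           covariates = ~ duration_years)
  nbe10 <- dplyr::mutate(nbe, richness = richness * 10)
  s10 <- meta_regress_slope(nbe10, moderator = "richness",
                            covariates = ~ duration_years)
  expect_equal(s10$slope, s1$slope / 10, tolerance = 1e-6)
  expect_equal(s10$QM, s1$QM, tolerance = 1e-5)
  expect_error(
    meta_regress_slope(dplyr::mutate(nbe, flat = 1), moderator = "flat"),
    "constant moderator")
})
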