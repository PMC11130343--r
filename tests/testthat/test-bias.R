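test_that("funnel data pairs every residual with its sampling SE", {
  set.seed(14)
  eff <- simulate_effects(k = 15, n_studies = 5)
  V <- diag(eff$variance)
  fit <- fit_meta(eff, vcv = V)
  fd <- funnel_data(fit)
  expect_equal(nrow(fd), 15)
  expect_equal(fd$std.error, sqrt(eff$variance))
  expect_equal(fd$residual, eff$value - fit$fitted[1], tolerance = 1e-12)
})

test_that("Egger's regression flags simulated small-study suppression but
           not symmetric data", {
  set.seed(15)
  eff <- simulate_effects(k = 60, n_studies = 12, v_range = c(0.005, 0.25))
  sym <- egger_test(eff, vcv = diag(eff$variance))
  expect_true(all(c("estimate", "statistic", "p.value") %in% names(sym)))
  # suppress small, low effects: censor below a threshold scaled by SE
  biased <- eff
  biased$value <- biased$value + 2.5 * sqrt(biased$variance)
  asym <- egger_test(biased, vcv = diag(biased$variance))
  expect_gt(abs(asym$statistic), abs(sym$statistic))
  expect_lt(asym$p.value, 0.05)

  flat <- dplyr::mutate(eff, variance = 0.05)
  expect_error(egger_test(flat, vcv = diag(flat$variance)),
               "constant sampling standard errors")
  expect_error(egger_test(eff[1, ], vcv = diag(eff$variance[1], 1)),
               "at least 3")
})

test_that("Cook's distances are small and equal under symmetry, maximal for
           a displaced effect, and invariant to ordering", {
  set.seed(16)
  eff <- simulate_effects(k = 20, n_studies = 5, tau2_study = 0,
                          tau2_obs = 0.01)
  V <- diag(eff$variance)
  out_idx <- 7
  eff$value[out_idx] <- eff$value[out_idx] + 10 * sqrt(eff$variance[out_idx])
  cd <- cooks_distance_meta(eff, vcv = V)
  expect_equal(nrow(cd), 20)
  expect_true(all(cd$cooks_d >= 0, na.rm = TRUE))
  expect_equal(which.max(cd$cooks_d), out_idx)
  expect_true(cd$flagged[out_idx])

  perm <- sample(nrow(eff))
  cd_perm <- cooks_distance_meta(eff[perm, ], vcv = V[perm, perm])
  expect_equal(
    cd_perm$cooks_d[match(cd$effect_id, cd_perm$effect_id)],
    cd$cooks_d, tolerance = 1e-4)

  expect_error(cooks_distance_meta(eff[1:3, ], vcv = V[1:3, 1:3]),
               "leave-one-out")
})

test_that("sensitivity refits drop flagged rows consistently and an empty
           flag set reproduces the fit", {
  set.seed(17)
  eff <- simulate_effects(k = 18, n_studies = 6)
  V <- diag(eff$variance)
  full <- fit_meta(eff, vcv = V)
  same <- sensitivity_refit(eff, vcv = V, flagged = character())
  expect_equal(same$beta, full$beta, tolerance = 1e-10)
  expect_equal(same$sigma2, full$sigma2, tolerance = 1e-8)

  reduced <- sensitivity_refit(eff, vcv = V, flagged = eff$effect_id[1:3])
  expect_equal(reduced$k, 15)
  expect_error(sensitivity_refit(eff, vcv = V, flagged = "nope"),
               "not in the effect table")
  expect_error(sensitivity_refit(eff, vcv = V, flagged = eff$effect_id),
               "all effects flagged")
})

test_that("an (almost) zero-weight effect does not move the pooled
           estimate", {
  set.seed(18)
  eff <- simulate_effects(k = 16, n_studies = 4)
  heavy <- eff
  heavy$value[16] <- 50
  heavy$variance[16] <- 1e8   # infinite-variance limit: weight ~ 0
  fit_with <- fit_meta(heavy, vcv = diag(heavy$variance))
  fit_without <- fit_meta(heavy[-16, ], vcv = diag(heavy$variance[-16]))
  expect_lt(abs(unname(fit_with$beta) - unname(fit_without$beta)), 1e-6)
})

test_that("removing a constructed outlier moves the estimate toward the
           truth in most replicates", {
  set.seed(19)
  mu <- 0.3
  better <- 0
  reps <- 40
  for (r in seq_len(reps)) {
    eff <- simulate_effects(k = 15, n_studies = 5, mu = mu,
                            tau2_study = 0.01, tau2_obs = 0.01,
                            v_range = c(0.01, 0.03))
    eff$value[1] <- mu + 10 * sqrt(eff$variance[1])
    full <- fit_meta(eff, vcv = diag(eff$variance))
    red <- sensitivity_refit(eff, vcv = diag(eff$variance),
                             flagged = eff$effect_id[1])
    if (abs(unname(red$beta) - mu) < abs(unname(full$beta) - mu))
      better <- better + 1
  }
  expect_gte(better / reps, 0.9)
})
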