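test_that("NBE matches hand-computed log ratio and delta-method variance", {
  mono <- make_cell(mean = 10, sd = 2, n = 5)
  mix <- make_cell(role = "mixture", richness = 4L, mean = 20, sd = 4, n = 5)
  eff <- compute_nbe(mono, mix)
  # ln(10/20); 4/(5*100) + 16/(5*400)
  expect_equal(eff$value, log(0.5), tolerance = 1e-12)
  expect_equal(eff$variance, 0.016, tolerance = 1e-12)
  expect_equal(eff$es_type, "nbe_invasion")
  expect_equal(eff$richness, 4L)

  equal <- compute_nbe(make_cell(mean = 5, sd = 1, n = 4),
                       make_cell(role = "mixture", mean = 5, sd = 2, n = 4))
  expect_equal(equal$value, 0)
})

test_that("NBE rejects non-positive means and mismatched pairings", {
  mix <- make_cell(role = "mixture", richness = 4L)
  expect_error(compute_nbe(make_cell(mean = 0), mix), "domain error")
  expect_error(compute_nbe(make_cell(study_id = "S2"), mix), "pairing error")
  expect_error(compute_nbe(make_cell(), make_cell()), "pairing error")
  expect_error(
    compute_nbe(make_cell(condition = "manipulated", factor_type = "warming"),
                mix),
    "pairing error")
})

test_that("log-ratio antisymmetry: swapping the means flips the value only", {
  set.seed(41)
  for (i in 1:20) {
    m1 <- stats::runif(1, 1, 50); m2 <- stats::runif(1, 1, 50)
    s1 <- stats::runif(1, 0.1, 5); s2 <- stats::runif(1, 0.1, 5)
    a <- compute_nbe(make_cell(mean = m1, sd = s1),
                     make_cell(role = "mixture", mean = m2, sd = s2))
    b <- compute_nbe(make_cell(mean = m2, sd = s1),
                     make_cell(role = "mixture", mean = m1, sd = s2))
    swapped_var <- s1^2 / (5 * m2^2) + s2^2 / (5 * m1^2)
    expect_equal(a$value, log(m1 / m2), tolerance = 1e-12)
    expect_equal(b$value, -a$value, tolerance = 1e-12)
    expect_equal(b$variance, swapped_var, tolerance = 1e-12)
  }
})

test_that("delta-NBE is the NBE difference with summed variance and
           four-cell signed provenance", {
  nbe_of <- function(condition, mono_mean, mix_mean, factor_type = NULL) {
    ft <- if (condition == "ambient") NA_character_ else factor_type
    compute_nbe(
      make_cell(condition = condition, factor_type = ft, mean = mono_mean),
      make_cell(condition = condition, factor_type = ft, role = "mixture",
                richness = 4L, mean = mix_mean))
  }
  amb <- nbe_of("ambient", 10, 7.4)
  man <- nbe_of("manipulated", 10, 6, "warming")
  d <- compute_delta_nbe(amb, man)
  expect_equal(d$value, man$value - amb$value, tolerance = 1e-15)
  expect_equal(d$variance, man$variance + amb$variance, tolerance = 1e-15)
  expect_equal(d$factor_type, "warming")
  expect_equal(d$n_factors, 1L)
  prov <- d$source_cells[[1]]
  expect_equal(nrow(prov), 4)
  # value equals the signed sum of log cell means
  expect_equal(sum(prov$sign * log(prov$mean)), d$value, tolerance = 1e-12)

  # stated example: 0.5 (v 0.02) vs 0.3 (v 0.01) -> 0.2, 0.03
  man2 <- man; man2$value <- 0.5; man2$variance <- 0.02
  amb2 <- amb; amb2$value <- 0.3; amb2$variance <- 0.01
  d2 <- compute_delta_nbe(amb2, man2)
  expect_equal(d2$value, 0.2, tolerance = 1e-12)
  expect_equal(d2$variance, 0.03, tolerance = 1e-12)

  expect_error(compute_delta_nbe(amb, amb), "pairing error")
})

test_that("factor effects match hand values and honour orientation", {
  a <- make_cell(mean = 8, sd = 2, n = 4)
  m <- make_cell(condition = "manipulated", factor_type = "drought",
                 mean = 4, sd = 1, n = 4)
  fx <- compute_factor_effect_invasion(a, m)
  expect_equal(fx$value, log(2), tolerance = 1e-12)
  expect_equal(fx$variance, 4 / (4 * 64) + 1 / (4 * 16), tolerance = 1e-12)
  expect_equal(fx$stratum, "monoculture")
  expect_error(
    compute_factor_effect_invasion(
      a, make_cell(condition = "manipulated", factor_type = "drought",
                   role = "mixture", richness = 4L)),
    "pairing error")

  pa <- make_cell(response_kind = "resident_productivity", mean = 6, sd = 1)
  pm <- make_cell(condition = "manipulated", factor_type = "warming",
                  response_kind = "resident_productivity", mean = 12, sd = 1)
  fp <- compute_factor_effect_productivity(pa, pm)
  expect_equal(fp$value, log(2), tolerance = 1e-12)  # M over A: reversed
  expect_gt(fp$variance, 0)
  expect_error(
    compute_factor_effect_productivity(
      make_cell(response_kind = "resident_productivity", role = "mixture",
                richness = 2L),
      pm),
    "pairing error")
})

test_that("build_effect_table enumerates pairings and reports the unmatched", {
  one <- dplyr::bind_rows(make_cell(),
                          make_cell(role = "mixture", richness = 4L))
  expect_equal(nrow(build_effect_table(one, "nbe")), 1)

  two_cond <- dplyr::bind_rows(
    make_cell(),
    make_cell(role = "mixture", richness = 2L),
    make_cell(role = "mixture", richness = 8L),
    make_cell(condition = "manipulated", factor_type = "warming"),
    make_cell(condition = "manipulated", factor_type = "warming",
              role = "mixture", richness = 2L),
    make_cell(condition = "manipulated", factor_type = "warming",
              role = "mixture", richness = 8L)
  )
  expect_equal(nrow(build_effect_table(two_cond, "nbe")), 4)
  delta <- build_effect_table(two_cond, "delta_nbe")
  expect_equal(nrow(delta), 2)
  expect_true(all(delta$factor_type == "warming"))

  orphan <- make_cell(study_id = "S9", role = "mixture", richness = 4L)
  eff <- build_effect_table(orphan, "nbe")
  expect_equal(nrow(eff), 0)
  expect_equal(attr(eff, "diagnostics")$cell_id, orphan$cell_id)
})
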