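# Builders for small in-code fixtures. make_cell() fills every schema column
# with a consistent default so tests only state what they care about.

make_cell <- function(study_id = "S1", condition = "ambient",
                      factor_type = NA_character_,
                      n_factors = if (condition == "ambient") 0L else 1L,
                      role = "monoculture",
                      richness = if (role == "monoculture") 1L else 4L,
                      response_kind = "invader_performance",
                      metric = "biomass", invader_type = "all",
                      mean = 10, sd = 2, n = 5L,
                      duration_years = 2, unit_size_m2 = 1) {
  tibble::tibble(
    cell_id = paste(study_id, condition,
                    ifelse(is.na(factor_type), "none", factor_type),
                    role, richness, response_kind, metric, invader_type,
                    sep = ":"),
    study_id = study_id, condition = condition, factor_type = factor_type,
    n_factors = as.integer(n_factors), role = role,
    richness = as.integer(richness), response_kind = response_kind,
    metric = metric, invader_type = invader_type,
    mean = mean, sd = sd, n = as.integer(n),
    duration_years = duration_years, unit_size_m2 = unit_size_m2
  )
}

# Direct simulation from the three-level meta-analytic model (not via the
# cell generator): y_i = mu + X extras + u_study + e_obs + sampling error.
simulate_effects <- function(k = 30, n_studies = 10, mu = 0.3,
                             tau2_study = 0.04, tau2_obs = 0.02,
                             v_range = c(0.02, 0.08)) {
  study <- rep_len(sprintf("S%02d", seq_len(n_studies)), k)
  v <- stats::runif(k, v_range[1], v_range[2])
  u <- stats::rnorm(n_studies, 0, sqrt(tau2_study))
  y <- mu + u[match(study, unique(study))] +
    stats::rnorm(k, 0, sqrt(tau2_obs)) + stats::rnorm(k, 0, sqrt(v))
  eff <- tibble::tibble(
    effect_id = sprintf("e%03d", seq_len(k)),
    es_type = "nbe_invasion", value = y, variance = v, study_id = study,
    condition = "ambient", factor_type = NA_character_, n_factors = 0L,
    richness = sample(c(2L, 4L, 8L, 16L), k, replace = TRUE),
    response_kind = "invader_performance",
    metric = "biomass", invader_type = "all",
    duration_years = stats::runif(k, 0.25, 24),
    unit_size_m2 = stats::runif(k, 0.01, 47.5),
    stratum = NA_character_
  )
  eff$source_cells <- purrr::map(seq_len(k), function(i) {
    tibble::tibble(cell_id = paste0("c", i), sign = 1,
                   mean = 1, sd = sqrt(v[i] * 5), n = 5L)
  })
  eff
}

# Dense grid search over the two variance components, refined `refine` times
# around the running optimum: the independent REML oracle.
grid_reml <- function(effects, vcv, moderators = ~ 1, lim = c(0, 2),
                      n_grid = 50, refine = 3) {
  y <- effects$value
  X <- nbemeta:::.design_matrix(effects, moderators)$X
  Zs <- stats::model.matrix(~ 0 + factor(effects$study_id))
  ZZt <- tcrossprod(Zs)
  V <- unclass(vcv)
  lo <- c(lim[1], lim[1]); hi <- c(lim[2], lim[2])
  best <- NULL
  for (r in seq_len(refine + 1)) {
    g1 <- seq(lo[1], hi[1], length.out = n_grid)
    g2 <- seq(lo[2], hi[2], length.out = n_grid)
    ll <- outer(g1, g2, Vectorize(function(a, b)
      nbemeta:::.reml_loglik(c(a, b), y, X, V, ZZt)))
    idx <- arrayInd(which.max(ll), dim(ll))
    best <- list(par = c(g1[idx[1]], g2[idx[2]]), loglik = max(ll))
    step <- c(diff(g1[1:2]), diff(g2[1:2]))
    lo <- pmax(best$par - 2 * step, 0)
    hi <- best$par + 2 * step
  }
  best
}
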