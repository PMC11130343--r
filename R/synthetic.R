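# Generative mirror of the analysis data model: studies with a shared true
# biodiversity effect, factor-specific shifts, study- and observation-level
# heterogeneity, and lognormal replicate noise at the cell level. Lognormal
# replicates keep cell means positive and make the log response ratio
# unbiased to first order.

.factor_categories <- c("warming", "drought", "elevated_CO2",
                        "eutrophication", "pesticide", "grazing", "fire",
                        "physical_disturbance", "combination_2",
                        "combination_3")

#' Configuration for the synthetic meta-dataset generator
#'
#' Defines the ground truth of a simulated multi-study invasion experiment
#' compilation: how many studies, which environmental change factors they
#' manipulate, the true net biodiversity effect and its per-factor shifts,
#' heterogeneity variances, and cell-level replicate noise. The defaults
#' emulate a 25-study grassland compilation: richness 1-60, durations 0.25-24
#' years, plot sizes 0.01-47.5 m^2, eight single factors plus two- and
#' three-factor combinations, and true delta-NBE shifts of +0.8 under
#' warming, -0.5 under drought, +0.16 for two co-acting factors and +0.64 for
#' three.
#'
#' @param n_studies Number of studies (default 25).
#' @param richness_pool Mixture richness levels sampled per study (default
#'   `c(2, 4, 8, 16, 60)`; monocultures are always present).
#' @param levels_per_study Range of mixture diversity levels per study
#'   (default 2 to 3).
#' @param factor_probs Named probabilities over the factor categories (eight
#'   single factors, `combination_2`, `combination_3`); default uniform. Each
#'   category is first allocated `floor(prob * n_studies)` studies so that no
#'   category is empty by chance, the remainder at random.
#' @param mu_nbe True mean NBE under ambient conditions (default 0.4).
#' @param delta_shifts Named vector of true delta-NBE per factor category
#'   (log-ratio units).
#' @param prod_shifts Named vector of true monoculture-productivity log
#'   response per factor category (positive = favorable condition).
#' @param mono_invader_shifts Named vector of true shifts of log invader
#'   performance in monocultures under each factor (how the factor itself
#'   helps or hinders the invader).
#' @param mu_nbe_productivity True mean productivity NBE (default -0.3:
#'   mixtures overyield, so the mono/mix log ratio is negative).
#' @param tau2_study,tau2_obs Study- and observation-level heterogeneity
#'   variances of the true NBE (defaults 0.04 and 0.02).
#' @param cv Lognormal coefficient of variation of cell replicates (0.3).
#' @param n_rep Replicates per cell (default 5).
#' @param prop_productivity Fraction of studies also reporting resident
#'   productivity (default 16/25).
#' @param invader_type_probs Named probabilities of each study's invader
#'   type.
#' @param metric_probs Named probabilities of each study's response metric.
#' @param baseline_mean True monoculture invader performance under ambient
#'   conditions (metric units; default 100).
#' @param baseline_productivity True ambient monoculture productivity
#'   (default 500).
#' @param seed Integer seed; the generator is byte-deterministic given the
#'   config.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_studies = 25,
    richness_pool = c(2L, 4L, 8L, 16L, 60L),
    levels_per_study = c(2L, 3L),
    factor_probs = NULL,
    mu_nbe = 0.4,
    delta_shifts = c(warming = 0.8, drought = -0.5, elevated_CO2 = 0,
                     eutrophication = 0, pesticide = 0, grazing = 0,
                     fire = 0, physical_disturbance = 0,
                     combination_2 = 0.16, combination_3 = 0.64),
    prod_shifts = c(warming = 0.3, drought = -0.2, elevated_CO2 = 0,
                    eutrophication = 0.4, pesticide = 0, grazing = -0.4,
                    fire = 0, physical_disturbance = 0,
                    combination_2 = 0, combination_3 = -0.5),
    mono_invader_shifts = c(warming = 0.4, drought = -0.4, elevated_CO2 = 0,
                            eutrophication = 0, pesticide = 0, grazing = 0,
                            fire = 0, physical_disturbance = 0,
                            combination_2 = 0, combination_3 = 0),
    mu_nbe_productivity = -0.3,
    tau2_study = 0.04,
    tau2_obs = 0.02,
    cv = 0.3,
    n_rep = 5L,
    prop_productivity = 16 / 25,
    invader_type_probs = c(all = 0.4, internal = 0.2,
                           external_native = 0.2, external_alien = 0.2),
    metric_probs = c(biomass = 0.8, cover = 0.2),
    baseline_mean = 100,
    baseline_productivity = 500,
    seed = 1L) {
  if (is.null(factor_probs)) {
    factor_probs <- stats::setNames(
      rep(1 / length(.factor_categories), length(.factor_categories)),
      .factor_categories)
  }
  cfg <- list(
    n_studies = as.integer(n_studies), richness_pool = as.integer(richness_pool),
    levels_per_study = as.integer(levels_per_study),
    factor_probs = factor_probs, mu_nbe = mu_nbe,
    delta_shifts = delta_shifts, prod_shifts = prod_shifts,
    mono_invader_shifts = mono_invader_shifts,
    mu_nbe_productivity = mu_nbe_productivity,
    tau2_study = tau2_study, tau2_obs = tau2_obs, cv = cv,
    n_rep = as.integer(n_rep), prop_productivity = prop_productivity,
    invader_type_probs = invader_type_probs, metric_probs = metric_probs,
    baseline_mean = baseline_mean,
    baseline_productivity = baseline_productivity,
    seed = as.integer(seed)
  )
  .validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

.validate_config <- function(cfg) {
  if (cfg$n_studies < 1) stop("config error: n_studies must be >= 1",
                              call. = FALSE)
  if (any(c(cfg$tau2_study, cfg$tau2_obs) < 0)) {
    stop("config error: heterogeneity variances must be >= 0", call. = FALSE)
  }
  if (cfg$cv < 0) stop("config error: cv must be >= 0", call. = FALSE)
  if (cfg$n_rep < 2) stop("config error: n_rep must be >= 2 (an SD is needed)",
                          call. = FALSE)
  if (abs(sum(cfg$factor_probs) - 1) > 1e-8) {
    stop("config error: factor_probs must sum to 1", call. = FALSE)
  }
  if (!setequal(names(cfg$factor_probs), .factor_categories)) {
    stop("config error: factor_probs must cover exactly the factor categories",
         call. = FALSE)
  }
  for (nm in c("delta_shifts", "prod_shifts", "mono_invader_shifts")) {
    if (!all(.factor_categories %in% names(cfg[[nm]]))) {
      stop("config error: ", nm, " must name every factor category",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

# Allocate one factor category per study: floor(prob * n) deterministic slots
# per category (cycled in order), remaining studies drawn at random.
.assign_factors <- function(cfg) {
  base_counts <- floor(cfg$factor_probs * cfg$n_studies)
  assigned <- rep(names(base_counts), times = base_counts)
  n_left <- cfg$n_studies - length(assigned)
  if (n_left > 0) {
    assigned <- c(assigned,
                  sample(names(cfg$factor_probs), n_left, replace = TRUE,
                         prob = cfg$factor_probs))
  }
  sample(assigned)  # shuffle so category order is not confounded with study id
}

.category_fields <- function(category) {
  if (grepl("^combination_", category)) {
    list(factor_type = "combination",
         n_factors = as.integer(sub("combination_", "", category)))
  } else {
    list(factor_type = category, n_factors = 1L)
  }
}

# Draw n_rep lognormal replicates with expectation m and coefficient of
# variation cv; return the sample mean and SD.
.lognormal_cell <- function(m, cv, n_rep) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(m) - sdlog^2 / 2
  x <- stats::rlnorm(n_rep, meanlog, sdlog)
  c(mean = mean(x), sd = stats::sd(x))
}

#' Generate a synthetic cell-level meta-dataset
#'
#' Simulates the full compilation the analysis ingests. For each study: a
#' factor category, invader type, metric, duration and plot size are drawn; a
#' study effect `u_s ~ N(0, tau2_study)` perturbs the true NBE; for each
#' mixture richness level and condition an observation effect
#' `e ~ N(0, tau2_obs)` is added; the true log mixture invader performance is
#' the monoculture's minus the true NBE (`mu_nbe + factor shift + u_s + e`
#' under manipulation); each cell's reported mean and SD come from `n_rep`
#' lognormal replicates at the stated coefficient of variation. A subset of
#' studies also reports resident productivity (monoculture and mixture cells)
#' with its own true factor shifts.
#'
#' @param config A [synthetic_config()].
#' @return A validated cell tibble (same shape as [read_cells()] output),
#'   deterministic given `config$seed`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  .validate_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)
  cfg <- config

  categories <- .assign_factors(cfg)
  has_prod <- seq_len(cfg$n_studies) <= round(cfg$prop_productivity *
                                                cfg$n_studies)
  rows <- list()
  emit <- function(study, condition, category, role, richness, response,
                   metric, invader, true_mean, duration, unit) {
    cf <- if (condition == "ambient") {
      list(factor_type = NA_character_, n_factors = 0L)
    } else .category_fields(category)
    cell <- .lognormal_cell(true_mean, cfg$cv, cfg$n_rep)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      study_id = study, condition = condition,
      factor_type = cf$factor_type, n_factors = cf$n_factors,
      role = role, richness = as.integer(richness),
      response_kind = response, metric = metric, invader_type = invader,
      mean = unname(cell["mean"]), sd = unname(cell["sd"]), n = cfg$n_rep,
      duration_years = duration, unit_size_m2 = unit
    )
  }

  for (s in seq_len(cfg$n_studies)) {
    study <- sprintf("S%02d", s)
    category <- categories[s]
    invader <- sample(names(cfg$invader_type_probs), 1,
                      prob = cfg$invader_type_probs)
    metric <- sample(names(cfg$metric_probs), 1, prob = cfg$metric_probs)
    duration <- exp(stats::runif(1, log(0.25), log(24)))
    unit <- exp(stats::runif(1, log(0.01), log(47.5)))
    u_s <- stats::rnorm(1, 0, sqrt(cfg$tau2_study))
    n_levels <- sample(seq(cfg$levels_per_study[1],
                           cfg$levels_per_study[2]), 1)
    richness_levels <- sort(sample(cfg$richness_pool, n_levels))

    log_mono_amb <- log(cfg$baseline_mean)
    log_mono_man <- log_mono_amb + cfg$mono_invader_shifts[[category]]
    emit(study, "ambient", category, "monoculture", 1,
         "invader_performance", metric, invader, exp(log_mono_amb),
         duration, unit)
    emit(study, "manipulated", category, "monoculture", 1,
         "invader_performance", metric, invader, exp(log_mono_man),
         duration, unit)
    for (r in richness_levels) {
      nbe_amb <- cfg$mu_nbe + u_s + stats::rnorm(1, 0, sqrt(cfg$tau2_obs))
      nbe_man <- cfg$mu_nbe + cfg$delta_shifts[[category]] + u_s +
        stats::rnorm(1, 0, sqrt(cfg$tau2_obs))
      emit(study, "ambient", category, "mixture", r,
           "invader_performance", metric, invader,
           exp(log_mono_amb - nbe_amb), duration, unit)
      emit(study, "manipulated", category, "mixture", r,
           "invader_performance", metric, invader,
           exp(log_mono_man - nbe_man), duration, unit)
    }

    if (has_prod[s]) {
      log_prod_amb <- log(cfg$baseline_productivity)
      log_prod_man <- log_prod_amb + cfg$prod_shifts[[category]]
      emit(study, "ambient", category, "monoculture", 1,
           "resident_productivity", "biomass", invader,
           exp(log_prod_amb), duration, unit)
      emit(study, "manipulated", category, "monoculture", 1,
           "resident_productivity", "biomass", invader,
           exp(log_prod_man), duration, unit)
      for (r in richness_levels) {
        pn_amb <- cfg$mu_nbe_productivity + u_s +
          stats::rnorm(1, 0, sqrt(cfg$tau2_obs))
        pn_man <- cfg$mu_nbe_productivity + u_s +
          stats::rnorm(1, 0, sqrt(cfg$tau2_obs))
        emit(study, "ambient", category, "mixture", r,
             "resident_productivity", "biomass", invader,
             exp(log_prod_amb - pn_amb), duration, unit)
        emit(study, "manipulated", category, "mixture", r,
             "resident_productivity", "biomass", invader,
             exp(log_prod_man - pn_man), duration, unit)
      }
    }
  }
  cells <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      cell_id = paste(.data$study_id, .data$condition,
                      dplyr::coalesce(.data$factor_type, "none"),
                      .data$role, .data$richness, .data$response_kind,
                      .data$metric, .data$invader_type, sep = ":"),
      .before = 1
    )
  attr(cells, "diagnostics") <- validate_cells(cells)
  attr(cells, "truth") <- ground_truth(config)
  cells
}

#' Ground-truth parameter table of a synthetic configuration
#'
#' @param config A [synthetic_config()].
#' @return A tibble `parameter`, `category` (`NA` for global parameters),
#'   `value` listing every generative parameter, for recovery tests.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  global <- tibble::tibble(
    parameter = c("mu_nbe", "mu_nbe_productivity", "tau2_study", "tau2_obs",
                  "cv", "n_rep", "n_studies"),
    category = NA_character_,
    value = c(config$mu_nbe, config$mu_nbe_productivity, config$tau2_study,
              config$tau2_obs, config$cv, config$n_rep, config$n_studies)
  )
  per_factor <- function(vec, name) {
    tibble::tibble(parameter = name, category = names(vec),
                   value = unname(vec))
  }
  dplyr::bind_rows(
    global,
    per_factor(config$delta_shifts[.factor_categories], "delta_nbe"),
    per_factor(config$prod_shifts[.factor_categories], "prod_effect"),
    per_factor(config$mono_invader_shifts[.factor_categories],
               "mono_invader_shift")
  )
}
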