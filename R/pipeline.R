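# The analyses mirror the structure of a multi-factor invasion meta-analysis:
# an omnibus ambient-vs-manipulated model, stratified per-factor models with
# Bonferroni-corrected means, moderator slopes (richness, productivity,
# stress), and bias/influence diagnostics. Stratified fits are used rather
# than one omnibus interaction model (the invader-type analysis alone uses an
# explicit interaction term).

#' Label each effect with its environmental factor category
#'
#' Single factors keep their `factor_type`; multi-factor manipulations are
#' labelled `combination_2` / `combination_3`.
#'
#' @param effects An effect tibble.
#' @return The tibble with a `factor_category` column appended.
#' @export
add_factor_category <- function(effects) {
  dplyr::mutate(effects, factor_category = dplyr::case_when(
    is.na(.data$n_factors) | .data$n_factors == 0L ~ NA_character_,
    .data$n_factors >= 2L ~ paste0("combination_", .data$n_factors),
    TRUE ~ .data$factor_type
  ))
}

#' Covariate-adjusted overall mean of a fitted model
#'
#' The model prediction averaged over the fitted effects (continuous
#' covariates at their observed means), with a Bonferroni-corrected Wald
#' interval — the per-stratum summary used when models are fitted separately
#' per factor category.
#'
#' @param fit A `meta_fit` object.
#' @param k Bonferroni family size (default 1, an ordinary 95% interval).
#' @param alpha Family-wise error rate.
#' @return A one-row tibble: `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `k`, `significant`.
#' @export
adjusted_mean <- function(fit, k = 1, alpha = 0.05) {
  stopifnot(inherits(fit, "meta_fit"))
  xb <- colMeans(fit$X)
  est <- drop(crossprod(xb, fit$beta))
  se <- sqrt(drop(crossprod(xb, fit$vb %*% xb)))
  crit <- stats::qnorm(1 - alpha / (2 * k))
  tibble::tibble(estimate = est, std.error = se,
                 conf.low = est - crit * se, conf.high = est + crit * se,
                 k = k, significant = (est - crit * se) > 0 |
                   (est + crit * se) < 0)
}

# Fit a subset with as much of the requested covariate set as the subset
# supports: constant covariates are dropped, then covariates are removed from
# the tail of the list until k >= p + 2.
.fit_subset <- function(effects, covariates = c("richness", "duration_years",
                                                "unit_size_m2"),
                        vcv = NULL) {
  covs <- covariates[vapply(covariates, function(v)
    length(unique(effects[[v]])) > 1, logical(1))]
  # keep only covariates that add rank (small strata can make study-level
  # covariates collinear with each other)
  kept <- character()
  X <- matrix(1, nrow(effects), 1)
  for (v in covs) {
    cand <- cbind(X, effects[[v]])
    if (qr(cand)$rank > qr(X)$rank) {
      X <- cand
      kept <- c(kept, v)
    }
  }
  covs <- kept
  repeat {
    p <- length(covs) + 1L
    if (nrow(effects) >= p + 2 || length(covs) == 0) break
    covs <- covs[-length(covs)]
  }
  if (nrow(effects) < 3) {
    stop("too few effects in subset (", nrow(effects), ")", call. = FALSE)
  }
  rhs <- if (length(covs) == 0) "1" else paste(covs, collapse = " + ")
  fit_meta(effects, vcv = vcv,
           moderators = stats::as.formula(paste("~", rhs)))
}

.an_nbe_by_condition <- function(effects_nbe) {
  fit <- fit_meta(effects_nbe,
                  moderators = ~ condition + richness + duration_years +
                    unit_size_m2)
  qm <- qm_test(fit, "conditionmanipulated")
  mm <- marginal_means(fit, "condition")
  dplyr::mutate(mm, QM = qm$QM, df = qm$df, QM_p = qm$p.value)
}

.an_delta_by_category <- function(effects_delta, family = NULL) {
  tab <- add_factor_category(effects_delta)
  cats <- sort(unique(tab$factor_category))
  if (is.null(family)) family <- length(cats)
  purrr::map_dfr(cats, function(cat) {
    sub <- dplyr::filter(tab, .data$factor_category == cat)
    res <- tryCatch({
      fit <- .fit_subset(sub)
      dplyr::mutate(adjusted_mean(fit, k = family),
                    n_effects = nrow(sub), n_studies =
                      dplyr::n_distinct(sub$study_id))
    }, error = function(e) {
      tibble::tibble(estimate = NA_real_, std.error = NA_real_,
                     conf.low = NA_real_, conf.high = NA_real_,
                     k = family, significant = NA,
                     n_effects = nrow(sub),
                     n_studies = dplyr::n_distinct(sub$study_id))
    })
    dplyr::mutate(res, factor_category = cat, .before = 1)
  })
}

.an_invader_type <- function(effects_nbe) {
  usable <- dplyr::filter(effects_nbe,
                          .data$invader_type %in% c("internal",
                                                    "external_native",
                                                    "external_alien"))
  fit <- fit_meta(usable,
                  moderators = ~ condition * invader_type + richness +
                    duration_years + unit_size_m2)
  inter <- grep(":", names(fit$beta), value = TRUE)
  qm <- qm_test(fit, inter)
  contrasts <- pairwise_contrasts(fit, "invader_type")
  list(qm_interaction = qm, contrasts = contrasts,
       marginal_means = marginal_means(fit, "invader_type"))
}

.an_productivity_relationship <- function(effects_nbe, effects_prod_nbe) {
  prod_vals <- effects_prod_nbe |>
    dplyr::select("study_id", "condition", "richness",
                  prod_nbe = "value")
  purrr::map_dfr(c("ambient", "manipulated"), function(cond) {
    sub <- dplyr::filter(effects_nbe, .data$condition == cond) |>
      dplyr::inner_join(dplyr::filter(prod_vals, .data$condition == cond),
                        by = c("study_id", "condition", "richness"))
    res <- tryCatch(
      meta_regress_slope(sub, moderator = "prod_nbe"),
      error = function(e) tibble::tibble(
        moderator = "prod_nbe", slope = NA_real_, std.error = NA_real_,
        QM = NA_real_, df = NA_integer_, p.value = NA_real_)
    )
    dplyr::mutate(tibble::as_tibble(res), condition = cond,
                  n_effects = nrow(sub), .before = 1)
  })
}

.an_richness_relationship <- function(effects_nbe) {
  purrr::map_dfr(c("ambient", "manipulated"), function(cond) {
    sub <- dplyr::filter(effects_nbe, .data$condition == cond)
    res <- tryCatch(
      meta_regress_slope(sub, moderator = "richness",
                         covariates = ~ duration_years + unit_size_m2),
      error = function(e) tibble::tibble(
        moderator = "richness", slope = NA_real_, std.error = NA_real_,
        QM = NA_real_, df = NA_integer_, p.value = NA_real_)
    )
    dplyr::mutate(tibble::as_tibble(res), condition = cond,
                  n_effects = nrow(sub), .before = 1)
  })
}

.an_factor_effect_stress <- function(effects_delta, effects_prod) {
  prod_tab <- add_factor_category(effects_prod)
  cats <- sort(unique(prod_tab$factor_category))
  prod_means <- purrr::map_dfr(cats, function(cat) {
    sub <- dplyr::filter(prod_tab, .data$factor_category == cat)
    res <- tryCatch({
      fit <- .fit_subset(sub, covariates = c("duration_years",
                                             "unit_size_m2"))
      adjusted_mean(fit, k = length(cats))
    }, error = function(e) tibble::tibble(
      estimate = NA_real_, std.error = NA_real_, conf.low = NA_real_,
      conf.high = NA_real_, k = length(cats), significant = NA))
    dplyr::mutate(res, factor_category = cat, n_effects = nrow(sub),
                  .before = 1)
  })
  # stress relationship: delta-NBE against each study's productivity response
  study_prod <- effects_prod |>
    dplyr::group_by(.data$study_id) |>
    dplyr::summarise(prod_effect = mean(.data$value), .groups = "drop")
  joined <- dplyr::inner_join(effects_delta, study_prod, by = "study_id")
  slope <- tryCatch(
    meta_regress_slope(joined, moderator = "prod_effect"),
    error = function(e) tibble::tibble(
      moderator = "prod_effect", slope = NA_real_, std.error = NA_real_,
      QM = NA_real_, df = NA_integer_, p.value = NA_real_)
  )
  list(factor_productivity_means = prod_means,
       stress_relationship = dplyr::mutate(tibble::as_tibble(slope),
                                           n_effects = nrow(joined)))
}

#' Run the full meta-analysis pipeline
#'
#' Orchestrates ingest, effect-size construction, sampling-VCV assembly,
#' the per-question model fits, and bias/sensitivity diagnostics. Analyses
#' run in a fixed order; a failure in one is recorded in the report and does
#' not stop the others. Deterministic given the input (and, for synthetic
#' input, the config seed).
#'
#' @param cells A validated cell tibble ([read_cells()] or
#'   [generate_dataset()]); alternatively pass `input` or `config`.
#' @param input Path to a cell-level CSV (used when `cells` is `NULL`).
#' @param config A [synthetic_config()] (used when `cells` and `input` are
#'   `NULL`).
#' @param analyses Character vector of analyses to run; any subset of
#'   `c("nbe_by_condition", "delta_nbe_by_factor", "invader_type",
#'   "productivity_relationship", "richness_relationship",
#'   "factor_effect_stress", "publication_bias", "sensitivity")`.
#' @param metric_preference When a study reports both biomass and cover,
#'   keep only this metric for invader performance (default `"biomass"`;
#'   `NA` keeps everything).
#' @param cook_threshold Cook's distance flagging threshold (default `4/k`).
#' @param out_dir Optional directory; when given, every result table is
#'   written as CSV and the manifest as JSON.
#' @return A list of class `nbe_report`: `tables` (one element per analysis,
#'   each a tibble or list of tibbles), `failures` (named character vector of
#'   captured error messages), `effects` (the NBE and delta-NBE tables),
#'   and `manifest`.
#' @export
run_pipeline <- function(cells = NULL, input = NULL, config = NULL,
                         analyses = c("nbe_by_condition",
                                      "delta_nbe_by_factor",
                                      "invader_type",
                                      "productivity_relationship",
                                      "richness_relationship",
                                      "factor_effect_stress",
                                      "publication_bias", "sensitivity"),
                         metric_preference = "biomass",
                         cook_threshold = NULL,
                         out_dir = NULL) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (is.null(cells)) {
    cells <- if (!is.null(input)) read_cells(input)
             else if (!is.null(config)) generate_dataset(config)
             else stop("provide cells, input, or config", call. = FALSE)
  }
  if (!is.na(metric_preference)) {
    both <- cells |>
      dplyr::filter(.data$response_kind == "invader_performance") |>
      dplyr::distinct(.data$study_id, .data$metric) |>
      dplyr::count(.data$study_id) |>
      dplyr::filter(.data$n > 1)
    cells <- dplyr::filter(
      cells,
      !(.data$study_id %in% both$study_id &
          .data$response_kind == "invader_performance" &
          .data$metric != metric_preference))
  }

  nbe <- build_effect_table(cells, "nbe")
  delta <- build_effect_table(cells, "delta_nbe")
  prod_nbe_cells <- dplyr::filter(cells,
                                  .data$response_kind ==
                                    "resident_productivity")
  prod_nbe <- build_effect_table(prod_nbe_cells, "nbe")
  fx_prod <- build_effect_table(cells, "factor_effect_productivity")

  tables <- list()
  failures <- character()
  run_one <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      failures[[name]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) tables[[name]] <<- res
  }

  if ("nbe_by_condition" %in% analyses)
    run_one("nbe_by_condition", .an_nbe_by_condition(nbe))
  if ("delta_nbe_by_factor" %in% analyses)
    run_one("delta_nbe_by_factor", .an_delta_by_category(delta))
  if ("invader_type" %in% analyses)
    run_one("invader_type", .an_invader_type(nbe))
  if ("productivity_relationship" %in% analyses)
    run_one("productivity_relationship",
            .an_productivity_relationship(nbe, prod_nbe))
  if ("richness_relationship" %in% analyses)
    run_one("richness_relationship", .an_richness_relationship(nbe))
  if ("factor_effect_stress" %in% analyses)
    run_one("factor_effect_stress",
            .an_factor_effect_stress(delta, fx_prod))
  if ("publication_bias" %in% analyses)
    run_one("publication_bias", {
      fit <- fit_meta(delta, moderators = ~ richness + duration_years +
                        unit_size_m2)
      list(egger = egger_test(delta,
                              moderators = ~ richness + duration_years +
                                unit_size_m2),
           funnel = funnel_data(fit))
    })
  if ("sensitivity" %in% analyses)
    run_one("sensitivity", {
      infl <- cooks_distance_meta(delta,
                                  moderators = ~ richness + duration_years +
                                    unit_size_m2,
                                  threshold = cook_threshold)
      refit <- sensitivity_refit(delta,
                                 moderators = ~ richness + duration_years +
                                   unit_size_m2,
                                 flagged = infl$effect_id[infl$flagged %in%
                                                            TRUE])
      list(influence = infl, refit_glance = glance(refit),
           refit_mean = adjusted_mean(refit))
    })

  manifest <- list(
    analyses = analyses,
    n_cells = nrow(cells),
    n_nbe = nrow(nbe), n_delta_nbe = nrow(delta),
    n_productivity_nbe = nrow(prod_nbe),
    n_factor_effect_productivity = nrow(fx_prod),
    metric_preference = metric_preference,
    failures = as.list(failures),
    seed = if (!is.null(config)) config$seed else NA
  )
  report <- structure(list(tables = tables, failures = failures,
                           effects = list(nbe = nbe, delta_nbe = delta,
                                          productivity_nbe = prod_nbe,
                                          factor_effect_productivity =
                                            fx_prod),
                           manifest = manifest),
                      class = "nbe_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write all tables of a pipeline report to disk
#'
#' One subdirectory per analysis, tables as CSV, manifest as JSON.
#'
#' @param report An `nbe_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `invisible(out_dir)`.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  flatten <- function(x, prefix) {
    if (is.data.frame(x)) {
      write_table(x, file.path(out_dir, paste0(prefix, ".csv")))
    } else if (is.list(x)) {
      dir.create(file.path(out_dir, prefix), showWarnings = FALSE)
      for (nm in names(x)) flatten(x[[nm]], file.path(prefix, nm))
    }
  }
  for (nm in names(report$tables)) flatten(report$tables[[nm]], nm)
  for (nm in names(report$effects)) {
    write_table(dplyr::select(report$effects[[nm]], -"source_cells"),
                file.path(out_dir, paste0("effects_", nm, ".csv")))
  }
  write_manifest(report$manifest, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' @export
print.nbe_report <- function(x, ...) {
  cat("Invasion-resistance meta-analysis report\n")
  cat(sprintf("  cells: %d; NBE: %d; delta-NBE: %d\n",
              x$manifest$n_cells, x$manifest$n_nbe, x$manifest$n_delta_nbe))
  cat("  analyses:", paste(names(x$tables), collapse = ", "), "\n")
  if (length(x$failures) > 0) {
    cat("  failures:\n")
    for (nm in names(x$failures)) cat("   -", nm, ":", x$failures[[nm]], "\n")
  }
  invisible(x)
}
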