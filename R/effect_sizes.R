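# Effect sizes are log response ratios with first-order (delta-method)
# sampling variances. Each effect carries its provenance: the summary cells it
# was built from, each with a sign giving the cell's log-scale contribution.
# The shared-cell signed provenance is what makes the sampling
# variance-covariance matrix computable in build_vcv().

# Per-cell delta-method variance contribution: Var[ln(mean_hat)] ~ sd^2/(n mean^2)
.cell_var <- function(cell) cell$sd^2 / (cell$n * cell$mean^2)

.check_cell <- function(cell, what) {
  if (!is.data.frame(cell) || nrow(cell) != 1L) {
    stop(what, " must be a single cell (one-row tibble)", call. = FALSE)
  }
  if (is.na(cell$mean) || cell$mean <= 0) {
    stop("domain error: ", what, " has mean <= 0; log ratio undefined",
         call. = FALSE)
  }
  invisible(cell)
}

.provenance <- function(cells, signs) {
  tibble::tibble(
    cell_id = cells$cell_id, sign = signs,
    mean = cells$mean, sd = cells$sd, n = cells$n
  )
}

.effect_row <- function(effect_id, es_type, value, variance, template,
                        source_cells, stratum = NA_character_) {
  tibble::tibble(
    effect_id = effect_id,
    es_type = es_type,
    value = value,
    variance = variance,
    study_id = template$study_id,
    condition = template$condition,
    factor_type = template$factor_type,
    n_factors = template$n_factors,
    richness = template$richness,
    response_kind = template$response_kind,
    metric = template$metric,
    invader_type = template$invader_type,
    duration_years = template$duration_years,
    unit_size_m2 = template$unit_size_m2,
    stratum = stratum,
    source_cells = list(source_cells)
  )
}

#' Net biodiversity effect (NBE) of one monoculture/mixture pair
#'
#' Computes the log response ratio `ln(X_mono / X_mix)` of invader performance
#' (or resident productivity) in the monoculture control versus a mixture, with
#' the delta-method sampling variance
#' `sd_mono^2/(n_mono * mean_mono^2) + sd_mix^2/(n_mix * mean_mix^2)`.
#' Positive values mean mixtures resist invasion better than monocultures.
#'
#' @param mono,mix One-row cell tibbles (rows of a [read_cells()] /
#'   [generate_dataset()] table) from the same study, condition, response kind
#'   and metric; `mono` must be a monoculture, `mix` a mixture.
#' @return A one-row effect tibble with moderators inherited from the mixture
#'   cell and signed provenance in the `source_cells` list-column.
#' @export
#' @examples
#' cells <- generate_dataset(synthetic_config(n_studies = 2, seed = 1))
#' grp <- dplyr::filter(cells, study_id == "S01", condition == "ambient",
#'                      response_kind == "invader_performance")
#' compute_nbe(dplyr::filter(grp, role == "monoculture"),
#'             dplyr::slice(dplyr::filter(grp, role == "mixture"), 1))
compute_nbe <- function(mono, mix) {
  .check_cell(mono, "mono"); .check_cell(mix, "mix")
  keys <- c("study_id", "condition", "response_kind", "metric")
  same <- vapply(keys, function(k) identical(mono[[k]], mix[[k]]), logical(1))
  if (!all(same)) {
    stop("pairing error: cells differ on ",
         paste(keys[!same], collapse = ", "), call. = FALSE)
  }
  if (mono$role != "monoculture" || mix$role != "mixture") {
    stop("pairing error: expected a monoculture and a mixture cell",
         call. = FALSE)
  }
  es_type <- if (mix$response_kind == "invader_performance")
    "nbe_invasion" else "nbe_productivity"
  .effect_row(
    effect_id = paste0("nbe|", mix$cell_id),
    es_type = es_type,
    value = log(mono$mean / mix$mean),
    variance = .cell_var(mono) + .cell_var(mix),
    template = mix,
    source_cells = .provenance(dplyr::bind_rows(mono, mix), c(1, -1))
  )
}

#' Change in NBE between ambient and manipulated conditions
#'
#' The contrast `delta-NBE = NBE_M - NBE_A` between a manipulated-condition
#' and an ambient-condition NBE at the same diversity level, with variance
#' `v_M + v_A` (the two NBEs share no cells). Positive values mean the
#' environmental change strengthens the biodiversity effect. Provenance is the
#' four underlying cells, with the ambient pair's signs flipped, so that the
#' value equals the signed sum of log cell means.
#'
#' @param nbe_ambient,nbe_manipulated One-row effect tibbles from
#'   [compute_nbe()] for the same study, richness and response kind, under
#'   ambient and manipulated conditions respectively.
#' @return A one-row effect tibble; `factor_type` and `n_factors` are
#'   inherited from the manipulated side, `condition` is `NA`.
#' @export
compute_delta_nbe <- function(nbe_ambient, nbe_manipulated) {
  ok_types <- c("nbe_invasion", "nbe_productivity")
  if (!(nbe_ambient$es_type %in% ok_types) ||
      !identical(nbe_ambient$es_type, nbe_manipulated$es_type)) {
    stop("pairing error: both effects must be NBEs of the same kind",
         call. = FALSE)
  }
  if (nbe_ambient$condition != "ambient" ||
      nbe_manipulated$condition != "manipulated") {
    stop("pairing error: need one ambient and one manipulated NBE",
         call. = FALSE)
  }
  keys <- c("study_id", "richness", "response_kind")
  same <- vapply(keys, function(k)
    identical(nbe_ambient[[k]], nbe_manipulated[[k]]), logical(1))
  if (!all(same)) {
    stop("pairing error: effects differ on ",
         paste(keys[!same], collapse = ", "), call. = FALSE)
  }
  amb <- nbe_ambient$source_cells[[1]]
  man <- nbe_manipulated$source_cells[[1]]
  amb$sign <- -amb$sign
  template <- nbe_manipulated  # carries factor_type, n_factors, moderators
  template$condition <- NA_character_
  .effect_row(
    effect_id = paste0("dnbe|", sub("^nbe\\|", "", nbe_manipulated$effect_id)),
    es_type = "delta_nbe",
    value = nbe_manipulated$value - nbe_ambient$value,
    variance = nbe_manipulated$variance + nbe_ambient$variance,
    template = template,
    source_cells = dplyr::bind_rows(man, amb)
  )
}

#' Environmental factor effect on invasion resistance
#'
#' The log response ratio `ln(X_A / X_M)` of invader performance under ambient
#' versus manipulated conditions within one stratum (both cells monocultures,
#' or both mixtures at the same richness), with the delta-method variance.
#' Positive values mean the factor increases invasion resistance (the invader
#' performs worse under the manipulation).
#'
#' @param cell_A,cell_M One-row invader-performance cell tibbles from the same
#'   study and stratum, under ambient and manipulated conditions respectively.
#' @return A one-row effect tibble with `stratum` set from the cells' role and
#'   `factor_type`/`n_factors` from the manipulated cell.
#' @export
compute_factor_effect_invasion <- function(cell_A, cell_M) {
  .check_cell(cell_A, "cell_A"); .check_cell(cell_M, "cell_M")
  if (cell_A$response_kind != "invader_performance" ||
      cell_M$response_kind != "invader_performance") {
    stop("pairing error: cells must measure invader performance", call. = FALSE)
  }
  if (cell_A$condition != "ambient" || cell_M$condition != "manipulated") {
    stop("pairing error: need one ambient and one manipulated cell",
         call. = FALSE)
  }
  keys <- c("study_id", "role", "richness", "metric")
  same <- vapply(keys, function(k) identical(cell_A[[k]], cell_M[[k]]),
                 logical(1))
  if (!all(same)) {
    stop("pairing error: cells differ on ",
         paste(keys[!same], collapse = ", "), call. = FALSE)
  }
  template <- cell_M
  template$condition <- NA_character_
  .effect_row(
    effect_id = paste0("fx_inv|", cell_M$cell_id),
    es_type = "factor_effect_invasion",
    value = log(cell_A$mean / cell_M$mean),
    variance = .cell_var(cell_A) + .cell_var(cell_M),
    template = template,
    source_cells = .provenance(dplyr::bind_rows(cell_A, cell_M), c(1, -1)),
    stratum = cell_M$role
  )
}

#' Environmental factor effect on resident monoculture productivity
#'
#' The log response ratio `ln(Y_mono,M / Y_mono,A)` of resident monoculture
#' productivity under manipulated versus ambient conditions — note the
#' orientation is reversed relative to the invasion-resistance factor effect.
#' Positive values classify the factor as a favorable growth condition,
#' negative values as a stressful one. The variance uses the same delta-method
#' form as the other log ratios.
#'
#' @param mono_A,mono_M One-row monoculture resident-productivity cell tibbles
#'   from the same study, under ambient and manipulated conditions.
#' @return A one-row effect tibble with `stratum = "monoculture"`.
#' @export
compute_factor_effect_productivity <- function(mono_A, mono_M) {
  .check_cell(mono_A, "mono_A"); .check_cell(mono_M, "mono_M")
  if (mono_A$role != "monoculture" || mono_M$role != "monoculture") {
    stop("pairing error: productivity factor effects use monocultures only",
         call. = FALSE)
  }
  if (mono_A$response_kind != "resident_productivity" ||
      mono_M$response_kind != "resident_productivity") {
    stop("pairing error: cells must measure resident productivity",
         call. = FALSE)
  }
  if (mono_A$condition != "ambient" || mono_M$condition != "manipulated") {
    stop("pairing error: need one ambient and one manipulated cell",
         call. = FALSE)
  }
  if (!identical(mono_A$study_id, mono_M$study_id)) {
    stop("pairing error: cells differ on study_id", call. = FALSE)
  }
  template <- mono_M
  template$condition <- NA_character_
  .effect_row(
    effect_id = paste0("fx_prod|", mono_M$cell_id),
    es_type = "factor_effect_productivity",
    value = log(mono_M$mean / mono_A$mean),
    variance = .cell_var(mono_A) + .cell_var(mono_M),
    template = template,
    source_cells = .provenance(dplyr::bind_rows(mono_M, mono_A), c(1, -1)),
    stratum = "monoculture"
  )
}

#' Build the full effect table for one analysis
#'
#' Pairs cells into effect sizes across the whole dataset. Pairing is exact on
#' `(study_id, richness, response_kind, metric, invader_type)` plus the
#' condition/role structure each effect type requires; unmatched cells are
#' reported in the `diagnostics` attribute, never silently dropped. Cells with
#' `mean == 0` are excluded from log ratios with a diagnostic.
#'
#' @param cells A validated cell tibble.
#' @param analysis One of `"nbe"` (one NBE per study x condition x mixture
#'   richness x invader type, against that study x condition's monoculture
#'   control), `"delta_nbe"` (NBE pairs matched pairwise per diversity level),
#'   `"factor_effect_invasion"` (ambient/manipulated pairs per stratum), or
#'   `"factor_effect_productivity"` (monoculture productivity pairs).
#' @return An effect tibble (possibly 0 rows), with a `diagnostics` attribute
#'   listing unmatched or excluded cells.
#' @export
build_effect_table <- function(cells,
                               analysis = c("nbe", "delta_nbe",
                                            "factor_effect_invasion",
                                            "factor_effect_productivity")) {
  analysis <- match.arg(analysis)
  diag <- list()
  note <- function(id, why) {
    diag[[length(diag) + 1L]] <<- tibble::tibble(cell_id = id, reason = why)
  }
  zero <- cells$mean <= 0
  if (any(zero)) note(cells$cell_id[zero], "mean <= 0: log ratio undefined")
  cells <- cells[!zero, , drop = FALSE]

  nbe_table <- function(kind) {
    usable <- dplyr::filter(cells, .data$response_kind == kind)
    groups <- usable |>
      dplyr::distinct(.data$study_id, .data$condition, .data$factor_type,
                      .data$metric)
    out <- list()
    for (i in seq_len(nrow(groups))) {
      g <- groups[i, ]
      grp <- dplyr::semi_join(usable, g,
        by = c("study_id", "condition", "metric")) |>
        dplyr::filter(
          (.data$condition == "ambient") |
            (is.na(g$factor_type) & is.na(.data$factor_type)) |
            (!is.na(g$factor_type) & !is.na(.data$factor_type) &
               .data$factor_type == g$factor_type))
      mono <- dplyr::filter(grp, .data$role == "monoculture")
      mixes <- dplyr::filter(grp, .data$role == "mixture")
      if (nrow(mono) == 0 && nrow(mixes) > 0) {
        note(mixes$cell_id, "mixture with no same-study monoculture control")
        next
      }
      if (nrow(mixes) == 0 && nrow(mono) > 0) {
        note(mono$cell_id, "monoculture with no mixture to compare")
        next
      }
      for (j in seq_len(nrow(mixes))) {
        mx <- mixes[j, ]
        mn <- dplyr::filter(mono, .data$invader_type == mx$invader_type)
        if (nrow(mn) == 0) mn <- mono[1, , drop = FALSE]
        out[[length(out) + 1L]] <- compute_nbe(mn[1, ], mx)
      }
    }
    if (length(out) == 0) .empty_effects() else dplyr::bind_rows(out)
  }

  result <- switch(analysis,
    nbe = nbe_table("invader_performance"),
    delta_nbe = {
      nbe <- nbe_table("invader_performance")
      amb <- dplyr::filter(nbe, .data$condition == "ambient")
      man <- dplyr::filter(nbe, .data$condition == "manipulated")
      out <- list()
      for (i in seq_len(nrow(man))) {
        m <- man[i, ]
        a <- dplyr::filter(amb, .data$study_id == m$study_id,
                           .data$richness == m$richness,
                           .data$metric == m$metric,
                           .data$invader_type == m$invader_type)
        if (nrow(a) == 0) {
          note(m$effect_id, "manipulated NBE with no ambient pair")
          next
        }
        out[[length(out) + 1L]] <- compute_delta_nbe(a[1, ], m)
      }
      if (length(out) == 0) .empty_effects() else dplyr::bind_rows(out)
    },
    factor_effect_invasion = {
      usable <- dplyr::filter(cells,
                              .data$response_kind == "invader_performance")
      man <- dplyr::filter(usable, .data$condition == "manipulated")
      amb <- dplyr::filter(usable, .data$condition == "ambient")
      out <- list()
      for (i in seq_len(nrow(man))) {
        m <- man[i, ]
        a <- dplyr::filter(amb, .data$study_id == m$study_id,
                           .data$role == m$role,
                           .data$richness == m$richness,
                           .data$metric == m$metric,
                           .data$invader_type == m$invader_type)
        if (nrow(a) == 0) {
          note(m$cell_id, "manipulated cell with no ambient counterpart")
          next
        }
        out[[length(out) + 1L]] <- compute_factor_effect_invasion(a[1, ], m)
      }
      if (length(out) == 0) .empty_effects() else dplyr::bind_rows(out)
    },
    factor_effect_productivity = {
      usable <- dplyr::filter(cells,
                              .data$response_kind == "resident_productivity",
                              .data$role == "monoculture")
      man <- dplyr::filter(usable, .data$condition == "manipulated")
      amb <- dplyr::filter(usable, .data$condition == "ambient")
      out <- list()
      for (i in seq_len(nrow(man))) {
        m <- man[i, ]
        a <- dplyr::filter(amb, .data$study_id == m$study_id,
                           .data$metric == m$metric)
        if (nrow(a) == 0) {
          note(m$cell_id, "manipulated monoculture with no ambient counterpart")
          next
        }
        out[[length(out) + 1L]] <- compute_factor_effect_productivity(a[1, ], m)
      }
      if (length(out) == 0) .empty_effects() else dplyr::bind_rows(out)
    }
  )
  attr(result, "diagnostics") <-
    if (length(diag) == 0) {
      tibble::tibble(cell_id = character(), reason = character())
    } else dplyr::bind_rows(diag)
  result
}

.empty_effects <- function() {
  tibble::tibble(
    effect_id = character(), es_type = character(), value = numeric(),
    variance = numeric(), study_id = character(), condition = character(),
    factor_type = character(), n_factors = integer(), richness = integer(),
    response_kind = character(), metric = character(),
    invader_type = character(), duration_years = numeric(),
    unit_size_m2 = numeric(), stratum = character(), source_cells = list()
  )
}

#' Sampling variance-covariance matrix of an effect table
#'
#' Effects computed against a shared cell (for instance several mixture
#' diversity levels compared with the same monoculture control) are not
#' independent: to first order,
#' `cov(i, j) = sum over shared cells c of s_ic * s_jc * sd_c^2/(n_c mean_c^2)`,
#' where `s_ic` is the sign with which cell `c` enters effect `i`. The
#' diagonal holds the effects' delta-method variances. The construction is
#' symmetric and positive semidefinite (each cell contributes a rank-one
#' outer product `v_c s_c s_c'`).
#'
#' @param effects An effect tibble with signed `source_cells` provenance.
#' @return A symmetric matrix with `dimnames` equal to `effect_id`, of class
#'   `c("effect_vcv", "matrix")`.
#' @export
build_vcv <- function(effects) {
  k <- nrow(effects)
  if (k == 0) stop("construction error: no effects", call. = FALSE)
  if (any(!is.finite(effects$variance) | effects$variance <= 0)) {
    stop("construction error: every effect needs a positive finite variance",
         call. = FALSE)
  }
  prov <- dplyr::bind_rows(
    purrr::map2(effects$source_cells, seq_len(k),
                function(sc, i) dplyr::mutate(sc, .effect = i))
  )
  prov <- dplyr::mutate(prov, v_cell = .data$sd^2 / (.data$n * .data$mean^2))
  V <- matrix(0, k, k, dimnames = list(effects$effect_id, effects$effect_id))
  for (cell in split(prov, prov$cell_id)) {
    s <- numeric(k)
    s[cell$.effect] <- cell$sign
    V <- V + cell$v_cell[1] * tcrossprod(s)
  }
  structure(V, class = c("effect_vcv", "matrix"))
}
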