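#' Read and validate a cell-level dataset
#'
#' Reads a UTF-8 CSV of community cells (one row per study x condition x role
#' summary), checks the header against [cell_schema()], converts any `se` or
#' `ci95` statistical-variation column to an SD (`sd = se * sqrt(n)`;
#' `sd = ci95 * sqrt(n) / 1.96`, treating `ci95` as the half-width of a
#' symmetric normal interval), and validates every row. Rows are never
#' silently dropped: validation problems are attached as a diagnostics tibble.
#'
#' @param path Path to the CSV file.
#' @param strict If `TRUE` (default), error when any row-level diagnostic of
#'   severity `"error"` is present; warnings are always tolerated.
#' @return A tibble of cells with a single `sd` column, a `cell_id` key column
#'   (deterministic, built from the grouping fields), an `sd_source` column
#'   recording which variation column each row supplied, and attributes
#'   `diagnostics` (the [validate_cells()] table) accessible via
#'   [cell_diagnostics()].
#' @export
read_cells <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  schema <- cell_schema()
  required <- schema$column[schema$required]
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  variation_cols <- intersect(c("sd", "se", "ci95"), names(raw))
  if (length(variation_cols) == 0) {
    stop("schema error: need one of columns sd, se, ci95", call. = FALSE)
  }
  for (col in setdiff(c("sd", "se", "ci95"), names(raw))) raw[[col]] <- NA_character_

  num <- function(x) suppressWarnings(as.numeric(x))
  int <- function(x) suppressWarnings(as.integer(x))
  cells <- tibble::tibble(
    study_id       = as.character(raw$study_id),
    condition      = as.character(raw$condition),
    factor_type    = dplyr::if_else(is.na(raw$factor_type) | raw$factor_type == "",
                                    NA_character_, as.character(raw$factor_type)),
    n_factors      = int(raw$n_factors),
    role           = as.character(raw$role),
    richness       = int(raw$richness),
    response_kind  = as.character(raw$response_kind),
    metric         = as.character(raw$metric),
    invader_type   = as.character(raw$invader_type),
    mean           = num(raw$mean),
    sd             = num(raw$sd),
    se             = num(raw$se),
    ci95           = num(raw$ci95),
    n              = int(raw$n),
    duration_years = num(raw$duration_years),
    unit_size_m2   = num(raw$unit_size_m2)
  )

  n_var <- (!is.na(cells$sd)) + (!is.na(cells$se)) + (!is.na(cells$ci95))
  if (any(n_var != 1L)) {
    stop("validation error: rows ",
         paste(utils::head(which(n_var != 1L), 10), collapse = ", "),
         " must supply exactly one of sd, se, ci95", call. = FALSE)
  }
  cells <- cells |>
    dplyr::mutate(
      sd_source = dplyr::case_when(
        !is.na(.data$sd)   ~ "sd",
        !is.na(.data$se)   ~ "se",
        TRUE               ~ "ci95"
      ),
      sd = dplyr::case_when(
        !is.na(.data$sd)   ~ .data$sd,
        !is.na(.data$se)   ~ .data$se * sqrt(.data$n),
        TRUE               ~ .data$ci95 * sqrt(.data$n) / 1.96
      )
    ) |>
    dplyr::select(-"se", -"ci95") |>
    dplyr::mutate(
      cell_id = paste(.data$study_id, .data$condition,
                      dplyr::coalesce(.data$factor_type, "none"),
                      .data$role, .data$richness, .data$response_kind,
                      .data$metric, .data$invader_type, sep = ":"),
      .before = 1
    )
  if (anyDuplicated(cells$cell_id)) {
    dup <- cells$cell_id[duplicated(cells$cell_id)]
    stop("validation error: duplicate cells for key(s): ",
         paste(utils::head(unique(dup), 5), collapse = "; "), call. = FALSE)
  }

  diagnostics <- validate_cells(cells)
  if (strict && any(diagnostics$severity == "error")) {
    bad <- dplyr::filter(diagnostics, .data$severity == "error")
    stop("validation error in ", nrow(bad), " row(s); first: row ",
         bad$row[1], " [", bad$check[1], "] ", bad$message[1], call. = FALSE)
  }
  attr(cells, "diagnostics") <- diagnostics
  cells
}

#' Diagnostics attached to a cell dataset
#'
#' @param cells A tibble returned by [read_cells()].
#' @return The diagnostics tibble (possibly empty).
#' @export
cell_diagnostics <- function(cells) {
  d <- attr(cells, "diagnostics")
  if (is.null(d)) {
    d <- tibble::tibble(row = integer(), severity = character(),
                        check = character(), message = character())
  }
  d
}

#' Write a result table to CSV
#'
#' Writes any homogeneous result tibble (cells, effect sizes, marginal means,
#' influence records, ...) to a CSV with stable column order; list-columns
#' (such as effect provenance) are serialised as compact JSON so the file
#' round-trips. Numeric columns are written at full precision.
#'
#' @param records A tibble (all rows of one result type).
#' @param path Output path.
#' @return `invisible(path)`.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) {
    stop("records must be a single data frame of one result type", call. = FALSE)
  }
  out <- records
  is_list <- vapply(out, is.list, logical(1))
  for (col in names(out)[is_list]) {
    out[[col]] <- vapply(
      out[[col]],
      function(x) as.character(jsonlite::toJSON(x, digits = NA)),
      character(1)
    )
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records what a pipeline run saw and produced: configuration, seed, row
#' counts and diagnostics summary, as a small JSON file.
#'
#' @param manifest A named list.
#' @param path Output path.
#' @return `invisible(path)`.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
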