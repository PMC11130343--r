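#' Column dictionary for the cell-level dataset
#'
#' The unit of data entry is a *community cell*: one summary (mean, SD, n) of
#' invader performance or resident productivity for a study x environmental
#' condition x diversity role combination. `cell_schema()` returns the
#' machine-readable column dictionary used by [read_cells()] to validate an
#' input CSV: required columns, enum domains, and unit annotations.
#'
#' Statistical variation may be supplied as any one of `sd`, `se`, or `ci95`
#' (the full width is not accepted; `ci95` is the half-width of a symmetric
#' 95% interval). Exactly one of the three must be non-missing per row;
#' [read_cells()] converts everything to an SD.
#'
#' @return A tibble with one row per column: `column`, `type`, `required`,
#'   `domain` (allowed values, or `NA` for free/numeric columns), `units`.
#' @export
#' @examples
#' cell_schema()
cell_schema <- function() {
  tibble::tribble(
    ~column,          ~type,       ~required, ~domain,                     ~units,
    "study_id",       "character", TRUE,      NA_character_,               "label",
    "condition",      "character", TRUE,      paste(.conditions, collapse = "|"), "enum",
    "factor_type",    "character", FALSE,     paste(.factor_types, collapse = "|"), "enum (blank when ambient)",
    "n_factors",      "integer",   TRUE,      "0|1|2|3",                   "count",
    "role",           "character", TRUE,      paste(.roles, collapse = "|"), "enum",
    "richness",       "integer",   TRUE,      NA_character_,               "species (>= 1)",
    "response_kind",  "character", TRUE,      paste(.response_kinds, collapse = "|"), "enum",
    "metric",         "character", TRUE,      paste(.metrics, collapse = "|"), "enum",
    "invader_type",   "character", TRUE,      paste(.invader_types, collapse = "|"), "enum",
    "mean",           "numeric",   TRUE,      NA_character_,               "metric units (>= 0)",
    "sd",             "numeric",   FALSE,     NA_character_,               "metric units",
    "se",             "numeric",   FALSE,     NA_character_,               "metric units",
    "ci95",           "numeric",   FALSE,     NA_character_,               "metric units (CI half-width)",
    "n",              "integer",   TRUE,      NA_character_,               "replicates (>= 1)",
    "duration_years", "numeric",   TRUE,      NA_character_,               "years [0.25, 24]",
    "unit_size_m2",   "numeric",   TRUE,      NA_character_,               "m^2 [0.01, 47.5]"
  )
}

.conditions     <- c("ambient", "manipulated")
.factor_types   <- c("warming", "drought", "elevated_CO2", "eutrophication",
                     "pesticide", "grazing", "fire", "physical_disturbance",
                     "combination")
.roles          <- c("monoculture", "mixture")
.response_kinds <- c("invader_performance", "resident_productivity")
.metrics        <- c("biomass", "cover")
.invader_types  <- c("all", "internal", "external_native", "external_alien",
                     "unspecified")

#' Validate a tibble of community cells
#'
#' Checks every row against the cell invariants and returns a located, typed
#' diagnostic for each violation; no rows are dropped silently. Checked
#' invariants:
#' * monocultures have `richness == 1`, mixtures `richness >= 2`;
#' * ambient rows have `n_factors == 0` and no `factor_type`; manipulated
#'   rows have `n_factors` in 1..3 and a `factor_type`;
#' * `mean >= 0`, `sd >= 0`, `n >= 1`;
#' * `sd == 0` is flagged (a log-ratio variance would be degenerate);
#' * `mean == 0` is flagged (a log ratio would be undefined);
#' * enum columns take only known values;
#' * `duration_years` and `unit_size_m2` inside their plausible ranges.
#'
#' @param cells A tibble with the columns of [cell_schema()] (post-conversion,
#'   i.e. with a single `sd` column).
#' @return A tibble of diagnostics with columns `row`, `severity`
#'   (`"error"` or `"warning"`), `check`, and `message`. Zero rows when the
#'   dataset is clean.
#' @export
validate_cells <- function(cells) {
  stopifnot(is.data.frame(cells))
  diag <- list()
  note <- function(rows, severity, check, message) {
    if (length(rows) == 0) return()
    diag[[length(diag) + 1L]] <<- tibble::tibble(
      row = as.integer(rows), severity = severity, check = check,
      message = message
    )
  }

  bad_enum <- function(col, domain) {
    which(!is.na(cells[[col]]) & !(cells[[col]] %in% domain))
  }
  note(bad_enum("condition", .conditions), "error", "enum",
       "unknown condition value")
  note(bad_enum("factor_type", .factor_types), "error", "enum",
       "unknown factor_type value")
  note(bad_enum("role", .roles), "error", "enum", "unknown role value")
  note(bad_enum("response_kind", .response_kinds), "error", "enum",
       "unknown response_kind value")
  note(bad_enum("metric", .metrics), "error", "enum", "unknown metric value")
  note(bad_enum("invader_type", .invader_types), "error", "enum",
       "unknown invader_type value")

  note(which(cells$role == "monoculture" & cells$richness != 1L),
       "error", "richness_role", "monoculture rows must have richness = 1")
  note(which(cells$role == "mixture" & cells$richness < 2L),
       "error", "richness_role", "mixture rows must have richness >= 2")
  note(which(cells$condition == "ambient" & cells$n_factors != 0L),
       "error", "condition_factors", "ambient rows must have n_factors = 0")
  note(which(cells$condition == "manipulated" &
               !(cells$n_factors %in% 1:3)),
       "error", "condition_factors",
       "manipulated rows must have n_factors in 1..3")
  note(which(cells$condition == "manipulated" & is.na(cells$factor_type)),
       "error", "condition_factors",
       "manipulated rows must name a factor_type")
  note(which(cells$mean < 0), "error", "nonnegative", "negative mean")
  note(which(cells$sd < 0), "error", "nonnegative", "negative sd")
  note(which(cells$n < 1L), "error", "sample_size", "n must be >= 1")
  note(which(cells$mean == 0), "warning", "zero_mean",
       "mean = 0: row excluded from log-ratio effect sizes")
  note(which(cells$sd == 0), "warning", "zero_sd",
       "sd = 0: delta-method variance degenerate for this cell")
  note(which(cells$duration_years < 0.25 | cells$duration_years > 24),
       "warning", "range", "duration_years outside [0.25, 24]")
  note(which(cells$unit_size_m2 < 0.01 | cells$unit_size_m2 > 47.5),
       "warning", "range", "unit_size_m2 outside [0.01, 47.5]")

  if (length(diag) == 0) {
    return(tibble::tibble(row = integer(), severity = character(),
                          check = character(), message = character()))
  }
  dplyr::arrange(dplyr::bind_rows(diag), .data$row)
}
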