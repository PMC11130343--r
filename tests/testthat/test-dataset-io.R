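write_fixture_csv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(rows, path, progress = FALSE)
  path
}

base_row <- function(...) {
  row <- tibble::tibble(
    study_id = "S1", condition = "ambient", factor_type = NA_character_,
    n_factors = 0L, role = "monoculture", richness = 1L,
    response_kind = "invader_performance", metric = "biomass",
    invader_type = "all", mean = 10, sd = 2, n = 5L,
    duration_years = 2, unit_size_m2 = 1
  )
  dplyr::mutate(row, ...)
}

test_that("a well-formed CSV round-trips with no diagnostics", {
  rows <- dplyr::bind_rows(
    base_row(),
    base_row(role = "mixture", richness = 4L),
    base_row(condition = "manipulated", factor_type = "warming",
             n_factors = 1L)
  )
  cells <- read_cells(write_fixture_csv(rows))
  expect_equal(nrow(cells), 3)
  expect_equal(nrow(cell_diagnostics(cells)), 0)
  expect_equal(cells$mean, rows$mean)
  expect_equal(cells$sd, rows$sd)
})

test_that("se and ci95 inputs are converted to sd and recorded", {
  rows <- dplyr::bind_rows(
    dplyr::select(base_row(), -"sd") |> dplyr::mutate(se = 1.0, n = 4L),
    dplyr::select(base_row(role = "mixture", richness = 2L), -"sd") |>
      dplyr::mutate(ci95 = 1.96, n = 4L)
  )
  cells <- read_cells(write_fixture_csv(rows))
  expect_equal(cells$sd[1], 2.0)          # se * sqrt(n)
  expect_equal(cells$sd[2], 2.0)          # ci95 half-width * sqrt(n) / 1.96
  expect_equal(cells$sd_source, c("se", "ci95"))
})

test_that("rows supplying zero or several variation columns are rejected", {
  rows <- base_row() |> dplyr::mutate(se = 0.5)
  expect_error(read_cells(write_fixture_csv(rows)), "exactly one")
})

test_that("schema and row-level validation errors are located and typed", {
  expect_error(
    read_cells(write_fixture_csv(dplyr::select(base_row(), -"richness"))),
    "missing required column.*richness")
  expect_error(
    read_cells(write_fixture_csv(base_row(role = "mixture", richness = 1L))),
    "validation error")
  expect_error(
    read_cells(write_fixture_csv(base_row(mean = -3))), "validation error")
  expect_error(
    read_cells(write_fixture_csv(base_row(condition = "strange"))),
    "validation error")
  expect_error(read_cells("no/such/file.csv"), "not found")
})

test_that("zero means are retained at ingest but flagged for log ratios", {
  rows <- dplyr::bind_rows(base_row(mean = 0),
                           base_row(role = "mixture", richness = 4L))
  cells <- read_cells(write_fixture_csv(rows))
  expect_equal(nrow(cells), 2)
  d <- cell_diagnostics(cells)
  expect_true(any(d$check == "zero_mean" & d$severity == "warning"))
  eff <- build_effect_table(cells, "nbe")
  expect_equal(nrow(eff), 0)
  expect_gt(nrow(attr(eff, "diagnostics")), 0)
})

test_that("write_table round-trips result tables, including provenance", {
  cells <- dplyr::bind_rows(base_row(),
                            base_row(role = "mixture", richness = 4L),
                            base_row(role = "mixture", richness = 8L)) |>
    dplyr::mutate(cell_id = paste0("c", dplyr::row_number()), .before = 1)
  eff <- build_effect_table(cells, "nbe")
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(eff, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 2)
  expect_equal(back$value, eff$value)
  expect_equal(back$variance, eff$variance, tolerance = 1e-15)

  empty <- eff[0, ]
  write_table(empty, path)
  expect_equal(nrow(readr::read_csv(path, show_col_types = FALSE)), 0)

  expect_error(write_table(list(eff, cells), path), "single data frame")
})
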