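# CSV I/O for the three input tables. All files are RFC-4180 CSV, UTF-8,
# "." decimal separator, with the canonical column order documented in the
# constructors; write(read(x)) is byte-identical for canonical files.

#' @keywords internal
read_checked_csv <- function(path, col_types, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  tbl <- readr::read_csv(path, col_types = col_types,
                         progress = FALSE, show_col_types = FALSE)
  problems <- readr::problems(tbl)
  if (nrow(problems) > 0) {
    stopf("%s parse error at row %d: %s", what,
          problems$row[1], problems$expected[1])
  }
  tbl
}

#' Read and write resource-use tables
#'
#' @param path Path to a CSV file with columns `item_id, name, category,
#'   stream, applicability, qty_moderate, qty_severe, qty_critical, unit`.
#' @return `read_resource_table()` returns a validated tibble;
#'   `write_resource_table()` returns `path` invisibly.
#' @seealso [resource_table()] for the schema and semantics.
#' @export
read_resource_table <- function(path) {
  tbl <- read_checked_csv(
    path,
    readr::cols(item_id = "c", name = "c", category = "c", stream = "c",
                applicability = "c", qty_moderate = "d", qty_severe = "d",
                qty_critical = "d", unit = "c"),
    "resource table")
  validate_resource_table(tbl)
}

#' @rdname read_resource_table
#' @param resources A resource table.
#' @export
write_resource_table <- function(resources, path) {
  readr::write_csv(validate_resource_table(resources), path, progress = FALSE)
  invisible(path)
}

#' Read and write price books
#'
#' @param path Path to a CSV file with columns `item_id, price, currency,
#'   cost_type, useful_life_years, needs_uplift, source`.
#' @return `read_pricebook()` returns a validated tibble; duplicate
#'   `item_id`s and capital rows without a useful life are rejected.
#' @seealso [pricebook()]
#' @export
read_pricebook <- function(path) {
  tbl <- read_checked_csv(
    path,
    readr::cols(item_id = "c", price = "d", currency = "c", cost_type = "c",
                useful_life_years = "d", needs_uplift = "l", source = "c"),
    "pricebook")
  tbl$source[is.na(tbl$source)] <- ""
  validate_pricebook(tbl)
}

#' @rdname read_pricebook
#' @param prices A price book.
#' @export
write_pricebook <- function(prices, path) {
  readr::write_csv(validate_pricebook(prices), path, progress = FALSE)
  invisible(path)
}

#' Read and write salary schedules
#'
#' @param path Path to a CSV file with columns `country, cadre, grade, band,
#'   annual_salary, currency`.
#' @return `read_salary_schedule()` returns a validated tibble.
#' @seealso [salary_schedule()]
#' @export
read_salary_schedule <- function(path) {
  tbl <- read_checked_csv(
    path,
    readr::cols(country = "c", cadre = "c", grade = "c", band = "c",
                annual_salary = "d", currency = "c"),
    "salary schedule")
  validate_salary_schedule(tbl)
}

#' @rdname read_salary_schedule
#' @param salaries A salary schedule.
#' @export
write_salary_schedule <- function(salaries, path) {
  readr::write_csv(validate_salary_schedule(salaries), path, progress = FALSE)
  invisible(path)
}
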