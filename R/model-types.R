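#' Severity levels of the tracer condition
#'
#' Patients are stratified into three WHO-defined severity categories of the
#' COVID-19 tracer condition. Moderate patients are not critically ill: at
#' the essential care level they consume resources only in the
#' identification stream (vital-signs monitoring), and they are excluded
#' from advanced-care costing. Severe and critical patients consume
#' identification plus treatment resources. The ordering
#' moderate < severe < critical is total.
#'
#' @return Character vector of the three severity levels, in order.
#' @export
severity_levels <- function() c("moderate", "severe", "critical")

#' Care levels
#'
#' `"EECC"` is Essential Emergency and Critical Care, the low-cost first-tier
#' package. `"ACC"` is Advanced Critical Care, defined as EECC plus the
#' resource-intensive organ support typical of an ICU; its resource set is a
#' superset of the EECC set.
#'
#' @return Character vector `c("EECC", "ACC")`.
#' @export
care_levels <- function() c("EECC", "ACC")

#' Care activity streams
#'
#' Essential care comprises two streams: identification of the critically
#' ill (vital-signs monitoring) and essential treatment (organ support).
#' Treatment-stream resources are never consumed by moderate patients.
#'
#' @return Character vector `c("identification", "treatment")`.
#' @export
care_streams <- function() c("identification", "treatment")

#' Cost categories
#'
#' The eight cost categories used throughout the package, matching the row
#' labels of the published per-patient-day breakdown tables:
#' \describe{
#'   \item{hotel}{Hotel costs (accommodation and overheads).}
#'   \item{staffing}{Staff time, valued from public-sector salaries.}
#'   \item{oxygen}{Oxygen provision.}
#'   \item{pharmaceuticals}{Medicines.}
#'   \item{nonpharma_capital}{Non-pharmaceutical capital items (equipment).}
#'   \item{nonpharma_recurrent}{Non-pharmaceutical recurrent items (fluids,
#'     devices).}
#'   \item{ppe}{Personal protective equipment.}
#'   \item{diagnostics}{Support services; consumed only at the ACC level.}
#' }
#'
#' @return Character vector of the eight category codes, in table row order.
#' @export
cost_categories <- function() {
  c("hotel", "staffing", "oxygen", "pharmaceuticals",
    "nonpharma_capital", "nonpharma_recurrent", "ppe", "diagnostics")
}

#' Human-readable category labels mirroring the published table rows
#' @return Named character vector keyed by category code.
#' @export
cost_category_labels <- function() {
  c(hotel = "Hotel costs (accommodation + overheads)",
    staffing = "Staffing costs",
    oxygen = "Oxygen provision",
    pharmaceuticals = "Pharmaceuticals (Medicines etc.)",
    nonpharma_capital = "Non-pharmaceutical costs (capital)",
    nonpharma_recurrent = "Non-pharmaceutical costs (fluids, devices etc.)",
    ppe = "Personal protective equipment (PPE)",
    diagnostics = "Support services (diagnostics)")
}

#' Supported currencies and countries
#' @return Character vectors of ISO-style codes.
#' @export
#' @rdname codes
currencies <- function() c("TZS", "KES", "USD")

#' @export
#' @rdname codes
countries <- function() c("TZ", "KE")

#' @keywords internal
cost_types <- function() c("capital", "recurrent", "staff_time")

#' @keywords internal
applicability_levels <- function() c("EECC", "ACC", "both")

#' @keywords internal
match_enum <- function(value, allowed, what) {
  bad <- setdiff(unique(value), allowed)
  if (length(bad) > 0) {
    stopf("invalid %s: %s (allowed: %s)", what,
          paste(bad, collapse = ", "), paste(allowed, collapse = ", "))
  }
  value
}

#' Assemble a resource-use table
#'
#' One row per costed ingredient: an item consumed per patient-day, with a
#' severity-specific daily quantity in natural units (minutes for staff
#' time, litres per day for oxygen, counts for consumables, device-fractions
#' for shared equipment) and a care-level applicability tag. A line tagged
#' `"both"` is required at both care levels and is listed once; `"ACC"`
#' lines never contribute to EECC totals; `"EECC"` lines contribute to both
#' levels because ACC is a superset of EECC.
#'
#' @param item_id Character identifiers, unique within the table.
#' @param name Item names (free text).
#' @param category Cost category codes, see [cost_categories()].
#' @param stream `"identification"` or `"treatment"`.
#' @param applicability `"EECC"`, `"ACC"` or `"both"`.
#' @param qty_moderate,qty_severe,qty_critical Non-negative daily quantities.
#' @param unit Natural unit label (free text).
#' @return A validated tibble with the canonical column order.
#' @export
resource_table <- function(item_id, name, category, stream, applicability,
                           qty_moderate, qty_severe, qty_critical,
                           unit = "unit") {
  tbl <- tibble::tibble(
    item_id = as.character(item_id), name = as.character(name),
    category = as.character(category), stream = as.character(stream),
    applicability = as.character(applicability),
    qty_moderate = as.numeric(qty_moderate),
    qty_severe = as.numeric(qty_severe),
    qty_critical = as.numeric(qty_critical),
    unit = as.character(unit)
  )
  validate_resource_table(tbl)
}

#' @keywords internal
validate_resource_table <- function(tbl) {
  required <- c("item_id", "name", "category", "stream", "applicability",
                "qty_moderate", "qty_severe", "qty_critical", "unit")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stopf("resource table schema error: missing column(s) %s",
          paste(missing, collapse = ", "))
  }
  match_enum(tbl$category, cost_categories(), "cost category")
  match_enum(tbl$stream, care_streams(), "care stream")
  match_enum(tbl$applicability, applicability_levels(), "applicability")
  for (col in c("qty_moderate", "qty_severe", "qty_critical")) {
    q <- tbl[[col]]
    if (anyNA(q)) {
      stopf("resource table validation error: %s is NA at row %d",
            col, which(is.na(q))[1])
    }
    if (any(q < 0)) {
      stopf("resource table validation error: negative %s at row %d",
            col, which(q < 0)[1])
    }
  }
  if (anyDuplicated(tbl$item_id)) {
    stopf("resource table validation error: duplicated item_id '%s'",
          tbl$item_id[duplicated(tbl$item_id)][1])
  }
  tbl[required]
}

#' Assemble a price book
#'
#' One row per item: a unit price in a source currency, its cost type, and
#' the flags the valuation rules need. Capital rows must (and only capital
#' rows may) carry a useful life; `needs_uplift` marks goods whose quoted
#' price excludes shipping, so a transport/insurance percentage uplift is
#' added during valuation. Staff-time rows carry the annual salary as the
#' price; the line quantity is then minutes per patient-day.
#'
#' @param item_id Character identifiers, unique.
#' @param price Non-negative unit prices in `currency`.
#' @param currency `"TZS"`, `"KES"` or `"USD"`.
#' @param cost_type `"capital"`, `"recurrent"` or `"staff_time"`.
#' @param useful_life_years Positive, for capital rows only (else `NA`).
#' @param needs_uplift Logical.
#' @param source Free-text provenance of the price.
#' @return A validated tibble.
#' @export
pricebook <- function(item_id, price, currency, cost_type,
                      useful_life_years = NA_real_, needs_uplift = FALSE,
                      source = "") {
  tbl <- tibble::tibble(
    item_id = as.character(item_id), price = as.numeric(price),
    currency = as.character(currency), cost_type = as.character(cost_type),
    useful_life_years = as.numeric(useful_life_years),
    needs_uplift = as.logical(needs_uplift), source = as.character(source)
  )
  validate_pricebook(tbl)
}

#' @keywords internal
validate_pricebook <- function(tbl) {
  required <- c("item_id", "price", "currency", "cost_type",
                "useful_life_years", "needs_uplift", "source")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stopf("pricebook schema error: missing column(s) %s",
          paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tbl$item_id)) {
    stopf("pricebook validation error: duplicated item_id '%s'",
          tbl$item_id[duplicated(tbl$item_id)][1])
  }
  match_enum(tbl$currency, currencies(), "currency")
  match_enum(tbl$cost_type, cost_types(), "cost type")
  if (anyNA(tbl$price) || any(tbl$price < 0)) {
    stopf("pricebook validation error: prices must be non-negative")
  }
  capital <- tbl$cost_type == "capital"
  bad <- capital & (is.na(tbl$useful_life_years) | tbl$useful_life_years <= 0)
  if (any(bad)) {
    stopf("pricebook validation error: capital item '%s' lacks a positive useful_life_years",
          tbl$item_id[bad][1])
  }
  bad <- !capital & !is.na(tbl$useful_life_years)
  if (any(bad)) {
    stopf("pricebook validation error: non-capital item '%s' carries useful_life_years",
          tbl$item_id[bad][1])
  }
  tbl[required]
}

#' Assemble a staff salary schedule
#'
#' Public-sector annual salaries per cadre and grade used to value staff
#' time and to build the low/high staffing scenarios. `band` marks which
#' staffing scenario a cadre belongs to: `"low"` is the lowest-cost cadre
#' that could carry out the tasks, `"reference"` the cadre mix of the
#' reference scenario, `"high"` the highest nurse grade plus
#' consultant-level doctor.
#'
#' @param country `"TZ"` or `"KE"`.
#' @param cadre,grade Free text.
#' @param band `"low"`, `"reference"` or `"high"`.
#' @param annual_salary Positive annual salary in `currency`.
#' @param currency `"TZS"`, `"KES"` or `"USD"`.
#' @return A validated tibble.
#' @export
salary_schedule <- function(country, cadre, grade, band, annual_salary,
                            currency) {
  tbl <- tibble::tibble(
    country = as.character(country), cadre = as.character(cadre),
    grade = as.character(grade), band = as.character(band),
    annual_salary = as.numeric(annual_salary),
    currency = as.character(currency)
  )
  validate_salary_schedule(tbl)
}

#' @keywords internal
validate_salary_schedule <- function(tbl) {
  required <- c("country", "cadre", "grade", "band", "annual_salary",
                "currency")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stopf("salary schedule schema error: missing column(s) %s",
          paste(missing, collapse = ", "))
  }
  match_enum(tbl$country, countries(), "country")
  match_enum(tbl$band, c("low", "reference", "high"), "salary band")
  match_enum(tbl$currency, currencies(), "currency")
  if (anyNA(tbl$annual_salary) || any(tbl$annual_salary <= 0)) {
    stopf("salary schedule validation error: annual_salary must be positive")
  }
  tbl[required]
}

#' Cross-check a resource table against a price book
#'
#' Report-only consistency check: lists (a) resource lines with no price,
#' (b) priced items never used by a line, and (c) treatment-stream lines
#' with a nonzero moderate quantity — moderate patients are not critically
#' ill, so they consume identification-stream resources only.
#'
#' @param resources A resource table, see [resource_table()].
#' @param prices A price book, see [pricebook()].
#' @return An object of class `eecc_validation`: a list with character
#'   vectors `missing_price`, `unused_price`, `moderate_treatment`.
#' @export
validate_model <- function(resources, prices) {
  resources <- validate_resource_table(resources)
  prices <- validate_pricebook(prices)
  report <- list(
    missing_price = setdiff(resources$item_id, prices$item_id),
    unused_price = setdiff(prices$item_id, resources$item_id),
    moderate_treatment = resources$item_id[
      resources$stream == "treatment" & resources$qty_moderate > 0]
  )
  structure(report, class = "eecc_validation")
}

#' @export
print.eecc_validation <- function(x, ...) {
  if (is_clean(x)) {
    cat("model validation: clean\n")
  } else {
    for (nm in names(x)) {
      if (length(x[[nm]]) > 0) {
        cat(sprintf("%s: %s\n", nm, paste(x[[nm]], collapse = ", ")))
      }
    }
  }
  invisible(x)
}

#' @rdname validate_model
#' @param report An `eecc_validation` object.
#' @export
is_clean <- function(report) all(lengths(report) == 0)
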