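# Synthetic item-level models. The study's item-level resource lists and
# price books are not machine-readable, but its category-level daily costs
# are; the generator fabricates an item-level model (lognormal price noise,
# country-specific salary anchors) whose quantities are calibrated so the
# valued category costs reproduce a target cost structure - by default the
# category-level reference table for the chosen country. This gives
# item-level inputs that exercise the full valuation path while remaining
# faithful to the study conditions.

#' Generator configuration
#'
#' @param seed Integer seed; identical configurations generate identical
#'   models.
#' @param country `"TZ"` or `"KE"` country profile. Kenyan staff salary
#'   anchors sit well above the Tanzanian ones (staff time is more
#'   expensive in Kenya).
#' @param n_items_per_category Positive integer: how many synthetic items
#'   to fabricate per multi-item category.
#' @param price_dispersion Lognormal sigma of unit-price noise around the
#'   category anchors (strictly positive, right-skewed prices).
#' @param salary_grade_spread Half-width of the uniform log-spread applied
#'   to salary anchors; must stay below `log(2.2)` so the Kenyan premium
#'   over Tanzanian anchors is preserved for every cadre.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, country = "TZ",
                             n_items_per_category = 2L,
                             price_dispersion = 0.3,
                             salary_grade_spread = 0.2) {
  match_enum(country, countries(), "country")
  if (n_items_per_category < 1) stopf("n_items_per_category must be >= 1")
  if (price_dispersion <= 0) stopf("price_dispersion must be positive")
  if (salary_grade_spread <= 0 || salary_grade_spread >= log(2.2)) {
    stopf("salary_grade_spread must lie in (0, log(2.2))")
  }
  structure(list(seed = as.integer(seed), country = country,
                 n_items_per_category = as.integer(n_items_per_category),
                 price_dispersion = price_dispersion,
                 salary_grade_spread = salary_grade_spread),
            class = "generator_config")
}

#' @keywords internal
generator_salary_anchors_usd <- function() {
  tibble::tibble(
    cadre = c("nursing assistant", "nurse officer", "medical officer",
              "senior nurse officer", "consultant physician"),
    grade = c("auxiliary", "grade II", "grade I", "principal", "consultant"),
    band = c("low", "reference", "reference", "high", "high"),
    anchor_usd = c(1200, 3600, 9600, 7200, 24000)
  )
}

#' Generate a synthetic item-level costing model
#'
#' Fabricates a resource table, price book, salary schedule and oxygen
#' scenarios for one country profile. Item unit prices carry lognormal
#' noise; per-severity quantities are then calibrated against the target
#' category cost structure using the package's own valuation rules, so the
#' costed model reproduces the targets while the item-level decomposition
#' varies with the seed. The generated model always satisfies the
#' structural rules: moderate patients consume identification-stream
#' resources only (no oxygen, pharmaceuticals or fluids), diagnostics occur
#' only at the advanced care level, and the advanced resource set is a
#' superset of the essential one.
#'
#' @param cfg A [generator_config()].
#' @param ctx A [costing_context()] used for the calibration arithmetic.
#' @return An object of class `eecc_model`: a list with `resources`,
#'   `prices`, `salaries`, `oxygen_scenarios`, `country`, and the
#'   bookkeeping `targets` tibble of intended category daily costs.
#' @export
generate_model <- function(cfg = generator_config(),
                           ctx = costing_context()) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, generate_model_impl(cfg, ctx))
}

#' @keywords internal
generate_model_impl <- function(cfg, ctx) {
  country <- cfg$country
  fx <- if (country == "TZ") ctx$fx_rate_tzs_per_usd else ctx$fx_rate_kes_per_usd
  local_ccy <- if (country == "TZ") "TZS" else "KES"
  premium <- if (country == "TZ") 1 else 2.2

  anchors <- generator_salary_anchors_usd()
  spread <- cfg$salary_grade_spread
  anchors$salary_usd <- anchors$anchor_usd * premium *
    exp(stats::runif(nrow(anchors), -spread, spread))
  salaries <- salary_schedule(
    country = country, cadre = anchors$cadre, grade = anchors$grade,
    band = anchors$band, annual_salary = anchors$salary_usd * fx,
    currency = local_ccy)

  scenarios <- default_oxygen_scenarios()
  p_district <- cost_per_litre(scenarios$district_concentrator, ctx)
  p_icu <- cost_per_litre(scenarios$icu_high_flow, ctx)

  ref <- reference_costs()
  target_of <- function(level, category) {
    vapply(severity_levels(), function(sv) {
      row <- ref[ref$country == country & ref$care_level == level &
                   ref$severity == sv & ref$category == category, ]
      if (nrow(row) == 0) 0 else row$usd_per_day
    }, numeric(1))
  }
  eecc_t <- function(cat) target_of("EECC", cat)
  extra_t <- function(cat) pmax(target_of("ACC", cat) - target_of("EECC", cat), 0)

  rows_res <- list()
  rows_prc <- list()
  add_items <- function(prefix, name, category, stream, applicability,
                        cost_type, targets, n = cfg$n_items_per_category,
                        anchor_usd = 1, needs_uplift = TRUE,
                        life = NA_real_, unit = "unit",
                        usd_price_fixed = NULL, salary_row = NULL) {
    if (all(targets == 0) && cost_type != "staff_time") n <- 1L
    w <- stats::runif(n)
    w <- w / sum(w)
    for (i in seq_len(n)) {
      id <- sprintf("%s_%02d", prefix, i)
      if (!is.null(salary_row)) {
        price <- salaries$annual_salary[salary_row]
        ccy <- salaries$currency[salary_row]
        rate_usd <- convert_to_usd(price, ccy, ctx) /
          ctx$working_minutes_per_year
        f <- rate_usd
      } else if (!is.null(usd_price_fixed)) {
        price <- usd_price_fixed
        ccy <- "USD"
        f <- price
        needs_uplift <- FALSE
      } else {
        usd <- anchor_usd * stats::rlnorm(1, 0, cfg$price_dispersion)
        price <- usd * fx
        ccy <- local_ccy
        unit_usd <- apply_uplift(convert_to_usd(price, ccy, ctx), ctx,
                                 needs_uplift)
        f <- if (cost_type == "capital") {
          annualize_capital(unit_usd, life, ctx$discount_rate) / 365
        } else unit_usd
      }
      qty <- w[i] * targets / f
      rows_res[[length(rows_res) + 1]] <<- tibble::tibble(
        item_id = id, name = sprintf("%s %d", name, i), category = category,
        stream = stream, applicability = applicability,
        qty_moderate = qty[["moderate"]], qty_severe = qty[["severe"]],
        qty_critical = qty[["critical"]], unit = unit)
      rows_prc[[length(rows_prc) + 1]] <<- tibble::tibble(
        item_id = id, price = price, currency = ccy, cost_type = cost_type,
        useful_life_years = if (cost_type == "capital") life else NA_real_,
        needs_uplift = needs_uplift && cost_type != "staff_time" &&
          is.null(usd_price_fixed),
        source = "synthetic")
    }
  }

  nurse_row <- which(salaries$cadre == "nurse officer")
  doctor_row <- which(salaries$cadre == "medical officer")

  # --- shared (EECC + ACC) lines -------------------------------------------
  add_items("hotel", "ward overhead charge", "hotel", "identification",
            "both", "recurrent", eecc_t("hotel"), n = 1L, anchor_usd = 20,
            needs_uplift = FALSE, unit = "bed-day fraction")
  staff_id <- eecc_t("staffing")
  # monitoring minutes are constant across severities at the moderate level
  # of effort; the treatment stream carries the severity gradient
  id_part <- c(moderate = staff_id[["moderate"]],
               severe = staff_id[["moderate"]],
               critical = staff_id[["moderate"]])
  add_items("staff_monitor", "vital signs monitoring", "staffing",
            "identification", "both", "staff_time", id_part, n = 1L,
            salary_row = nurse_row, unit = "minutes")
  treat_part <- pmax(staff_id - id_part, 0)
  treat_part[["moderate"]] <- 0
  add_items("staff_treat_n", "nursing treatment time", "staffing",
            "treatment", "both", "staff_time", treat_part * 0.7, n = 1L,
            salary_row = nurse_row, unit = "minutes")
  add_items("staff_treat_d", "doctor treatment time", "staffing",
            "treatment", "both", "staff_time", treat_part * 0.3, n = 1L,
            salary_row = doctor_row, unit = "minutes")
  add_items("oxygen", "oxygen therapy", "oxygen", "treatment", "both",
            "recurrent", eecc_t("oxygen"), n = 1L,
            usd_price_fixed = p_district, unit = "litres")
  add_items("pharma", "essential medicine", "pharmaceuticals", "treatment",
            "both", "recurrent", eecc_t("pharmaceuticals"), anchor_usd = 2,
            unit = "dose")
  add_items("capital", "monitoring equipment", "nonpharma_capital",
            "identification", "both", "capital", eecc_t("nonpharma_capital"),
            anchor_usd = 800, life = 5, unit = "device fraction")
  add_items("fluids", "fluids and giving sets", "nonpharma_recurrent",
            "treatment", "both", "recurrent", eecc_t("nonpharma_recurrent"),
            anchor_usd = 1.5, unit = "item")
  add_items("ppe", "protective equipment", "ppe", "identification", "both",
            "recurrent", eecc_t("ppe"), anchor_usd = 0.5, unit = "item")

  # --- ACC-only lines -------------------------------------------------------
  add_items("acc_hotel", "ICU overhead charge", "hotel", "identification",
            "ACC", "recurrent", extra_t("hotel"), n = 1L, anchor_usd = 40,
            needs_uplift = FALSE, unit = "bed-day fraction")
  acc_staff <- extra_t("staffing")
  add_items("acc_staff_n", "ICU nursing time", "staffing", "treatment",
            "ACC", "staff_time", acc_staff * 0.6, n = 1L,
            salary_row = nurse_row, unit = "minutes")
  add_items("acc_staff_d", "intensivist time", "staffing", "treatment",
            "ACC", "staff_time", acc_staff * 0.4, n = 1L,
            salary_row = doctor_row, unit = "minutes")
  add_items("acc_oxygen", "high-flow oxygen therapy", "oxygen", "treatment",
            "ACC", "recurrent", extra_t("oxygen"), n = 1L,
            usd_price_fixed = p_icu, unit = "litres")
  add_items("acc_pharma", "ICU medicine", "pharmaceuticals", "treatment",
            "ACC", "recurrent", extra_t("pharmaceuticals"), anchor_usd = 8,
            unit = "dose")
  add_items("acc_capital", "ventilator and ICU equipment",
            "nonpharma_capital", "treatment", "ACC", "capital",
            extra_t("nonpharma_capital"), anchor_usd = 15000, life = 8,
            unit = "device fraction")
  add_items("acc_fluids", "ICU consumables", "nonpharma_recurrent",
            "treatment", "ACC", "recurrent", extra_t("nonpharma_recurrent"),
            anchor_usd = 3, unit = "item")
  add_items("acc_ppe", "ICU protective equipment", "ppe", "identification",
            "ACC", "recurrent", extra_t("ppe"), anchor_usd = 0.5,
            unit = "item")
  add_items("diagnostics", "laboratory and imaging", "diagnostics",
            "treatment", "ACC", "recurrent", extra_t("diagnostics"),
            anchor_usd = 10, unit = "test")

  resources <- validate_resource_table(dplyr::bind_rows(rows_res))
  prices <- validate_pricebook(dplyr::bind_rows(rows_prc))
  targets <- ref[ref$country == country, ]

  structure(list(resources = resources, prices = prices,
                 salaries = salaries, oxygen_scenarios = scenarios,
                 country = country, targets = targets),
            class = "eecc_model")
}

#' Cost an item-level model across the patient-group grid
#'
#' Values and aggregates a model for every costed cell: the three
#' severities at the essential level and severe/critical at the advanced
#' level.
#'
#' @param model An `eecc_model` from [generate_model()].
#' @param ctx A [costing_context()].
#' @return Named list of `cost_breakdown`s keyed
#'   `<country>_<care_level>_<severity>`.
#' @export
model_breakdowns <- function(model, ctx = costing_context()) {
  stopifnot(inherits(model, "eecc_model"))
  cells <- list(c("EECC", "moderate"), c("EECC", "severe"),
                c("EECC", "critical"), c("ACC", "severe"),
                c("ACC", "critical"))
  out <- lapply(cells, function(cell) {
    lines <- value_lines(model$resources, model$prices, cell[2], cell[1], ctx)
    cost_per_patient_day(lines, model$country, cell[2], cell[1])
  })
  names(out) <- vapply(cells, function(cell)
    paste(model$country, cell[1], cell[2], sep = "_"), character(1))
  out
}

#' Write a model's tables to CSV
#'
#' @param model An `eecc_model`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_model <- function(model, dir) {
  stopifnot(inherits(model, "eecc_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    resources = file.path(dir, "resources.csv"),
    pricebook = file.path(dir, "pricebook.csv"),
    salaries = file.path(dir, "salaries.csv"))
  write_resource_table(model$resources, paths[["resources"]])
  write_pricebook(model$prices, paths[["pricebook"]])
  write_salary_schedule(model$salaries, paths[["salaries"]])
  invisible(paths)
}
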