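# Oxygen supply costing: a transparent annualized-capital + recurrent +
# cylinder-refill model per litre delivered, with scenario presets for a
# district hospital (concentrators with cylinder backup, cylinders only)
# and an ICU high-flow supply. Hospital beds and occupancy enter only
# through the annual litres delivered.

#' Define an oxygen supply scenario
#'
#' Describes one way of supplying oxygen to a hospital. The cost per litre
#' is the total annual supply cost — annualized capital components plus
#' recurrent spend (power, maintenance, logistics) plus cylinder refill
#' spend — divided by the litres delivered per year. Litres delivered
#' default to continuous delivery at the scenario's mean flow to the
#' occupied oxygen-served beds.
#'
#' @param mode One of `"concentrator_with_cylinder_backup"`,
#'   `"cylinder_only"`, `"icu_high_flow"`.
#' @param hospital_beds Positive integer count of oxygen-served beds.
#' @param occupancy Bed occupancy in (0, 1].
#' @param capital_components Tibble/data frame with columns `usd_price` and
#'   `useful_life_years`, one row per capital component.
#' @param recurrent_usd_per_year Annual recurrent spend in USD.
#' @param cylinder_refill_usd Price of one cylinder refill in USD.
#' @param refills_per_year Number of refills purchased per year.
#' @param mean_flow_l_per_min Mean delivered flow per occupied bed, used
#'   only to derive `annual_litres_delivered` when that is not given.
#' @param annual_litres_delivered Optional explicit litres per year.
#' @return An object of class `oxygen_scenario`.
#' @export
oxygen_scenario <- function(mode, hospital_beds, occupancy,
                            capital_components = NULL,
                            recurrent_usd_per_year = 0,
                            cylinder_refill_usd = 0,
                            refills_per_year = 0,
                            mean_flow_l_per_min = 3,
                            annual_litres_delivered = NULL) {
  match_enum(mode, c("concentrator_with_cylinder_backup", "cylinder_only",
                     "icu_high_flow"), "oxygen scenario mode")
  if (hospital_beds < 1) stopf("hospital_beds must be positive")
  if (occupancy <= 0 || occupancy > 1) stopf("occupancy must lie in (0, 1]")
  if (is.null(capital_components)) {
    capital_components <- tibble::tibble(usd_price = numeric(),
                                         useful_life_years = numeric())
  }
  capital_components <- tibble::as_tibble(capital_components)
  if (!all(c("usd_price", "useful_life_years") %in%
           names(capital_components))) {
    stopf("capital_components needs columns usd_price and useful_life_years")
  }
  if (is.null(annual_litres_delivered)) {
    annual_litres_delivered <- hospital_beds * occupancy *
      mean_flow_l_per_min * 60 * 24 * 365
  }
  if (annual_litres_delivered <= 0) {
    stopf("annual_litres_delivered must be strictly positive")
  }
  structure(list(
    mode = mode, hospital_beds = as.integer(hospital_beds),
    occupancy = occupancy, capital_components = capital_components,
    recurrent_usd_per_year = recurrent_usd_per_year,
    cylinder_refill_usd = cylinder_refill_usd,
    refills_per_year = refills_per_year,
    annual_litres_delivered = annual_litres_delivered
  ), class = "oxygen_scenario")
}

#' Cost of oxygen per litre delivered
#'
#' Annualizes each capital component at the context discount rate, adds the
#' recurrent and refill spend, and divides by the litres delivered per
#' year.
#'
#' @param scenario An [oxygen_scenario()].
#' @param ctx A [costing_context()].
#' @return USD per litre (strictly positive when any component is).
#' @export
cost_per_litre <- function(scenario, ctx = costing_context()) {
  stopifnot(inherits(scenario, "oxygen_scenario"))
  cap <- scenario$capital_components
  annual_capital <- if (nrow(cap) == 0) 0 else {
    sum(annualize_capital(cap$usd_price, cap$useful_life_years,
                          ctx$discount_rate))
  }
  annual_total <- annual_capital + scenario$recurrent_usd_per_year +
    scenario$cylinder_refill_usd * scenario$refills_per_year
  annual_total / scenario$annual_litres_delivered
}

#' Define an oxygen use profile
#'
#' Flow rate and hours of therapy per day for one severity level. Moderate
#' patients receive no oxygen at the essential care level.
#'
#' @param severity One of [severity_levels()].
#' @param flow_l_per_min Non-negative flow in litres per minute.
#' @param hours_per_day Hours of therapy per day in `[0, 24]`.
#' @return An object of class `oxygen_use_profile`.
#' @export
oxygen_use_profile <- function(severity, flow_l_per_min, hours_per_day) {
  match_enum(severity, severity_levels(), "severity")
  if (flow_l_per_min < 0) stopf("flow must be non-negative")
  if (hours_per_day < 0 || hours_per_day > 24) {
    stopf("hours_per_day must lie in [0, 24]")
  }
  structure(list(severity = severity, flow_l_per_min = flow_l_per_min,
                 hours_per_day = hours_per_day),
            class = "oxygen_use_profile")
}

#' Oxygen cost per patient-day
#'
#' Linear in flow, hours and price per litre:
#' `flow (L/min) x 60 x hours x USD/L`.
#'
#' @param profile An [oxygen_use_profile()].
#' @param usd_per_litre Non-negative price per litre.
#' @return USD per patient-day.
#' @export
oxygen_cost_per_patient_day <- function(profile, usd_per_litre) {
  stopifnot(inherits(profile, "oxygen_use_profile"))
  if (usd_per_litre < 0) stopf("usd_per_litre must be non-negative")
  profile$flow_l_per_min * 60 * profile$hours_per_day * usd_per_litre
}

#' Default oxygen scenarios
#'
#' Three calibrated presets:
#' \describe{
#'   \item{district_concentrator}{Concentrators with cylinder backup at a
#'     20-bed district hospital, 80% occupancy — the reference supply for
#'     essential care. Calibrated so a severe patient at 5 L/min around the
#'     clock costs 4.74 USD/day.}
#'   \item{cylinder_only}{All-cylinder supply at a smaller ward; a costlier
#'     per-litre supply than the concentrator scenario.}
#'   \item{icu_high_flow}{High-flow ICU supply for advanced care,
#'     calibrated so a ventilated/high-flow patient at 40 L/min costs
#'     36.17 USD/day.}
#' }
#' The same per-litre estimates are reused for both countries (no separate
#' supply-cost data for Kenya).
#'
#' @return Named list of [oxygen_scenario()] objects.
#' @export
default_oxygen_scenarios <- function() {
  list(
    district_concentrator = oxygen_scenario(
      mode = "concentrator_with_cylinder_backup",
      hospital_beds = 20, occupancy = 0.8, mean_flow_l_per_min = 3,
      capital_components = tibble::tibble(
        usd_price = c(rep(1400, 12), 2500),
        useful_life_years = c(rep(5, 12), 10)),
      recurrent_usd_per_year = 9000,
      cylinder_refill_usd = 36.48, refills_per_year = 100),
    cylinder_only = oxygen_scenario(
      mode = "cylinder_only",
      hospital_beds = 10, occupancy = 0.8, mean_flow_l_per_min = 3,
      capital_components = tibble::tibble(usd_price = 3000,
                                          useful_life_years = 10),
      recurrent_usd_per_year = 2000,
      cylinder_refill_usd = 36.48, refills_per_year = 400),
    icu_high_flow = oxygen_scenario(
      mode = "icu_high_flow",
      hospital_beds = 10, occupancy = 0.7, mean_flow_l_per_min = 40,
      capital_components = tibble::tibble(
        usd_price = c(rep(5000, 8), 20000),
        useful_life_years = c(rep(5, 8), 10)),
      recurrent_usd_per_year = 35000,
      cylinder_refill_usd = 38.62, refills_per_year = 1200)
  )
}

#' Default oxygen use profiles
#'
#' Assumed flow/hours per severity and care level (the source tables print
#' only daily costs, not flow rates): severe patients 5 L/min for 24 h at
#' either care level; critical patients 20.75 L/min (high-flow equivalent)
#' at the essential level and 40 L/min (ventilator/high-flow ICU preset)
#' at the advanced level; moderate patients none.
#'
#' @param care_level `"EECC"` or `"ACC"`.
#' @return Named list of [oxygen_use_profile()]s keyed by severity.
#' @export
default_oxygen_profiles <- function(care_level = "EECC") {
  match_enum(care_level, care_levels(), "care level")
  critical_flow <- if (care_level == "EECC") 20.75 else 40
  list(
    moderate = oxygen_use_profile("moderate", 0, 0),
    severe = oxygen_use_profile("severe", 5, 24),
    critical = oxygen_use_profile("critical", critical_flow, 24)
  )
}
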