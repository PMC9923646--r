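# Per-admission costs via length of stay, and the severity-mix weighted
# per-day headline figure.

#' Length-of-stay table
#'
#' Average hospital days per admission by country, severity and care level.
#' `default_los_table()` ships the values implied by dividing the published
#' per-stay row by the per-day totals (the primary literature source prints
#' no day counts): 3 days for moderate patients, 8 for severe, and for
#' critical patients 8 (Tanzania) or 14 (Kenya) at the essential level;
#' advanced-care stays are 8/14 (Tanzania severe/critical), 14 and 14.8
#' (Kenya severe/critical). All entries are data, marked reverse-engineered,
#' and overridable.
#'
#' @param country,severity,care_level,los_days,source Column vectors.
#' @return A tibble with one positive `los_days` per
#'   country x severity x care level.
#' @export
los_table <- function(country, severity, care_level, los_days,
                      source = "user") {
  tbl <- tibble::tibble(country = as.character(country),
                        severity = as.character(severity),
                        care_level = as.character(care_level),
                        los_days = as.numeric(los_days),
                        source = as.character(source))
  match_enum(tbl$country, countries(), "country")
  match_enum(tbl$severity, severity_levels(), "severity")
  match_enum(tbl$care_level, care_levels(), "care level")
  if (any(tbl$los_days <= 0)) stopf("los_days must be strictly positive")
  if (anyDuplicated(tbl[c("country", "severity", "care_level")])) {
    stopf("duplicate length-of-stay entry")
  }
  tbl
}

#' @rdname los_table
#' @export
default_los_table <- function() {
  los_table(
    country = c("TZ", "TZ", "TZ", "KE", "KE", "KE",
                "TZ", "TZ", "KE", "KE"),
    severity = c("moderate", "severe", "critical",
                 "moderate", "severe", "critical",
                 "severe", "critical", "severe", "critical"),
    care_level = c(rep("EECC", 6), rep("ACC", 4)),
    los_days = c(3, 8, 8, 3, 8, 14, 8, 14, 14, 14.8),
    source = "reverse-engineered from published per-stay row"
  )
}

#' Look up a length of stay
#' @param los A [los_table()].
#' @param country,severity,care_level Cell to look up.
#' @return Length of stay in days.
#' @export
lookup_los <- function(los, country, severity, care_level) {
  row <- los[los$country == country & los$severity == severity &
               los$care_level == care_level, ]
  if (nrow(row) != 1) {
    stopf("no length of stay for %s/%s/%s", country, severity, care_level)
  }
  row$los_days
}

#' Cost per hospital admission
#'
#' Daily cost times average length of stay, reported at two decimals.
#'
#' @param per_day_usd Non-negative cost per patient-day.
#' @param los_days Non-negative average length of stay in days.
#' @return USD per admission (half-up, 2 dp).
#' @export
#' @examples
#' cost_per_admission(10.83, 8)  # 86.64
cost_per_admission <- function(per_day_usd, los_days) {
  if (any(per_day_usd < 0) || any(los_days < 0)) {
    stopf("inputs must be non-negative")
  }
  round_half_up(per_day_usd * los_days, 2)
}

#' Severity-mix weights
#'
#' Weights combining severe and critical per-day costs into one headline
#' cost of critical illness care. Default: 74% of the critically ill are
#' severe and 26% critical.
#'
#' @param w_severe,w_critical Weights in `[0, 1]` summing to 1.
#' @return An object of class `mix_weights`.
#' @export
mix_weights <- function(w_severe = 0.74, w_critical = 0.26) {
  if (w_severe < 0 || w_severe > 1 || w_critical < 0 || w_critical > 1) {
    stopf("weights must lie in [0, 1]")
  }
  if (abs(w_severe + w_critical - 1) > 1e-9) {
    stopf("weights must sum to 1")
  }
  structure(list(w_severe = w_severe, w_critical = w_critical),
            class = "mix_weights")
}

#' Severity-mix weighted daily cost
#'
#' @param severe_usd,critical_usd Per-day costs for severe and critical
#'   patients.
#' @param w A [mix_weights()].
#' @return The weighted daily cost (full precision; round to whole USD for
#'   headline reporting).
#' @export
#' @examples
#' weighted_daily_cost(10.83, 32.84)                 # 16.55...
#' round_half_up(weighted_daily_cost(10.83, 32.84), 0)  # 17
weighted_daily_cost <- function(severe_usd, critical_usd, w = mix_weights()) {
  stopifnot(inherits(w, "mix_weights"))
  w$w_severe * severe_usd + w$w_critical * critical_usd
}
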