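#' Global valuation constants
#'
#' Bundles the exchange rates, discount rate, transport/insurance uplift,
#' staff-time denominator and Monte Carlo settings used throughout a
#' costing run. The defaults are the study constants: 2020 exchange rates
#' of 2300 TZS and 115 KES per USD, a 3% discount rate for capital
#' annualization, a 17.4% uplift on goods priced without shipping, and
#' 1000 probabilistic draws summarised by the empirical 2.5% and 97.5%
#' quantiles.
#'
#' @param fx_rate_tzs_per_usd Tanzanian shillings per US dollar.
#' @param fx_rate_kes_per_usd Kenyan shillings per US dollar.
#' @param discount_rate Annual discount rate in `[0, 1)` for capital
#'   annualization.
#' @param transport_uplift Proportional uplift applied to goods flagged
#'   `needs_uplift` (0.174 = 17.4%).
#' @param working_minutes_per_year Staff-time denominator; default 108000
#'   (225 working days of 8 hours), a standard public-sector assumption.
#' @param psa_draws Monte Carlo sample size for the probabilistic
#'   sensitivity analysis.
#' @param ci_quantiles Lower and upper interval quantiles in (0, 1).
#' @param seed Integer root seed for all randomness.
#' @return An object of class `costing_context` (a validated list).
#' @export
#' @examples
#' ctx <- costing_context()
#' convert_to_usd(2300, "TZS", ctx)  # 1
costing_context <- function(fx_rate_tzs_per_usd = 2300,
                            fx_rate_kes_per_usd = 115,
                            discount_rate = 0.03,
                            transport_uplift = 0.174,
                            working_minutes_per_year = 108000L,
                            psa_draws = 1000L,
                            ci_quantiles = c(0.025, 0.975),
                            seed = 1L) {
  if (fx_rate_tzs_per_usd <= 0 || fx_rate_kes_per_usd <= 0) {
    stopf("exchange rates must be strictly positive")
  }
  if (discount_rate < 0 || discount_rate >= 1) {
    stopf("discount_rate must lie in [0, 1)")
  }
  if (transport_uplift < 0) stopf("transport_uplift must be non-negative")
  if (working_minutes_per_year <= 0) {
    stopf("working_minutes_per_year must be strictly positive")
  }
  if (psa_draws < 1) stopf("psa_draws must be at least 1")
  if (length(ci_quantiles) != 2 || any(ci_quantiles <= 0) ||
      any(ci_quantiles >= 1) || ci_quantiles[1] >= ci_quantiles[2]) {
    stopf("ci_quantiles must be an increasing pair in (0, 1)")
  }
  structure(list(
    fx_rate_tzs_per_usd = fx_rate_tzs_per_usd,
    fx_rate_kes_per_usd = fx_rate_kes_per_usd,
    discount_rate = discount_rate,
    transport_uplift = transport_uplift,
    working_minutes_per_year = as.integer(working_minutes_per_year),
    psa_draws = as.integer(psa_draws),
    ci_quantiles = as.numeric(ci_quantiles),
    seed = as.integer(seed)
  ), class = "costing_context")
}

#' Convert an amount to US dollars
#'
#' @param amount Non-negative numeric vector.
#' @param currency Character vector of currency codes (recycled).
#' @param ctx A [costing_context()].
#' @return Numeric vector in USD.
#' @export
convert_to_usd <- function(amount, currency, ctx = costing_context()) {
  match_enum(currency, currencies(), "currency")
  if (any(amount < 0, na.rm = TRUE)) stopf("amounts must be non-negative")
  rate <- c(TZS = ctx$fx_rate_tzs_per_usd, KES = ctx$fx_rate_kes_per_usd,
            USD = 1)[currency]
  unname(amount / rate)
}

#' Apply the transport and insurance uplift
#'
#' Goods priced without shipping receive a fixed percentage uplift
#' (default 17.4%) covering transportation and insurance. Salaries and
#' hotel charges are never uplifted; the flag travels with the price.
#'
#' @param usd_price Non-negative USD price(s).
#' @param ctx A [costing_context()].
#' @param needs_uplift Logical vector; prices with `FALSE` pass unchanged.
#' @return Uplifted USD price(s).
#' @export
apply_uplift <- function(usd_price, ctx = costing_context(),
                         needs_uplift = TRUE) {
  if (any(usd_price < 0, na.rm = TRUE)) stopf("prices must be non-negative")
  ifelse(needs_uplift, usd_price * (1 + ctx$transport_uplift), usd_price)
}

#' Annuity factor for capital annualization
#'
#' `AF(r, L) = (1 - (1 + r)^-L) / r` for discount rate `r > 0`, with the
#' straight-line limit `AF = L` at `r = 0`. Annualized cost is the purchase
#' price divided by this factor. For every `r > 0`, `AF(r, L) < L`.
#'
#' @param discount_rate Rate in `[0, 1)`.
#' @param useful_life_years Positive life in years.
#' @return The annuity factor.
#' @export
annuity_factor <- function(discount_rate, useful_life_years) {
  if (any(useful_life_years <= 0)) stopf("useful life must be positive")
  n <- max(length(discount_rate), length(useful_life_years))
  r <- rep_len(discount_rate, n)
  life <- rep_len(useful_life_years, n)
  ifelse(r == 0, life, (1 - (1 + r)^(-life)) / r)
}

#' Annualize a capital cost
#'
#' Spreads a capital purchase over its useful life as an equivalent annual
#' cost using the annuity factor at the context discount rate.
#'
#' @param usd_price Purchase price in USD.
#' @param useful_life_years Positive life in years.
#' @param discount_rate Rate in `[0, 1)`, default 0.03.
#' @return USD per year.
#' @export
#' @examples
#' annualize_capital(1000, 5)      # 218.35 per year at 3%
#' annualize_capital(1000, 5, 0)   # 200 per year, straight line
annualize_capital <- function(usd_price, useful_life_years,
                              discount_rate = 0.03) {
  if (discount_rate < 0 || discount_rate >= 1) {
    stopf("discount_rate must lie in [0, 1)")
  }
  usd_price / annuity_factor(discount_rate, useful_life_years)
}

#' Staff cost per patient-day
#'
#' Values staff time from an annual public-sector salary: the per-minute
#' rate (annual salary over annual working minutes) times the minutes of
#' care per patient-day.
#'
#' @param annual_salary Annual salary amount.
#' @param currency Currency of the salary.
#' @param minutes_per_day Non-negative minutes of this cadre's time per
#'   patient-day.
#' @param ctx A [costing_context()].
#' @return USD per patient-day.
#' @export
staff_cost_per_patient_day <- function(annual_salary, currency,
                                       minutes_per_day,
                                       ctx = costing_context()) {
  if (any(minutes_per_day < 0)) stopf("minutes_per_day must be non-negative")
  if (ctx$working_minutes_per_year <= 0) {
    stopf("working minutes per year must be strictly positive")
  }
  convert_to_usd(annual_salary, currency, ctx) * minutes_per_day /
    ctx$working_minutes_per_year
}

#' @keywords internal
severity_qty_col <- function(severity) {
  match_enum(severity, severity_levels(), "severity")
  paste0("qty_", severity)
}

#' Cost of one resource line per patient-day
#'
#' Applies the valuation rule for the line's cost type:
#' \itemize{
#'   \item recurrent: daily quantity times the (uplifted) USD unit price;
#'   \item capital: annualized USD cost times the device-fraction quantity,
#'     divided by 365 days;
#'   \item staff time: annual salary valued via
#'     [staff_cost_per_patient_day()] with the quantity read as minutes per
#'     patient-day.
#' }
#'
#' @param line One row of a [resource_table()].
#' @param price The matching row of a [pricebook()].
#' @param severity One of [severity_levels()].
#' @param ctx A [costing_context()].
#' @return A one-row tibble with `item_id`, `category`, `severity` and
#'   `usd_per_patient_day`.
#' @export
line_daily_cost <- function(line, price, severity, ctx = costing_context()) {
  if (!identical(line$item_id, price$item_id)) {
    stopf("price item_id '%s' does not match line item_id '%s'",
          price$item_id, line$item_id)
  }
  qty <- line[[severity_qty_col(severity)]]
  if (is.na(qty)) stopf("quantity undefined for severity '%s'", severity)
  usd <- convert_to_usd(price$price, price$currency, ctx)
  daily <- switch(
    price$cost_type,
    recurrent = qty * apply_uplift(usd, ctx, price$needs_uplift),
    capital = annualize_capital(apply_uplift(usd, ctx, price$needs_uplift),
                                price$useful_life_years,
                                ctx$discount_rate) * qty / 365,
    staff_time = staff_cost_per_patient_day(price$price, price$currency,
                                            qty, ctx),
    stopf("unknown cost type '%s'", price$cost_type)
  )
  tibble::tibble(item_id = line$item_id, category = line$category,
                 severity = severity, usd_per_patient_day = daily)
}

#' Value every applicable resource line for one patient group
#'
#' Filters the resource table to the requested care level (EECC excludes
#' ACC-only lines; ACC includes everything), joins prices, and applies
#' [line_daily_cost()] to each line at the requested severity.
#'
#' @param resources A [resource_table()].
#' @param prices A [pricebook()] covering every line.
#' @param severity One of [severity_levels()].
#' @param care_level `"EECC"` or `"ACC"`.
#' @param ctx A [costing_context()].
#' @return A tibble of line daily costs with columns `item_id`, `category`,
#'   `severity`, `care_level`, `usd_per_patient_day`.
#' @export
value_lines <- function(resources, prices, severity, care_level = "EECC",
                        ctx = costing_context()) {
  resources <- validate_resource_table(resources)
  prices <- validate_pricebook(prices)
  match_enum(care_level, care_levels(), "care level")
  report <- validate_model(resources, prices)
  if (length(report$missing_price) > 0) {
    stopf("no price for item(s): %s",
          paste(report$missing_price, collapse = ", "))
  }
  keep <- if (care_level == "EECC") resources$applicability != "ACC"
          else rep(TRUE, nrow(resources))
  resources <- resources[keep, ]
  out <- lapply(seq_len(nrow(resources)), function(i) {
    line <- resources[i, ]
    line_daily_cost(line, prices[prices$item_id == line$item_id, ],
                    severity, ctx)
  })
  costs <- dplyr::bind_rows(out)
  if (nrow(costs) == 0) {
    costs <- tibble::tibble(item_id = character(), category = character(),
                            severity = character(),
                            usd_per_patient_day = numeric())
  }
  costs$care_level <- care_level
  costs[c("item_id", "category", "severity", "care_level",
          "usd_per_patient_day")]
}
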