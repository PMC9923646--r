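# Scenario bounds and the gamma Monte Carlo probabilistic sensitivity
# analysis. Scenario analysis perturbs oxygen (and, for advanced care,
# pharmaceutical) costs by an indicative +/-25% and re-values staffing with
# alternative cadres/grades; the resulting low/high bounds per category
# parameterize independent gamma distributions whose Monte Carlo sum gives
# a mean and interval for the daily total.

#' Define a scenario specification
#'
#' @param oxygen_multipliers `(low, high)` multipliers on the oxygen
#'   category, default `c(0.75, 1.25)` (an indicative 25% swing).
#' @param pharma_multipliers `(low, high)` multipliers on pharmaceuticals,
#'   applied only when `vary_pharma = TRUE` (the advanced-care analysis).
#' @param vary_pharma Logical; vary pharmaceutical costs?
#' @param staffing_mode `"reference"` (no staffing scenario), or
#'   `"banded"`: re-value staffing with the lowest-cost cadre (low bound)
#'   and the highest nurse grade plus consultant doctor (high bound), via
#'   the salary-schedule bands.
#' @param overrides Optional named list `category -> c(low, high)` of
#'   explicit USD/day bounds that take precedence over the rules above.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(oxygen_multipliers = c(0.75, 1.25),
                          pharma_multipliers = c(0.75, 1.25),
                          vary_pharma = FALSE,
                          staffing_mode = c("reference", "banded"),
                          overrides = list()) {
  staffing_mode <- match.arg(staffing_mode)
  check_pair <- function(p, what) {
    if (length(p) != 2 || p[1] > 1 || p[2] < 1) {
      stopf("%s must be a (low, high) pair with low <= 1 <= high", what)
    }
  }
  check_pair(oxygen_multipliers, "oxygen_multipliers")
  check_pair(pharma_multipliers, "pharma_multipliers")
  if (length(overrides) > 0) {
    match_enum(names(overrides), cost_categories(), "override category")
    for (nm in names(overrides)) {
      if (length(overrides[[nm]]) != 2) {
        stopf("override for %s must be c(low, high)", nm)
      }
    }
  }
  structure(list(oxygen_multipliers = as.numeric(oxygen_multipliers),
                 pharma_multipliers = as.numeric(pharma_multipliers),
                 vary_pharma = isTRUE(vary_pharma),
                 staffing_mode = staffing_mode, overrides = overrides),
            class = "scenario_spec")
}

#' @keywords internal
band_rate <- function(salaries, country, band, ctx) {
  rows <- salaries[salaries$country == country & salaries$band == band, ]
  if (nrow(rows) == 0) {
    stopf("salary schedule lacks band '%s' for country %s", band, country)
  }
  mean(convert_to_usd(rows$annual_salary, rows$currency, ctx))
}

#' Build low/reference/high scenario bounds per category
#'
#' Applies the scenario rules to a reference breakdown: oxygen (and, for
#' advanced care, pharmaceutical) bounds are the reference times the
#' multiplier pair; staffing bounds in `"banded"` mode rescale the
#' reference staffing cost by the ratio of band salary rates (low cadre /
#' reference mix, and highest grades / reference mix); categories not
#' perturbed get degenerate `(ref, ref, ref)` bounds. Explicit per-category
#' overrides take precedence.
#'
#' @param reference A `cost_breakdown` for the reference scenario.
#' @param spec A [scenario_spec()].
#' @param salaries A [salary_schedule()] with `low`, `reference` and
#'   `high` bands for the breakdown's country; required for
#'   `staffing_mode = "banded"`.
#' @param ctx A [costing_context()].
#' @return An object of class `scenario_bounds`: a tibble with columns
#'   `category`, `low`, `reference`, `high` (USD per patient-day).
#' @export
build_bounds <- function(reference, spec = scenario_spec(),
                         salaries = NULL, ctx = costing_context()) {
  stopifnot(inherits(reference, "cost_breakdown"),
            inherits(spec, "scenario_spec"))
  ref <- reference$per_category_usd
  low <- ref
  high <- ref
  low["oxygen"] <- ref["oxygen"] * spec$oxygen_multipliers[1]
  high["oxygen"] <- ref["oxygen"] * spec$oxygen_multipliers[2]
  if (spec$vary_pharma) {
    low["pharmaceuticals"] <- ref["pharmaceuticals"] * spec$pharma_multipliers[1]
    high["pharmaceuticals"] <- ref["pharmaceuticals"] * spec$pharma_multipliers[2]
  }
  if (spec$staffing_mode == "banded" &&
      !("staffing" %in% names(spec$overrides))) {
    if (is.null(salaries)) {
      stopf("staffing_mode 'banded' requires a salary schedule")
    }
    r_ref <- band_rate(salaries, reference$country, "reference", ctx)
    low["staffing"] <- ref["staffing"] *
      band_rate(salaries, reference$country, "low", ctx) / r_ref
    high["staffing"] <- ref["staffing"] *
      band_rate(salaries, reference$country, "high", ctx) / r_ref
  }
  for (nm in names(spec$overrides)) {
    low[nm] <- spec$overrides[[nm]][1]
    high[nm] <- spec$overrides[[nm]][2]
  }
  bad <- which(low > ref + 1e-9 | high < ref - 1e-9)
  if (length(bad) > 0) {
    stopf("scenario bounds violate low <= reference <= high for: %s",
          paste(names(ref)[bad], collapse = ", "))
  }
  structure(tibble::tibble(category = names(ref), low = pmin(unname(low), unname(ref)),
                           reference = unname(ref),
                           high = pmax(unname(high), unname(ref))),
            class = c("scenario_bounds", "tbl_df", "tbl", "data.frame"))
}

#' Total cost range implied by scenario bounds
#'
#' @param bounds A `scenario_bounds` object.
#' @return Named numeric `c(low, reference, high)` daily totals.
#' @export
scenario_range <- function(bounds) {
  stopifnot(inherits(bounds, "scenario_bounds"))
  c(low = sum(bounds$low), reference = sum(bounds$reference),
    high = sum(bounds$high))
}

#' Fit a gamma distribution from a reference value and bounds
#'
#' Method-of-moments fit reading the scenario bounds as central-95% limits:
#' mean equals the reference and `sd = (high - low) / 3.92`, giving
#' `shape = (mean/sd)^2` and `scale = sd^2/mean`. Degenerate input
#' (`low == high`) yields a point mass at the reference.
#'
#' @param reference Reference (mean) value, `low <= reference <= high`.
#' @param low,high Non-negative bounds.
#' @return A list with `shape`, `scale`, `point_mass` (logical) and
#'   `value` (the point-mass location, when degenerate).
#' @export
#' @examples
#' fit_gamma(4, 4 - 1.96 * 2, 4 + 1.96 * 2)  # shape 4, scale 1
fit_gamma <- function(reference, low, high) {
  if (low < 0 || low > reference || reference > high) {
    stopf("need 0 <= low <= reference <= high")
  }
  sd <- (high - low) / 3.92
  if (sd == 0) {
    return(list(shape = NA_real_, scale = NA_real_, point_mass = TRUE,
                value = reference))
  }
  if (reference <= 0) stopf("reference must be positive unless low == high")
  list(shape = (reference / sd)^2, scale = sd^2 / reference,
       point_mass = FALSE, value = NA_real_)
}

#' Run the gamma Monte Carlo probabilistic sensitivity analysis
#'
#' Samples each category independently from its fitted gamma distribution
#' (point masses stay fixed), sums categories per draw, and reports the
#' sample mean and the empirical interval at the context quantiles.
#' Each category draws from its own random stream, derived from the root
#' seed by a stable hash of the category name, so adding or removing a
#' category never perturbs the other categories' draws.
#'
#' @param bounds A `scenario_bounds` object, see [build_bounds()].
#' @param ctx A [costing_context()]; `psa_draws`, `ci_quantiles` and `seed`
#'   are used.
#' @param keep_draws Keep the vector of sampled totals in the result?
#' @return An object of class `psa_result`: a list with `mean_usd`,
#'   `ci_low_usd`, `ci_high_usd`, `draws`, `seed` (and `totals` when
#'   `keep_draws = TRUE`).
#' @export
run_psa <- function(bounds, ctx = costing_context(), keep_draws = FALSE) {
  stopifnot(inherits(bounds, "scenario_bounds"))
  n <- ctx$psa_draws
  totals <- numeric(n)
  for (i in seq_len(nrow(bounds))) {
    fit <- fit_gamma(bounds$reference[i], bounds$low[i], bounds$high[i])
    if (fit$point_mass) {
      totals <- totals + fit$value
    } else {
      seed_i <- (as.numeric(ctx$seed) + string_hash(bounds$category[i])) %%
        2147483647
      draws <- with_seed(seed_i,
                         stats::rgamma(n, shape = fit$shape,
                                       scale = fit$scale))
      if (any(!is.finite(draws))) stopf("non-finite gamma sample")
      totals <- totals + draws
    }
  }
  ci <- unname(stats::quantile(totals, ctx$ci_quantiles))
  out <- list(mean_usd = mean(totals), ci_low_usd = ci[1],
              ci_high_usd = ci[2], draws = n, seed = ctx$seed)
  if (keep_draws) out$totals <- totals
  structure(out, class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("%.2f (%.2f-%.2f)  [n = %d, seed = %d]\n", x$mean_usd,
              x$ci_low_usd, x$ci_high_usd, x$draws, x$seed))
  invisible(x)
}

#' Format a PSA result in the published table style
#'
#' @param x A `psa_result`.
#' @return A string `"mean (low-high)"` at two decimal places.
#' @export
format_psa <- function(x) {
  stopifnot(inherits(x, "psa_result"))
  sprintf("%.2f (%.2f–%.2f)", round_half_up(x$mean_usd),
          round_half_up(x$ci_low_usd), round_half_up(x$ci_high_usd))
}
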