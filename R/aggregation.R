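# Aggregation of valued lines into per-patient-day cost breakdowns by
# country x severity x care level, with category percentage shares.

#' Rounded, internally consistent percentage shares
#'
#' Shares are reported in the mixed precision of the published tables:
#' whole percent when at least 1%, one decimal place below 1%. Whole-percent
#' shares are apportioned by largest remainder against the residual left by
#' the sub-1% shares, which keeps the rounded shares summing to
#' 100 plus/minus 0.5.
#'
#' @param shares Numeric vector of exact shares summing to 100.
#' @return Numeric vector of rounded shares, same names/order.
#' @export
round_shares <- function(shares) {
  if (length(shares) == 0) return(shares)
  out <- numeric(length(shares))
  small <- shares < 1
  out[small] <- round_half_up(shares[small], 1)
  if (any(!small)) {
    target <- round_half_up(100 - sum(out[small]), 0)
    base <- floor(shares[!small])
    remainder <- shares[!small] - base
    short <- target - sum(base)
    if (short > 0) {
      bump <- order(remainder, decreasing = TRUE)[seq_len(min(short, sum(!small)))]
      base[bump] <- base[bump] + 1
    }
    out[!small] <- base
  }
  names(out) <- names(shares)
  out
}

#' @keywords internal
new_cost_breakdown <- function(per_category, country, severity, care_level) {
  full <- stats::setNames(numeric(length(cost_categories())),
                          cost_categories())
  full[names(per_category)] <- per_category
  total <- sum(full)
  shares <- if (total > 0) 100 * full / total else
    stats::setNames(numeric(0), character(0))
  structure(list(
    country = country, severity = severity, care_level = care_level,
    per_category_usd = full, total_usd_per_day = total,
    shares_pct = shares,
    shares_rounded = if (total > 0) round_shares(shares) else shares
  ), class = "cost_breakdown")
}

#' Build a cost breakdown from category costs
#'
#' Low-level constructor taking per-category USD/patient-day values
#' directly (e.g. from a category-level cost table). Categories not named
#' are zero.
#'
#' @param per_category Named numeric vector keyed by [cost_categories()].
#' @param country `"TZ"` or `"KE"`.
#' @param severity One of [severity_levels()].
#' @param care_level `"EECC"` or `"ACC"`.
#' @return An object of class `cost_breakdown` with elements
#'   `per_category_usd`, `total_usd_per_day`, `shares_pct` (exact) and
#'   `shares_rounded` (reporting precision).
#' @export
cost_breakdown <- function(per_category, country, severity, care_level) {
  match_enum(country, countries(), "country")
  match_enum(severity, severity_levels(), "severity")
  match_enum(care_level, care_levels(), "care level")
  match_enum(names(per_category), cost_categories(), "cost category")
  if (any(per_category < 0)) stopf("category costs must be non-negative")
  new_cost_breakdown(per_category, country, severity, care_level)
}

#' Sum valued lines into a per-patient-day breakdown
#'
#' @param lines A tibble of line daily costs as produced by [value_lines()]
#'   (already filtered to the requested care level). A `country` column, if
#'   present, must be constant.
#' @param country,severity,care_level Labels for the breakdown.
#' @return A `cost_breakdown`, see [cost_breakdown()].
#' @export
cost_per_patient_day <- function(lines, country, severity, care_level) {
  if ("country" %in% names(lines) && length(unique(lines$country)) > 1) {
    stopf("lines mix countries: %s",
          paste(unique(lines$country), collapse = ", "))
  }
  per_category <- tapply(lines$usd_per_patient_day, lines$category, sum)
  per_category <- stats::setNames(as.numeric(per_category),
                                  names(per_category))
  per_category <- per_category[!is.na(per_category)]
  cost_breakdown(per_category, country, severity, care_level)
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("Cost per patient-day: %s / %s / %s\n",
              x$country, x$severity, x$care_level))
  labels <- cost_category_labels()
  width <- max(nchar(labels), nchar("Total"))
  for (nm in names(x$per_category_usd)) {
    share <- if (length(x$shares_rounded) > 0) x$shares_rounded[[nm]] else NA
    cat(sprintf("  %-*s %8.2f  %s\n", width, labels[[nm]],
                x$per_category_usd[[nm]],
                if (is.na(share)) "" else paste0(share, "%")))
  }
  cat(sprintf("  %-*s %8.2f\n", width, "Total", x$total_usd_per_day))
  invisible(x)
}

#' Percentage share of one category
#'
#' Returns the category's share of the daily total at reporting precision
#' (whole percent at or above 1%, one decimal below), consistent with the
#' breakdown's jointly rounded shares.
#'
#' @param breakdown A `cost_breakdown`.
#' @param category One of [cost_categories()].
#' @return The rounded share in percent.
#' @export
category_share <- function(breakdown, category) {
  stopifnot(inherits(breakdown, "cost_breakdown"))
  match_enum(category, cost_categories(), "cost category")
  if (breakdown$total_usd_per_day <= 0) {
    stopf("category shares are undefined for a zero total")
  }
  unname(breakdown$shares_rounded[category])
}

#' Daily total excluding hotel costs
#'
#' The incremental critical-care perspective excludes hotel care; the
#' published tables nonetheless print a hotel row, so the default total is
#' with-hotel and this accessor gives the without-hotel figure.
#'
#' @param breakdown A `cost_breakdown`.
#' @return USD per patient-day excluding the hotel category.
#' @export
total_excluding_hotel <- function(breakdown) {
  stopifnot(inherits(breakdown, "cost_breakdown"))
  breakdown$total_usd_per_day - breakdown$per_category_usd[["hotel"]]
}

#' Compare advanced with essential care for one patient group
#'
#' @param eecc,acc `cost_breakdown`s for the same country and severity at
#'   the EECC and ACC care levels respectively.
#' @return A list with `ratio` (ACC total over EECC total) and
#'   `per_category_delta` (ACC minus EECC, named by category).
#' @export
compare_levels <- function(eecc, acc) {
  stopifnot(inherits(eecc, "cost_breakdown"), inherits(acc, "cost_breakdown"))
  if (!identical(eecc$country, acc$country) ||
      !identical(eecc$severity, acc$severity)) {
    stopf("breakdowns must share country and severity")
  }
  if (eecc$total_usd_per_day <= 0) {
    stopf("EECC total must be positive to form a ratio")
  }
  if (acc$total_usd_per_day < eecc$total_usd_per_day - 1e-9) {
    stopf("ACC total below EECC total: the advanced resource set must be a superset")
  }
  list(ratio = acc$total_usd_per_day / eecc$total_usd_per_day,
       per_category_delta = acc$per_category_usd - eecc$per_category_usd)
}

#' Tabulate a set of breakdowns
#'
#' Long-format export of one or more breakdowns, one row per category plus
#' a `total` row per breakdown, suitable for CSV export mirroring the
#' published tables' row order.
#'
#' @param breakdowns A list of `cost_breakdown`s.
#' @return A tibble with columns `country`, `severity`, `care_level`,
#'   `category`, `usd_per_day`, `share_pct`.
#' @export
breakdown_table <- function(breakdowns) {
  if (inherits(breakdowns, "cost_breakdown")) breakdowns <- list(breakdowns)
  rows <- lapply(breakdowns, function(b) {
    shares <- if (length(b$shares_rounded) > 0) {
      unname(b$shares_rounded[cost_categories()])
    } else rep(NA_real_, length(cost_categories()))
    tibble::tibble(
      country = b$country, severity = b$severity, care_level = b$care_level,
      category = c(cost_categories(), "total"),
      usd_per_day = c(unname(b$per_category_usd[cost_categories()]),
                      b$total_usd_per_day),
      share_pct = c(shares, if (b$total_usd_per_day > 0) 100 else NA_real_)
    )
  })
  dplyr::bind_rows(rows)
}
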