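# Run configuration and report writers. A run is described by one YAML
# configuration file; reports mirror the published tables: per-category
# USD/patient-day with percentage shares, a per-stay row, PSA summaries in
# "mean (low-high)" style, and low/reference/high scenario ranges.

#' Read, write and default run configurations
#'
#' A run configuration is a YAML tree with keys:
#' \describe{
#'   \item{model}{`"reference"` (category-level reference table),
#'     `"synthetic"` (generate an item-level model) or `"files"` (read
#'     resource table, price book and salary schedule from CSV paths).}
#'   \item{countries}{Countries to report (reference model only).}
#'   \item{resources, pricebook, salaries}{CSV paths for `model: files`.}
#'   \item{generator}{[generator_config()] fields for `model: synthetic`.}
#'   \item{context}{[costing_context()] field overrides.}
#'   \item{los}{Optional length-of-stay rows (country, severity,
#'     care_level, los_days); defaults to [default_los_table()].}
#'   \item{mix_weights}{`severe` and `critical` weights.}
#'   \item{output_dir}{Where reports are written.}
#' }
#'
#' @param path Path to a YAML file.
#' @return `read_run_config()` returns a validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("run configuration not found: %s", path)
  raw <- yaml::read_yaml(path)
  validate_run_config(raw, path = path)
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  validate_run_config(list(model = "reference"))
}

#' @rdname read_run_config
#' @param config A `run_config` list.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out$context <- unclass(out$context)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @keywords internal
validate_run_config <- function(raw, path = "<config>") {
  known <- c("model", "countries", "resources", "pricebook", "salaries",
             "generator", "context", "los", "mix_weights", "output_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stopf("unknown run configuration key(s) in %s: %s", path,
          paste(unknown, collapse = ", "))
  }
  model <- raw$model %||% "reference"
  match_enum(model, c("reference", "synthetic", "files"), "model")
  ctx <- do.call(costing_context, raw$context %||% list())
  config <- list(
    model = model,
    countries = raw$countries %||% countries(),
    resources = raw$resources, pricebook = raw$pricebook,
    salaries = raw$salaries,
    generator = raw$generator %||% list(),
    context = ctx,
    los = if (is.null(raw$los)) default_los_table() else
      do.call(los_table, raw$los),
    mix_weights = mix_weights(raw$mix_weights$severe %||% 0.74,
                              raw$mix_weights$critical %||% 0.26),
    output_dir = raw$output_dir %||% "."
  )
  match_enum(config$countries, countries(), "country")
  if (model == "files") {
    for (key in c("resources", "pricebook")) {
      if (is.null(config[[key]])) {
        stopf("run configuration key '%s' is required for model: files", key)
      }
      if (!file.exists(config[[key]])) {
        stopf("run configuration key '%s' points to a missing file: %s",
              key, config[[key]])
      }
    }
  }
  structure(config, class = "run_config")
}

#' @keywords internal
config_breakdowns <- function(config) {
  if (config$model == "reference") {
    bs <- reference_breakdowns()
    bs[vapply(bs, function(b) b$country %in% config$countries, logical(1))]
  } else if (config$model == "synthetic") {
    cfg <- do.call(generator_config, config$generator)
    model_breakdowns(generate_model(cfg, config$context), config$context)
  } else {
    resources <- read_resource_table(config$resources)
    prices <- read_pricebook(config$pricebook)
    country <- config$countries[1]
    model <- structure(list(resources = resources, prices = prices,
                            country = country), class = "eecc_model")
    model_breakdowns(model, config$context)
  }
}

#' @keywords internal
config_salaries <- function(config) {
  if (config$model == "files" && !is.null(config$salaries)) {
    read_salary_schedule(config$salaries)
  } else if (config$model == "synthetic") {
    cfg <- do.call(generator_config, config$generator)
    generate_model(cfg, config$context)$salaries
  } else {
    reference_salary_schedule()
  }
}

#' @keywords internal
config_spec <- function(config, b) {
  if (config$model == "reference") {
    reference_scenario_spec(b$country, b$severity, b$care_level)
  } else {
    scenario_spec(vary_pharma = b$care_level == "ACC",
                  staffing_mode = "banded")
  }
}

#' Wide cost table for one care level
#'
#' @param breakdowns List of `cost_breakdown`s (one care level).
#' @param los A [los_table()] supplying the per-stay row.
#' @return A tibble: category label rows plus `Patient cost/day` and
#'   `Cost per patient per stay` rows; one USD and one share column per
#'   country x severity.
#' @export
cost_table <- function(breakdowns, los = default_los_table()) {
  labels <- c(cost_category_labels(), total = "Patient cost/day (USD)",
              stay = "Cost per patient per stay in hospital (USD)")
  out <- tibble::tibble(row = unname(labels))
  for (b in breakdowns) {
    usd <- c(unname(b$per_category_usd[cost_categories()]),
             b$total_usd_per_day,
             cost_per_admission(b$total_usd_per_day,
                                lookup_los(los, b$country, b$severity,
                                           b$care_level)))
    shr <- if (length(b$shares_rounded) > 0) {
      c(unname(b$shares_rounded[cost_categories()]), 100, NA_real_)
    } else rep(NA_real_, length(usd))
    key <- paste(b$country, b$severity, sep = "_")
    out[[paste0(key, "_usd")]] <- round_half_up(usd, 2)
    out[[paste0(key, "_pct")]] <- shr
  }
  out
}

#' @keywords internal
format_aligned <- function(tbl) {
  widths <- vapply(names(tbl), function(nm) {
    max(nchar(nm), nchar(format(tbl[[nm]])), na.rm = TRUE)
  }, numeric(1))
  fmt_row <- function(values) {
    paste(mapply(formatC, as.character(values), width = widths), collapse = "  ")
  }
  c(fmt_row(names(tbl)),
    vapply(seq_len(nrow(tbl)), function(i) fmt_row(tbl[i, ]), character(1)))
}

#' Run the costing report
#'
#' Computes every cost breakdown defined by the configuration and writes,
#' per care level, a CSV and an aligned-text table (category rows, daily
#' total, per-stay row), plus a severity-mix summary and a run manifest.
#'
#' @param config A `run_config`, see [read_run_config()].
#' @param config_path Optional path of the source YAML, recorded (with its
#'   MD5) in the manifest.
#' @return Invisibly, the list of `cost_breakdown`s.
#' @export
run_costing <- function(config = default_run_config(), config_path = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  breakdowns <- config_breakdowns(config)
  if (all(vapply(breakdowns, function(b) b$total_usd_per_day == 0,
                 logical(1)))) {
    warning("all breakdown totals are zero; check the resource table",
            call. = FALSE)
  }
  files <- character(0)
  for (level in care_levels()) {
    bs <- breakdowns[vapply(breakdowns, function(b)
      b$care_level == level, logical(1))]
    if (length(bs) == 0) next
    tbl <- cost_table(bs, config$los)
    csv <- file.path(config$output_dir, sprintf("costs_%s.csv", level))
    txt <- file.path(config$output_dir, sprintf("costs_%s.txt", level))
    readr::write_csv(tbl, csv, progress = FALSE)
    writeLines(format_aligned(tbl), txt)
    files <- c(files, csv, txt)
  }
  mix <- severity_mix_summary(breakdowns, config$mix_weights)
  mix_csv <- file.path(config$output_dir, "severity_mix.csv")
  readr::write_csv(mix, mix_csv, progress = FALSE)
  write_manifest(config, config_path, c(files, mix_csv))
  invisible(breakdowns)
}

#' Severity-mix weighted daily cost summary
#'
#' @param breakdowns List of `cost_breakdown`s.
#' @param w A [mix_weights()].
#' @return A tibble with one row per country x care level where both
#'   severe and critical breakdowns exist: the weighted daily cost and its
#'   whole-dollar headline rounding.
#' @export
severity_mix_summary <- function(breakdowns, w = mix_weights()) {
  keys <- unique(t(vapply(breakdowns, function(b)
    c(b$country, b$care_level), character(2))))
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    find <- function(sv) {
      hit <- Filter(function(b) b$country == keys[i, 1] &&
                      b$care_level == keys[i, 2] && b$severity == sv,
                    breakdowns)
      if (length(hit) == 1) hit[[1]]$total_usd_per_day else NA_real_
    }
    sev <- find("severe"); crit <- find("critical")
    if (is.na(sev) || is.na(crit)) next
    wd <- weighted_daily_cost(sev, crit, w)
    rows[[length(rows) + 1]] <- tibble::tibble(
      country = keys[i, 1], care_level = keys[i, 2],
      severe_usd = sev, critical_usd = crit,
      weighted_usd_per_day = wd,
      headline_usd = round_half_up(wd, 0))
  }
  dplyr::bind_rows(rows)
}

#' Run the probabilistic sensitivity analysis report
#'
#' Builds scenario bounds for every breakdown, runs the gamma Monte Carlo,
#' and writes a summary table in the published `mean (low-high)` style with
#' the seed and draw count recorded.
#'
#' @inheritParams run_costing
#' @return Invisibly, a tibble of PSA summaries.
#' @export
run_psa_report <- function(config = default_run_config(),
                           config_path = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  breakdowns <- config_breakdowns(config)
  salaries <- config_salaries(config)
  rows <- lapply(breakdowns, function(b) {
    bounds <- build_bounds(b, config_spec(config, b), salaries,
                           config$context)
    res <- run_psa(bounds, config$context)
    tibble::tibble(country = b$country, care_level = b$care_level,
                   severity = b$severity,
                   reference_usd = b$total_usd_per_day,
                   mean_usd = res$mean_usd, ci_low_usd = res$ci_low_usd,
                   ci_high_usd = res$ci_high_usd,
                   summary = format_psa(res),
                   draws = res$draws, seed = res$seed)
  })
  tbl <- dplyr::bind_rows(rows)
  out <- file.path(config$output_dir, "psa.csv")
  readr::write_csv(tbl, out, progress = FALSE)
  write_manifest(config, config_path, out)
  invisible(tbl)
}

#' Run the scenario-range report
#'
#' Writes the low/reference/high daily totals per patient group implied by
#' the staffing, oxygen and (advanced care) pharmaceutical scenarios.
#'
#' @inheritParams run_costing
#' @return Invisibly, a tibble of scenario ranges.
#' @export
run_scenario_report <- function(config = default_run_config(),
                                config_path = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  breakdowns <- config_breakdowns(config)
  salaries <- config_salaries(config)
  rows <- lapply(breakdowns, function(b) {
    bounds <- build_bounds(b, config_spec(config, b), salaries,
                           config$context)
    rng <- scenario_range(bounds)
    tibble::tibble(country = b$country, care_level = b$care_level,
                   severity = b$severity,
                   low_usd = rng[["low"]], reference_usd = rng[["reference"]],
                   high_usd = rng[["high"]])
  })
  tbl <- dplyr::bind_rows(rows)
  out <- file.path(config$output_dir, "scenario_ranges.csv")
  readr::write_csv(tbl, out, progress = FALSE)
  write_manifest(config, config_path, out)
  invisible(tbl)
}

#' @keywords internal
write_manifest <- function(config, config_path, outputs) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("eecccost")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_path = config_path,
    config_md5 = if (!is.null(config_path) && file.exists(config_path))
      unname(tools::md5sum(config_path)) else NA_character_,
    model = config$model,
    seed = config$context$seed,
    psa_draws = config$context$psa_draws,
    outputs = as.list(basename(outputs))
  )
  yaml::write_yaml(manifest,
                   file.path(config$output_dir, "run_manifest.yaml"))
  invisible(manifest)
}
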