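# eecccost

Ingredients-based costing of **Essential Emergency and Critical Care (EECC)**
and **Advanced Critical Care (ACC)** per patient-day and per hospital
admission, for two East African country contexts (Tanzania and Kenya).

EECC is the low-cost, first-tier package of identification and treatment of
critical illness feasible in low-resource hospitals; ACC adds
resource-intensive organ support (e.g. mechanical ventilation) typical of an
ICU. The package implements a *normative, incremental* costing model: the
cost of the resources required to deliver the defined standard of care over
and above existing hospital care, built bottom-up as
Σ (quantity × unit price) over an itemized resource list, stratified by
patient severity (moderate / severe / critical).

## What the package provides

- **Domain types and CSV I/O** — validated resource-use tables, price books
  and salary schedules (`resource_table()`, `pricebook()`,
  `salary_schedule()`, `read_*()`/`write_*()`), with cross-validation of
  item/price coverage (`validate_model()`).
- **Valuation** — currency conversion at fixed study exchange rates
  (2300 TZS and 115 KES per USD), a 17.4% transport/insurance uplift on
  goods, capital annualization at a 3% discount rate via the annuity factor
  `(1 − (1 + r)^−L) / r`, and staff-time costing from annual salaries
  (`costing_context()`, `value_lines()`).
- **Oxygen supply-cost model** — a transparent cost-per-litre model
  (annualized equipment capital + recurrent spend + cylinder refills, divided
  by annual litres delivered) combined with severity-specific flow/duration
  profiles (`oxygen_scenario()`, `cost_per_litre()`,
  `oxygen_cost_per_patient_day()`).
- **Aggregation** — per-category USD/patient-day breakdowns with jointly
  rounded percentage shares that always sum to 100 ± 0.5
  (`cost_per_patient_day()`, `cost_breakdown()`).
- **Scenarios and PSA** — low/reference/high scenario bounds (±25% oxygen
  and, for ACC, pharmaceuticals; salary-band staffing substitution) feeding a
  per-category gamma Monte Carlo probabilistic sensitivity analysis with
  reproducible seeding (`build_bounds()`, `run_psa()`).
- **Admissions and severity mix** — length-of-stay conversion to per-stay
  costs and 0.74/0.26 severe/critical mix weighting into one headline daily
  cost (`cost_per_admission()`, `weighted_daily_cost()`).
- **Synthetic data generator** — item-level models calibrated so that
  costing them recovers the reference category totals exactly, for testing
  and demonstration (`generate_model()`).
- **Reporting** — YAML-configured runs writing publication-style cost
  tables, PSA and scenario-range CSVs plus a run manifest
  (`run_costing()`, `run_psa_report()`, `run_scenario_report()`), and a
  command-line wrapper in `inst/cli/eecccost.R`.
- **Reference fixture** — the category-level per-day reference costs for
  both countries ship in `inst/extdata/` and are exposed via
  `reference_costs()` / `reference_breakdown()`.

## Worked example

```r
library(eecccost)

# Reference cost of one severe-patient day of EECC in Tanzania
b <- reference_breakdown("TZ", "severe")
b
#> Cost per patient-day: TZ / severe / EECC
#>   Hotel costs (accommodation + overheads)             0.01  0.1%
#>   Staffing costs                                      3.35  31%
#>   Oxygen provision                                    4.74  44%
#>   Pharmaceuticals (Medicines etc.)                    1.70  16%
#>   Non-pharmaceutical costs (capital)                  0.13  1%
#>   Non-pharmaceutical costs (fluids, devices etc.)     0.66  6%
#>   Personal protective equipment (PPE)                 0.24  2%
#>   Support services (diagnostics)                      0.00  0%
#>   Total                                              10.83

# Per admission (8-day stay) and headline severity-mix figure
cost_per_admission(b$total_usd_per_day, 8)
#> [1] 86.64
weighted_daily_cost(10.83, 32.84, mix_weights(0.74, 0.26))  # ~17 USD/day
#> [1] 16.5526

# Probabilistic sensitivity analysis around the reference breakdown
bounds <- build_bounds(b, reference_scenario_spec("TZ", "severe"))
format_psa(run_psa(bounds, costing_context(seed = 1)))
#> [1] "10.67 (7.23–18.15)"

# Synthetic item-level model that recovers the same totals
m <- generate_model(generator_config(seed = 1, country = "TZ"))
model_breakdowns(m)[["TZ_EECC_severe"]]$total_usd_per_day
#> [1] 10.83
```

A full report run from a YAML configuration:

```r
cfg <- default_run_config()
cfg$output_dir <- "results"
run_costing(cfg)        # costs_EECC.csv/.txt, costs_ACC.csv/.txt,
                        # severity_mix.csv, run_manifest.yaml
run_psa_report(cfg)     # psa.csv
run_scenario_report(cfg)  # scenario_ranges.csv
```

Or from the command line:

```sh
Rscript inst/cli/eecccost.R cost --out results
Rscript inst/cli/eecccost.R psa --seed 1 --out results
```

## Documentation

See the methods vignette (`vignettes/costing-methods.Rmd`) for the model
structure, parameter defaults, the gamma parameterization of the PSA, the
share-rounding scheme, and known limitations.
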