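---
title: "Costing methods: ingredients-based EECC and ACC unit costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing methods: ingredients-based EECC and ACC unit costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eecccost)
```

## The model

`eecccost` estimates what it would cost, per patient-day and per hospital
admission, to deliver **Essential Emergency and Critical Care (EECC)** — the
low-cost first-tier package of identification and treatment of critical
illness — and **Advanced Critical Care (ACC)**, which adds resource-intensive
organ support, in Tanzanian and Kenyan district/regional hospitals.

The costing is *normative* and *incremental*: it values the resources a
defined standard of care requires over and above existing hospital care,
rather than observed expenditure. It is *ingredients-based*: a patient-day
cost is the sum over an itemized resource list of quantity × valued unit
price, stratified by patient severity (moderate, severe, critical). Resource
lines are tagged with a cost category (hotel, staffing, oxygen,
pharmaceuticals, capital and recurrent non-pharmaceuticals, PPE,
diagnostics), a care stream (identification of critical illness vs.
treatment), and an applicability level (EECC, ACC, or both): an EECC
breakdown excludes ACC-only lines, while ACC includes everything.

Moderate patients are costed for identification (monitoring) only — their
oxygen, pharmaceutical and fluid quantities are zero by construction — and
no ACC cost is defined for them.

## Valuation rules and parameter defaults

All valuation parameters live in one `costing_context()`:

| Parameter | Default | Role |
|---|---|---|
| `fx_tzs_per_usd` | 2300 | Study exchange rate, Tanzanian shilling |
| `fx_kes_per_usd` | 115 | Study exchange rate, Kenyan shilling |
| `discount_rate` | 0.03 | Capital annualization |
| `uplift_rate` | 0.174 | Transport/insurance uplift on goods prices |
| `working_minutes_per_year` | 108000 | Staff-time denominator |
| `psa_draws`, `seed` | 1000, 1 | Monte Carlo controls |

Three valuation rules map a resource line to a daily USD cost:

- **Recurrent goods**: quantity × uplifted USD price. The 17.4% uplift
  covers shipping and insurance excluded from quoted prices.
- **Capital goods**: the uplifted price is spread over the useful life `L`
  as an equivalent annual cost using the annuity factor
  `AF(r, L) = (1 − (1 + r)^−L) / r` at a 3% rate (with `AF = L` at a zero
  rate), then divided by 365 and multiplied by the per-day quantity
  (e.g. the share of a monitor a patient occupies).
- **Staff time**: minutes per patient-day × (annual salary in USD /
  annual working minutes). Salaries carry no uplift.

`annuity_factor()` is tested against an independent oracle
`sum((1 + r)^-(1:L))` to 1e-9 over rates 0, 0.01, 0.03 and 0.1 and lives
1–20 years.

## The oxygen supply-cost model

Oxygen is the single largest EECC cost driver, so it gets its own
sub-model. A supply scenario (`oxygen_scenario()`) describes a hospital
oxygen system: capital components (concentrators, piping) annualized as
above, recurrent spend (power, maintenance), and cylinder refills. Its cost
per litre is total annual cost divided by annual litres delivered, where
litres default to beds × occupancy × mean flow × minutes per year.

A patient's daily oxygen cost is flow (L/min) × 60 × hours/day × cost per
litre. The default profiles are 0 L/min for moderate patients, 5 L/min ×
24 h for severe, 20.75 L/min × 24 h for critical EECC, and 40 L/min × 24 h
for critical ACC (a high-flow ICU scenario). With the default
district-concentrator and ICU scenarios these yield 4.74, 19.67 and 36.17
USD/day respectively — the values embedded in the reference table.

```{r oxygen}
p <- cost_per_litre(default_oxygen_scenarios()$district_concentrator)
round(oxygen_cost_per_patient_day(default_oxygen_profiles("EECC")$severe, p), 2)
```

## Aggregation and share rounding

`cost_breakdown()` holds per-category USD/day, the total, and percentage
shares at two precisions. Reported shares use mixed precision — whole
percent at or above 1%, one decimal below — and are rounded *jointly* by a
largest-remainder step so that the printed column always sums to
100 ± 0.5. This reproduces every published share (e.g. oxygen 60% of the
Tanzanian critical EECC day; staffing 85% and PPE 12% of the moderate day)
while keeping the column internally consistent.

## Scenario analysis

`scenario_spec()` + `build_bounds()` produce a low/reference/high bound per
category:

- oxygen always varies by an indicative ±25%;
- pharmaceuticals vary by ±25% for ACC only (`vary_pharma`);
- staffing either stays at reference, is re-valued by **salary-band
  substitution** (`"banded"`: rescale the reference staffing cost by the
  ratio of the low-band and high-band salary rates to the reference band —
  i.e. task-shift to the cheapest cadre vs. employ the highest grades), or
  is set by explicit per-category `overrides`.

The reference scenario specifications use banded substitution where the
salary schedule reproduces the published ranges exactly (e.g. the Tanzanian
moderate day spans 0.36–2.28 USD) and explicit overrides for cells whose
published bounds are not a single salary ratio. Bounds must satisfy
`low ≤ reference ≤ high`; violations are an error, not silently clamped.

## Probabilistic sensitivity analysis

Each category's uncertainty is an independent gamma distribution fitted by
method of moments: mean = reference, sd = (high − low)/3.92 (the bounds are
read as a 95% interval), so shape = (mean/sd)² and scale = sd²/mean. A
degenerate category (low = high) is a point mass. The daily-total
distribution is the Monte Carlo sum of the per-category draws; the interval
is the empirical 2.5%/97.5% quantile.

The gamma parameterization is a *modelling decision*: published Monte Carlo
means from comparable analyses are not reproducible to the cent without the
original parameterization, so the tests assert distributional properties
instead — degenerate bounds return the point estimate exactly, the sample
mean at 10,000 draws falls within two standard errors of the analytic mean,
intervals bracket the mean, and identical seeds give identical output.
Reproducibility is per-category: each category's stream is seeded by the
root seed plus a hash of the category name, so adding a category does not
perturb the draws of the others.

```{r psa}
b <- reference_breakdown("TZ", "severe")
format_psa(run_psa(build_bounds(b, reference_scenario_spec("TZ", "severe"))))
```

## Admissions, length of stay and the severity mix

Per-admission cost is daily cost × length of stay. The default
length-of-stay table uses 3 days (moderate), 8 days (severe) and 8/14 days
(critical, Tanzania/Kenya) for EECC; the Kenyan ACC critical stay of 14.8
days is derived by dividing the published per-stay cost by the daily cost.
A single headline daily cost of critical illness care weights the severe
and critical days 0.74/0.26, giving 17 USD (Tanzania) and 21 USD (Kenya)
after whole-dollar rounding.

## The synthetic generator

`generate_model()` emits an item-level model (resource table, price book,
salary schedule) whose *costed* category totals recover the reference
table exactly: item quantities are calibrated as
`quantity = weight × target / unit-cost factor`, where the factor applies
the same valuation rule the costing engine will apply. Price noise is
lognormal around the calibrated values with compensating quantities, so the
product is invariant. Kenyan salaries are the Tanzanian anchors times a
2.2 premium with a log-uniform spread strictly below `log(2.2)`,
guaranteeing cadre-by-cadre dominance. The generator emulates *structure*
(category mix, severity gradients, EECC ⊆ ACC, moderate zeros), not
real-world item lists; it exists for testing and demonstration.

Typical problem sizes are small — tens of resource lines, eight categories,
five patient-day cells per country — so everything runs in well under a
second except the Monte Carlo (linear in draws) and multi-seed generator
sweeps.

## Limitations

- The model is normative: it costs a defined care standard, not observed
  practice, and excludes building construction, training and programme
  management above the hospital level.
- Exchange rates, the uplift, the discount rate and the oxygen scenarios
  are fixed study parameters; sensitivity to them must be explored through
  the scenario machinery, not re-estimated.
- The gamma PSA treats categories as independent; correlated input
  uncertainty (e.g. salaries moving together across cadres) is out of
  scope.
- The reference fixture is category-level; item-level reconstruction
  (the synthetic generator) is calibrated, not estimated.
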