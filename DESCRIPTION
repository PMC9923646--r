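Package: eecccost
Title: Ingredients-Based Costing of Essential Emergency and Critical Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normative, incremental, ingredients-based costing of Essential
    Emergency and Critical Care (EECC) and Advanced Critical Care (ACC) per
    patient-day and per hospital admission, for two East African country
    contexts (Tanzania and Kenya). Provides domain types and CSV input/output
    for resource-use tables, price books and salary schedules; valuation
    (currency conversion, transport and insurance uplift, capital
    annualization at a fixed discount rate, staff-time costing); a
    transparent oxygen supply-cost model (annualized capital plus recurrent
    and cylinder-refill spend per litre delivered); aggregation into
    per-category cost breakdowns with percentage shares; scenario bounds and
    a gamma-distribution Monte Carlo probabilistic sensitivity analysis;
    length-of-stay and severity-mix summaries; a synthetic-data generator;
    and a category-level reference cost table for both countries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
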