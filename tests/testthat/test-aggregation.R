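test_that("category sums, totals and shares reproduce the reference severe column", {
  b <- cost_breakdown(c(hotel = 0.01, staffing = 3.35, oxygen = 4.74,
                        pharmaceuticals = 1.70, nonpharma_capital = 0.13,
                        nonpharma_recurrent = 0.66, ppe = 0.24),
                      "TZ", "severe", "EECC")
  expect_equal(b$total_usd_per_day, 10.83)
  expect_equal(sum(b$per_category_usd), b$total_usd_per_day,
               tolerance = 1e-9)
  expect_equal(sum(b$shares_pct), 100, tolerance = 1e-9)
})

test_that("an empty line list gives a zero total and no shares", {
  empty <- tibble::tibble(item_id = character(), category = character(),
                          severity = character(),
                          usd_per_patient_day = numeric())
  b <- cost_per_patient_day(empty, "TZ", "moderate", "EECC")
  expect_equal(b$total_usd_per_day, 0)
  expect_length(b$shares_pct, 0)
  expect_error(category_share(b, "staffing"), "zero total")
})

test_that("mixed-country line sets are rejected", {
  lines <- tibble::tibble(item_id = c("a", "b"), category = "ppe",
                          severity = "severe", country = c("TZ", "KE"),
                          usd_per_patient_day = c(1, 2))
  expect_error(cost_per_patient_day(lines, "TZ", "severe", "EECC"),
               "mix countries")
})

test_that("rounded shares match the printed percentages", {
  expect_equal(category_share(reference_breakdown("TZ", "critical"), "oxygen"), 60)
  expect_equal(category_share(reference_breakdown("KE", "severe"), "staffing"), 54)
  expect_equal(category_share(reference_breakdown("TZ", "moderate"), "staffing"), 85)
  expect_equal(category_share(reference_breakdown("TZ", "moderate"), "ppe"), 12)
  expect_equal(category_share(reference_breakdown("TZ", "severe", "ACC"), "staffing"), 43)
  single <- cost_breakdown(c(staffing = 5), "TZ", "moderate", "EECC")
  expect_equal(category_share(single, "staffing"), 100)
})

test_that("shares are scale invariant and ignore zero-cost lines", {
  per_cat <- c(staffing = 3.35, oxygen = 4.74, ppe = 0.24)
  b1 <- cost_breakdown(per_cat, "TZ", "severe", "EECC")
  b2 <- cost_breakdown(per_cat * 7, "TZ", "severe", "EECC")
  expect_equal(b1$shares_pct, b2$shares_pct)

  lines <- tibble::tibble(
    item_id = c("a", "b"), category = c("staffing", "oxygen"),
    severity = "severe", usd_per_patient_day = c(3.35, 4.74))
  with_zero <- dplyr::bind_rows(lines, tibble::tibble(
    item_id = "z", category = "pharmaceuticals", severity = "severe",
    usd_per_patient_day = 0))
  b1 <- cost_per_patient_day(lines, "TZ", "severe", "EECC")
  b2 <- cost_per_patient_day(with_zero, "TZ", "severe", "EECC")
  expect_equal(b1$per_category_usd, b2$per_category_usd)
  expect_equal(b1$shares_rounded, b2$shares_rounded)
})

test_that("rounded shares sum to 100 within 0.5", {
  for (b in reference_breakdowns()) {
    expect_lt(abs(sum(b$shares_rounded) - 100), 0.5 + 1e-9)
  }
})

test_that("advanced over essential cost ratios match hand-divided figures", {
  eecc <- reference_breakdown("TZ", "severe", "EECC")
  acc <- reference_breakdown("TZ", "severe", "ACC")
  cmp <- compare_levels(eecc, acc)
  expect_equal(round_half_up(cmp$ratio), 1.21)
  expect_equal(cmp$per_category_delta[["staffing"]], 5.63 - 3.35)

  # published advanced critical mean over essential critical total
  expect_equal(round_half_up(293.77 / 32.84), 8.95)

  expect_equal(compare_levels(eecc, eecc)$ratio, 1)
  swapped <- reference_breakdown("TZ", "critical", "EECC")
  expect_error(compare_levels(eecc, swapped), "country and severity")
  zero <- cost_per_patient_day(
    tibble::tibble(item_id = character(), category = character(),
                   severity = character(), usd_per_patient_day = numeric()),
    "TZ", "severe", "EECC")
  expect_error(compare_levels(zero, acc), "positive")
})

test_that("the hotel row can be excluded for the strict incremental total", {
  b <- reference_breakdown("TZ", "severe")
  expect_equal(total_excluding_hotel(b), 10.82)
})

test_that("breakdown tables list all categories plus a total row", {
  tbl <- breakdown_table(reference_breakdown("TZ", "severe"))
  expect_equal(nrow(tbl), length(cost_categories()) + 1)
  expect_equal(tbl$usd_per_day[tbl$category == "total"], 10.83)
})
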