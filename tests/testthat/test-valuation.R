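ctx <- costing_context()

test_that("currency conversion matches the 2020 exchange rates", {
  expect_equal(convert_to_usd(2300, "TZS", ctx), 1)
  expect_equal(convert_to_usd(115, "KES", ctx), 1)
  expect_equal(convert_to_usd(42.5, "USD", ctx), 42.5)
  expect_equal(convert_to_usd(0, "TZS", ctx), 0)
  expect_error(convert_to_usd(10, "EUR", ctx), "currency")
  expect_error(convert_to_usd(-1, "USD", ctx), "non-negative")
})

test_that("the transport and insurance uplift is 17.4% and only applied when flagged", {
  expect_equal(apply_uplift(100, ctx), 117.40)
  expect_equal(apply_uplift(100, ctx, needs_uplift = FALSE), 100)
  expect_equal(apply_uplift(0, ctx), 0)
  no_uplift <- costing_context(transport_uplift = 0)
  expect_equal(apply_uplift(57.3, no_uplift), 57.3)
  expect_error(apply_uplift(-5, ctx), "non-negative")
})

test_that("capital annualization matches the independent discounted-sum oracle", {
  for (r in c(0, 0.01, 0.03, 0.1)) {
    for (life in 1:20) {
      expect_equal(annuity_factor(r, life), af_oracle(r, life),
                   tolerance = 1e-12)
      expect_equal(annualize_capital(1000, life, r),
                   1000 / af_oracle(r, life), tolerance = 1e-9)
    }
  }
  expect_equal(round_half_up(annualize_capital(1000, 5, 0.03)), 218.35)
  expect_equal(annualize_capital(1000, 5, 0), 200)
  expect_equal(annualize_capital(1000, 1, 0.03), 1030)
  expect_error(annualize_capital(1000, 0, 0.03), "positive")
})

test_that("the annuity factor approaches the useful life from below as the rate vanishes", {
  life <- 7
  rates <- 10^seq(-1, -8)
  af <- annuity_factor(rates, rep(life, length(rates)))
  expect_true(all(af < life))
  expect_true(all(diff(abs(af - life)) < 0))
  expect_lt(abs(annuity_factor(1e-8, life) - life), 1e-5)
})

test_that("staff time is valued from annual salary and working minutes", {
  ctx120 <- costing_context(working_minutes_per_year = 120000)
  expect_equal(staff_cost_per_patient_day(12000, "USD", 60, ctx120), 6)
  expect_equal(staff_cost_per_patient_day(12000, "USD", 0, ctx120), 0)
  expect_equal(staff_cost_per_patient_day(12000, "USD", 120, ctx120),
               2 * staff_cost_per_patient_day(12000, "USD", 60, ctx120))
  expect_error(staff_cost_per_patient_day(12000, "USD", -1, ctx120),
               "non-negative")
})

test_that("line daily cost applies the valuation rule of each cost type", {
  line <- resource_table("swab", "swab", "ppe", "identification", "both",
                         1, 2, 3, "item")
  price <- pricebook("swab", 0.50, "USD", "recurrent")
  got <- line_daily_cost(line, price, "severe", ctx)
  expect_equal(got$usd_per_patient_day, 1)

  # capital item whose annualized cost is exactly 365 USD/yr -> 1 USD/day
  life <- 10
  price_for_365 <- 365 * annuity_factor(0.03, life)
  line <- resource_table("pump", "pump", "nonpharma_capital",
                         "identification", "both", 1, 1, 1, "device")
  price <- pricebook("pump", price_for_365, "USD", "capital",
                     useful_life_years = life)
  expect_equal(line_daily_cost(line, price, "moderate", ctx)$usd_per_patient_day,
               1, tolerance = 1e-12)

  # staff line: quantity read as minutes per day
  line <- resource_table("nurse", "nurse", "staffing", "identification",
                         "both", 30, 60, 90, "minutes")
  price <- pricebook("nurse", 10800000, "TZS", "staff_time")
  got <- line_daily_cost(line, price, "severe", ctx)
  expect_equal(got$usd_per_patient_day,
               (10800000 / 2300) * 60 / 108000)

  expect_error(line_daily_cost(line, pricebook("other", 1, "USD",
                                               "recurrent"), "severe", ctx),
               "does not match")
})

test_that("line daily cost is monotone in quantity, price and uplift, and in life", {
  base <- function(qty = 2, usd = 0.5, uplift = 0.174) {
    line <- resource_table("x", "x", "ppe", "identification", "both",
                           qty, qty, qty, "item")
    price <- pricebook("x", usd, "USD", "recurrent", needs_uplift = TRUE)
    line_daily_cost(line, price,
                    "severe", costing_context(transport_uplift = uplift))$usd_per_patient_day
  }
  expect_true(base(qty = 3) > base(qty = 2))
  expect_true(base(usd = 1) > base(usd = 0.5))
  expect_true(base(uplift = 0.3) > base(uplift = 0.174))

  annual <- vapply(1:15, function(life) annualize_capital(1000, life, 0.03),
                   numeric(1))
  expect_true(all(diff(annual) < 0))
})

test_that("converting lines then summing equals summing then converting in one currency", {
  amounts <- c(230, 4600, 11.5, 0)
  lhs <- sum(convert_to_usd(amounts, "TZS", ctx))
  rhs <- convert_to_usd(sum(amounts), "TZS", ctx)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})
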