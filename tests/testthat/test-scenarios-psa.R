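ctx <- costing_context()

test_that("oxygen bounds are the reference times the multiplier pair", {
  b <- reference_breakdown("TZ", "severe")
  bounds <- build_bounds(b, reference_scenario_spec("TZ", "severe"))
  oxy <- bounds[bounds$category == "oxygen", ]
  expect_equal(c(oxy$low, oxy$reference, oxy$high), c(3.555, 4.74, 5.925))
})

test_that("an all-reference specification yields fully degenerate bounds", {
  b <- reference_breakdown("TZ", "severe")
  spec <- scenario_spec(oxygen_multipliers = c(1, 1),
                        staffing_mode = "reference")
  bounds <- build_bounds(b, spec)
  expect_equal(bounds$low, bounds$reference)
  expect_equal(bounds$high, bounds$reference)
})

test_that("banded staffing re-valuation reproduces the moderate-patient cost range", {
  b <- reference_breakdown("TZ", "moderate")
  bounds <- build_bounds(b, reference_scenario_spec("TZ", "moderate"),
                         reference_salary_schedule(), ctx)
  rng <- scenario_range(bounds)
  expect_equal(round_half_up(rng[["low"]]), 0.36)
  expect_equal(round_half_up(rng[["high"]]), 2.28)
  expect_equal(rng[["reference"]], 1.01)
})

test_that("banded staffing requires a salary schedule with the needed bands", {
  b <- reference_breakdown("TZ", "moderate")
  spec <- scenario_spec(staffing_mode = "banded")
  expect_error(build_bounds(b, spec), "salary schedule")
  partial <- reference_salary_schedule()
  partial <- partial[partial$band != "high", ]
  expect_error(build_bounds(b, spec, partial, ctx), "band 'high'")
})

test_that("every scenario grid cell satisfies low <= reference <= high", {
  for (b in reference_breakdowns()) {
    bounds <- build_bounds(b, reference_scenario_spec(b$country, b$severity,
                                                      b$care_level),
                           reference_salary_schedule(), ctx)
    expect_true(all(bounds$low <= bounds$reference + 1e-9))
    expect_true(all(bounds$reference <= bounds$high + 1e-9))
  }
})

test_that("gamma moment fitting matches hand-computed shape and scale", {
  fit <- fit_gamma(4, 4 - 1.96 * 2, 4 + 1.96 * 2)
  expect_equal(fit$shape, 4)
  expect_equal(fit$scale, 1)

  fit <- fit_gamma(4.74, 3.555, 5.925)
  expect_equal(round_half_up(fit$shape), 61.47)
  expect_equal(round_half_up(fit$scale, 4), 0.0771)

  fit <- fit_gamma(5, 5, 5)
  expect_true(fit$point_mass)
  expect_equal(fit$value, 5)

  expect_error(fit_gamma(4, 5, 6), "low <= reference")
})

test_that("degenerate bounds give the point estimate exactly with zero width", {
  b <- reference_breakdown("TZ", "severe")
  spec <- scenario_spec(oxygen_multipliers = c(1, 1),
                        staffing_mode = "reference")
  res <- run_psa(build_bounds(b, spec), ctx)
  expect_identical(res$mean_usd, b$total_usd_per_day)
  expect_identical(res$ci_low_usd, res$ci_high_usd)
})

test_that("identical seed and inputs give identical PSA output", {
  b <- reference_breakdown("TZ", "severe")
  bounds <- build_bounds(b, reference_scenario_spec("TZ", "severe"))
  r1 <- run_psa(bounds, ctx, keep_draws = TRUE)
  r2 <- run_psa(bounds, ctx, keep_draws = TRUE)
  expect_identical(r1$totals, r2$totals)
  r3 <- run_psa(bounds, costing_context(seed = 99))
  expect_false(identical(r1$mean_usd, r3$mean_usd))
})

test_that("PSA intervals bracket the mean and scale with the bounds", {
  b <- reference_breakdown("TZ", "severe")
  bounds <- build_bounds(b, reference_scenario_spec("TZ", "severe"))
  res <- run_psa(bounds, ctx)
  expect_lte(res$ci_low_usd, res$mean_usd)
  expect_gte(res$ci_high_usd, res$mean_usd)

  doubled <- bounds
  doubled$low <- 2 * bounds$low
  doubled$reference <- 2 * bounds$reference
  doubled$high <- 2 * bounds$high
  res2 <- run_psa(doubled, ctx)
  expect_equal(res2$mean_usd, 2 * res$mean_usd)
  expect_equal(res2$ci_low_usd, 2 * res$ci_low_usd)
  expect_equal(res2$ci_high_usd, 2 * res$ci_high_usd)
})

test_that("the Monte Carlo mean converges to the analytic category-sum mean", {
  b <- reference_breakdown("TZ", "severe")
  bounds <- build_bounds(b, reference_scenario_spec("TZ", "severe"))
  sds <- (bounds$high - bounds$low) / 3.92
  n <- 10000
  se <- sqrt(sum(sds^2) / n)
  res <- run_psa(bounds, costing_context(psa_draws = n, seed = 1))
  expect_lt(abs(res$mean_usd - sum(bounds$reference)), 2 * se)
  # error shrinks roughly as 1/sqrt(n)
  errs <- vapply(1:20, function(s) {
    big <- run_psa(bounds, costing_context(psa_draws = n, seed = s))
    small <- run_psa(bounds, costing_context(psa_draws = 100, seed = s))
    c(abs(big$mean_usd - sum(bounds$reference)),
      abs(small$mean_usd - sum(bounds$reference)))
  }, numeric(2))
  expect_lt(mean(errs[1, ]), mean(errs[2, ]))
})

test_that("single-gamma empirical quantiles agree with the closed-form gamma quantiles", {
  ref <- 4.74
  bounds <- build_bounds(
    cost_breakdown(c(oxygen = ref), "TZ", "severe", "EECC"),
    scenario_spec(staffing_mode = "reference"))
  fit <- fit_gamma(4.74, 3.555, 5.925)
  n <- 10000
  res <- run_psa(bounds, costing_context(psa_draws = n, seed = 3))
  expect_lt(abs(res$ci_low_usd -
                  qgamma(0.025, shape = fit$shape, scale = fit$scale)), 0.1)
  expect_lt(abs(res$ci_high_usd -
                  qgamma(0.975, shape = fit$shape, scale = fit$scale)), 0.1)
})
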