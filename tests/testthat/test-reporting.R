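test_that("run configurations round-trip through write and read", {
  cfg <- default_run_config()
  cfg$context <- costing_context(seed = 42L, psa_draws = 500L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(back$model, cfg$model)
  expect_equal(back$context$seed, 42L)
  expect_equal(back$context$psa_draws, 500L)
  expect_equal(back$mix_weights$w_severe, 0.74)
})

test_that("malformed configurations fail naming the offending key", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("modle: reference", path)
  expect_error(read_run_config(path), "modle")
  writeLines(c("model: files", "pricebook: /nonexistent.csv"), path)
  expect_error(read_run_config(path), "resources")
})

test_that("the costing report reproduces the reference totals and re-parses at 2 dp", {
  out <- withr::local_tempdir()
  cfg <- default_run_config()
  cfg$output_dir <- out
  breakdowns <- run_costing(cfg)
  tbl <- readr::read_csv(file.path(out, "costs_EECC.csv"),
                         show_col_types = FALSE)
  total_row <- tbl[tbl$row == "Patient cost/day (USD)", ]
  expect_equal(total_row$TZ_severe_usd, 10.83)
  expect_equal(total_row$KE_critical_usd, 37.44)
  stay_row <- tbl[grepl("per stay", tbl$row), ]
  expect_equal(stay_row$TZ_severe_usd, 86.64)
  # every reported category cell re-parses to the breakdown value at 2 dp
  b <- breakdowns[["TZ_EECC_severe"]]
  cats <- unname(cost_category_labels())
  expect_equal(tbl$TZ_severe_usd[match(cats, tbl$row)],
               unname(round_half_up(b$per_category_usd, 2)))
  expect_true(file.exists(file.path(out, "run_manifest.yaml")))
  expect_true(file.exists(file.path(out, "severity_mix.csv")))
  mix <- readr::read_csv(file.path(out, "severity_mix.csv"),
                         show_col_types = FALSE)
  expect_equal(mix$headline_usd[mix$country == "TZ" &
                                  mix$care_level == "EECC"], 17)
  expect_equal(mix$headline_usd[mix$country == "KE" &
                                  mix$care_level == "EECC"], 21)
})

test_that("an empty resource table yields a zero table and a warning", {
  out <- withr::local_tempdir()
  resources <- tiny_resources()[0, ]
  prices <- tiny_pricebook()
  res_path <- file.path(out, "resources.csv")
  prc_path <- file.path(out, "pricebook.csv")
  write_resource_table(resources, res_path)
  write_pricebook(prices, prc_path)
  path <- file.path(out, "config.yaml")
  yaml::write_yaml(list(model = "files", countries = list("TZ"),
                        resources = res_path, pricebook = prc_path,
                        output_dir = out), path)
  cfg <- read_run_config(path)
  expect_warning(run_costing(cfg, path), "zero")
  tbl <- readr::read_csv(file.path(out, "costs_EECC.csv"),
                         show_col_types = FALSE)
  expect_true(all(tbl$TZ_severe_usd == 0))
})

test_that("PSA reports are reproducible for a fixed seed and contain the reference", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- default_run_config()
  cfg$countries <- "TZ"
  cfg$output_dir <- out1
  t1 <- run_psa_report(cfg)
  cfg$output_dir <- out2
  t2 <- run_psa_report(cfg)
  expect_identical(readLines(file.path(out1, "psa.csv")),
                   readLines(file.path(out2, "psa.csv")))
  sev <- t1[t1$severity == "severe" & t1$care_level == "EECC", ]
  expect_lte(sev$ci_low_usd, sev$reference_usd)
  expect_gte(sev$ci_high_usd, sev$reference_usd)
  expect_equal(sev$draws, 1000L)
})

test_that("degenerate bounds make the PSA table equal the point estimates", {
  b <- reference_breakdown("TZ", "severe")
  spec <- scenario_spec(oxygen_multipliers = c(1, 1),
                        staffing_mode = "reference")
  res <- run_psa(build_bounds(b, spec))
  expect_identical(format_psa(res), "10.83 (10.83–10.83)")
})

test_that("the scenario-range report brackets the reference everywhere", {
  out <- withr::local_tempdir()
  cfg <- default_run_config()
  cfg$output_dir <- out
  tbl <- run_scenario_report(cfg)
  expect_true(all(tbl$low_usd <= tbl$reference_usd + 1e-9))
  expect_true(all(tbl$reference_usd <= tbl$high_usd + 1e-9))
  mod <- tbl[tbl$country == "TZ" & tbl$severity == "moderate", ]
  expect_equal(round_half_up(mod$low_usd), 0.36)
  expect_equal(round_half_up(mod$high_usd), 2.28)
})
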