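test_that("a well-formed resource table parses to the same rows it was written from", {
  path <- withr::local_tempfile(fileext = ".csv")
  resources <- tiny_resources()
  write_resource_table(resources, path)
  parsed <- read_resource_table(path)
  expect_equal(nrow(parsed), 3)
  expect_equal(as.data.frame(parsed), as.data.frame(resources))
})

test_that("canonical CSV round-trips byte-identically through write(read(x))", {
  path1 <- withr::local_tempfile(fileext = ".csv")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_resource_table(tiny_resources(), path1)
  write_resource_table(read_resource_table(path1), path2)
  expect_identical(readLines(path1), readLines(path2))

  pb1 <- withr::local_tempfile(fileext = ".csv")
  pb2 <- withr::local_tempfile(fileext = ".csv")
  write_pricebook(tiny_pricebook(), pb1)
  write_pricebook(read_pricebook(pb1), pb2)
  expect_identical(readLines(pb1), readLines(pb2))
})

test_that("schema and validation errors name the offending column, row or id", {
  resources <- tiny_resources()
  bad <- resources
  bad$category[1] <- "oxigen"
  expect_error(validate_resource_table(bad), "oxigen")
  expect_error(validate_resource_table(bad), "hotel")  # lists allowed values

  bad <- resources
  bad$qty_severe[2] <- -1
  expect_error(validate_resource_table(bad), "row 2")

  expect_error(validate_resource_table(resources[, -1]), "item_id")

  prices <- tiny_pricebook()
  dup <- dplyr::bind_rows(prices, prices[1, ])
  expect_error(validate_pricebook(dup), "glove")

  bad <- prices
  bad$useful_life_years[2] <- NA
  expect_error(validate_pricebook(bad), "useful_life_years")

  bad <- prices
  bad$useful_life_years[1] <- 3  # recurrent row must not carry a life
  expect_error(validate_pricebook(bad), "glove")
})

test_that("capital items round-trip their useful life unchanged", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_pricebook(tiny_pricebook(), path)
  parsed <- read_pricebook(path)
  expect_identical(parsed$useful_life_years[parsed$item_id == "monitor"], 5)
})

test_that("model cross-validation reports missing prices, unused prices and moderate treatment use", {
  resources <- tiny_resources()
  prices <- tiny_pricebook()
  expect_true(is_clean(validate_model(resources, prices)))

  report <- validate_model(resources, prices[-1, ])
  expect_identical(report$missing_price, "glove")

  extra <- dplyr::bind_rows(prices, pricebook("spare", 1, "USD", "recurrent"))
  expect_identical(validate_model(resources, extra)$unused_price, "spare")

  oxy <- dplyr::bind_rows(resources, resource_table(
    "oxygen", "oxygen", "oxygen", "treatment", "both", 1, 7200, 29880,
    "litres"))
  oxy_prices <- dplyr::bind_rows(prices, pricebook(
    "oxygen", 0.0007, "USD", "recurrent"))
  report <- validate_model(oxy, oxy_prices)
  expect_identical(report$moderate_treatment, "oxygen")
})

test_that("restricting to the essential level equals dropping advanced-only lines", {
  model <- generate_model(generator_config(seed = 11))
  ctx <- costing_context()
  manual <- model$resources[model$resources$applicability != "ACC", ]
  for (sev in c("severe", "critical")) {
    via_level <- value_lines(model$resources, model$prices, sev, "EECC", ctx)
    via_subset <- value_lines(manual, model$prices, sev, "ACC", ctx)
    expect_equal(sum(via_level$usd_per_patient_day),
                 sum(via_subset$usd_per_patient_day))
  }
})
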