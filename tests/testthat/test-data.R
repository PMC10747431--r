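test_that("constructors validate and canonicalize dose groups", {
  d <- quantal_data(c(150, 0, 75), c(50, 50, 50), c(37, 24, 35))
  expect_equal(d$dose, c(0, 75, 150))
  expect_equal(d$affected, c(24, 35, 37))

  expect_error(quantal_data(c(0, 75, 150), c(50, 50, 50), c(24, 51, 37)),
               "row 2")
  expect_error(quantal_data(c(0, 75, 75), c(50, 50, 50), c(1, 2, 3)),
               "Duplicate dose")
  expect_error(quantal_data(c(10, 75, 150), c(50, 50, 50), c(1, 2, 3)),
               "control")
  expect_error(quantal_data(c(0, -5, 150), c(50, 50, 50), c(1, 2, 3)),
               ">= 0")
  expect_error(quantal_data(c(0, 75), c(50, 50), c(1, 2)), "At least 3")

  expect_error(continuous_data(c(0, 150, 300), rep(10, 3),
                               c(352, 336, 326), c(8, 0, 6)),
               "sd")
  cd <- continuous_data(c(300, 0, 150), rep(10, 3),
                        c(326, 352, 336), c(6, 8, 7))
  expect_equal(cd$mean, c(352, 336, 326))
})

test_that("CSV and JSON serialization round-trip exactly", {
  d <- atrophy_female_data()  # includes the fractional dose 37.5
  path <- withr::local_tempfile(fileext = ".csv")
  write_dose_response(d, path)
  d2 <- read_quantal(path, label = endpoint_label(d))
  expect_identical(tibble::as_tibble(d), tibble::as_tibble(d2))

  cd <- body_weight_data()
  d3 <- dose_response_from_json(dose_response_json(cd))
  expect_identical(tibble::as_tibble(cd), tibble::as_tibble(d3))
  expect_identical(endpoint_label(d3), endpoint_label(cd))
})

test_that("readers honor column dialects and report missing columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(
    tibble::tibble(Dose = c(0, 75, 150), N = c(50, 50, 50),
                   Incidence = c(24, 35, 37)),
    path)
  d <- read_quantal(path, dialect = c(dose = "Dose", n = "N",
                                      affected = "Incidence"))
  expect_equal(d$affected, c(24, 35, 37))
  expect_error(read_quantal(path), "Missing column")
  expect_error(read_quantal(path, dialect = c(bogus = "x")), "Unknown dialect")
})

test_that("bundled endpoints load with the printed incidences", {
  d <- isoeugenol_endpoint("adenoma")
  expect_equal(d$affected / d$n, c(0.48, 0.70, 0.74, 0.66))
  atro <- isoeugenol_endpoint("olfactory_atrophy_female")
  expect_equal(nrow(atro), 6)
  expect_equal(atro$affected, c(0, 1, 2, 2, 5, 6))
  bw <- isoeugenol_endpoint("body_weight")
  expect_s3_class(bw, "continuous_data")
  expect_equal(bw$mean[c(1, 6)], c(352, 307))
})

test_that("dropping dose groups obeys the rules and composes", {
  comb <- combined_data()
  d <- drop_dose_groups(comb, 300)
  expect_equal(d$dose, c(0, 75, 150))
  expect_equal(d$affected, c(28, 43, 43))

  bw <- body_weight_data()
  expect_equal(drop_dose_groups(bw, c(37.5, 75))$dose, c(0, 150, 300, 600))

  expect_identical(drop_dose_groups(comb, numeric(0)), comb)
  expect_error(drop_dose_groups(comb, 0), "control")
  expect_error(drop_dose_groups(comb, 42), "not in the dataset")
  expect_error(drop_dose_groups(d, c(75, 150)), "At least 3")

  # composition: dropping in two steps equals dropping the union
  two_step <- drop_dose_groups(drop_dose_groups(bw, 37.5), c(75, 300))
  one_step <- drop_dose_groups(bw, c(37.5, 75, 300))
  expect_identical(tibble::as_tibble(two_step), tibble::as_tibble(one_step))
})

test_that("default configuration matches the standard settings", {
  cfg <- bmd_config()
  expect_equal(cfg$bmrf, 0.1)
  expect_equal(cfg$confidence, 0.95)
  expect_equal(cfg$risk_type, "extra_risk")
  expect_equal(cfg$distribution, "normal")
  expect_equal(cfg$variance, "constant")
  expect_error(bmd_config(bmrf = 1.2), "bmrf")
  expect_error(bmd_config(confidence = 0.4), "confidence")

  # degree rule: one less than the number of groups, capped at 3
  expect_equal(max_model_degree(adenoma_data()), 3L)
  expect_equal(max_model_degree(drop_dose_groups(combined_data(), 300)), 2L)
  expect_equal(max_model_degree(atrophy_female_data()), 3L)
})
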