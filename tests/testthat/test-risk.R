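test_that("ADI derivation divides the POD by the exact composite factor", {
  uf <- uf_ledger(interspecies_intraspecies = 100, severity = 5)
  expect_identical(uf$composite, 500)
  expect_identical(derive_adi(8000, uf), 16)

  uf2 <- uf_ledger(interspecies_intraspecies = 100, loael_to_noael = 2,
                   severity = 5)
  expect_identical(uf2$composite, 1000)
  expect_identical(derive_adi(75000, uf2), 75)

  expect_identical(derive_adi(123.5, uf_ledger(none = 1)), 123.5)
  # adi * composite returns the pod exactly
  expect_identical(derive_adi(8000, uf) * uf$composite, 8000)
  expect_error(derive_adi(-1, uf), "> 0")
  expect_error(uf_ledger(100, 5), "named")
})

test_that("MRL back-calculation matches the residue arithmetic", {
  expect_identical(derive_mrl(75, 60, 0.3, 0.4), 6000)
  expect_identical(derive_mrl(16, 60, 0.3, 0.4), 1280)
  # allocation 1 and intake equal to body weight returns the ADI
  expect_identical(derive_mrl(42, 60, 60, 1), 42)
  expect_error(derive_mrl(75, 60, 0, 0.4), "> 0")
  expect_error(derive_mrl(75, 60, 0.3, 1.4), "allocation")

  # MRL of the derived ADI is linear in the POD
  uf <- uf_ledger(a = 100, b = 5)
  m <- function(pod) derive_mrl(derive_adi(pod, uf), 60, 0.3, 0.4)
  expect_equal(m(16000), 2 * m(8000))
  expect_equal(m(8000) + m(2000), m(10000))
})

test_that("exposure conversions and totals reproduce the published numbers", {
  expect_equal(per_capita_to_per_kg(117, 60), 1.95)
  expect_equal(round(per_capita_to_per_kg(43, 60), 2), 0.72)
  expect_identical(per_capita_to_per_kg(0, 75), 0)
  expect_identical(per_kg_to_per_capita(16, 60), 960)

  expect_equal(total_exposure(c(1.95, 0.4)), 2.35)
  expect_equal(total_exposure(c(0.72, 0.4)), 1.12)
  expect_identical(total_exposure(3.14), 3.14)
  expect_error(total_exposure(c(1, -0.1)), ">= 0")
})

test_that("margin of exposure is POD over exposure", {
  expect_equal(margin_of_exposure(8000, 2.35), 8000 / 2.35)
  expect_identical(margin_of_exposure(7, 7), 1)
  expect_true(margin_of_exposure(8000, 3) > margin_of_exposure(8000, 4))
  expect_error(margin_of_exposure(8000, 0), "> 0")
})

test_that("assess_risk chains the arithmetic and reads YAML configs", {
  ra <- assess_risk(8000, "bmdl",
                    uf_ledger(interspecies_intraspecies = 100, severity = 5),
                    body_weight = 60,
                    exposures = c(europe = 2.35, usa = 1.12),
                    daily_food_intake = 0.3, allocation = 0.4)
  expect_identical(ra$adi, 16)
  expect_identical(ra$acceptable_daily_amount, 960)
  expect_identical(ra$mrl, 1280)
  expect_equal(unname(ra$moe["europe"]), 8000 / 2.35)

  td <- tidy(ra)
  expect_identical(td$value[td$quantity == "mrl"], 1280)

  path <- system.file("extdata", "isoeugenol_assessment.yaml",
                      package = "benchdose")
  ra2 <- read_assessment(path)
  expect_identical(ra2$adi, 16)
  expect_identical(ra2$mrl, 1280)
  expect_error(assess_risk(8000, "bmdl", uf_ledger(a = 500),
                           daily_food_intake = 0.3),
               "allocation")
})
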