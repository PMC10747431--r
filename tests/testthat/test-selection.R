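test_that("classification follows the viability rules", {
  # adequate fit, sensible BMD -> viable
  ok <- classify_fit(stub_fit("A", bmd = 50, bmdl = 30, p_value = 0.5, aic = 100))
  expect_equal(ok$classification, "viable")

  # p-value below 0.10 -> questionable
  qp <- classify_fit(stub_fit("B", bmd = 50, bmdl = 30, p_value = 0.06, aic = 100))
  expect_equal(qp$classification, "questionable")
  expect_match(qp$reasons, "p-value", all = FALSE)

  # undefined p (saturated) -> questionable
  sat <- stub_fit("C", bmd = 50, bmdl = 30, p_value = NA_real_, aic = 100)
  expect_equal(classify_fit(sat)$classification, "questionable")

  # BMD or BMDL undefined -> unusable; nonconvergence -> unusable
  expect_equal(
    classify_fit(stub_fit("D", bmd = NA_real_, bmdl = NA_real_,
                          p_value = 0.5, aic = 100))$classification,
    "unusable")
  expect_equal(
    classify_fit(stub_fit("E", bmd = 50, bmdl = 30, p_value = 0.5, aic = 100,
                          converged = FALSE))$classification,
    "unusable")

  # BMD far below the lowest positive dose -> questionable
  low <- classify_fit(stub_fit("F", bmd = 2, bmdl = 0.5, p_value = 0.5, aic = 100))
  expect_equal(low$classification, "questionable")

  # large scaled residual -> questionable
  res <- classify_fit(stub_fit("G", bmd = 50, bmdl = 30, p_value = 0.5,
                               aic = 100, residuals = c(0, 2.5, 0, 0)))
  expect_equal(res$classification, "questionable")

  # BMD above the highest dose stays viable but warned
  hi <- classify_fit(stub_fit("H", bmd = 400, bmdl = 310, p_value = 0.9,
                              aic = 100,
                              flags = c("bmd_above_highest_dose",
                                        "bmdl_above_highest_dose")))
  expect_equal(hi$classification, "viable")
  expect_length(hi$warnings, 2)
})

test_that("recommendation picks lowest AIC in a narrow BMDL range, else lowest BMDL", {
  # narrow range (ratio <= 3): AIC decides
  narrow <- stub_suite(
    stub_fit("A", bmd = 60, bmdl = 40, p_value = 0.5, aic = 101),
    stub_fit("B", bmd = 55, bmdl = 35, p_value = 0.6, aic = 100),
    stub_fit("C", bmd = 90, bmdl = 80, p_value = 0.3, aic = 105))
  r <- recommend_model(narrow)
  expect_equal(r$recommended, "B")
  expect_equal(r$rationale, "lowest_aic")

  # wide range: BMDL decides even against a better AIC
  wide <- stub_suite(
    stub_fit("A", bmd = 30, bmdl = 10, p_value = 0.5, aic = 102),
    stub_fit("B", bmd = 90, bmdl = 60, p_value = 0.6, aic = 100))
  r <- recommend_model(wide)
  expect_equal(r$recommended, "A")
  expect_equal(r$rationale, "lowest_bmdl")

  # single viable model
  single <- stub_suite(
    stub_fit("A", bmd = 30, bmdl = 10, p_value = 0.5, aic = 102),
    stub_fit("B", bmd = 90, bmdl = 60, p_value = 0.05, aic = 100))
  r <- recommend_model(single)
  expect_equal(r$recommended, "A")
  expect_equal(r$rationale, "only_viable")

  # nothing viable
  none <- stub_suite(
    stub_fit("A", bmd = 30, bmdl = 10, p_value = 0.01, aic = 102),
    stub_fit("B", bmd = 90, bmdl = 60, p_value = 0.05, aic = 100))
  r <- recommend_model(none)
  expect_true(is.na(r$recommended))
  expect_equal(r$rationale, "none_viable")

  # AIC ties break by the lower BMDL
  tie <- stub_suite(
    stub_fit("A", bmd = 60, bmdl = 40, p_value = 0.5, aic = 100),
    stub_fit("B", bmd = 55, bmdl = 35, p_value = 0.6, aic = 100))
  expect_equal(recommend_model(tie)$recommended, "B")
})

test_that("recommendation is invariant to ordering and to pruning losers", {
  fits <- list(
    stub_fit("A", bmd = 60, bmdl = 40, p_value = 0.5, aic = 101),
    stub_fit("B", bmd = 55, bmdl = 35, p_value = 0.6, aic = 100),
    stub_fit("C", bmd = 90, bmdl = 80, p_value = 0.3, aic = 105),
    stub_fit("D", bmd = 90, bmdl = 60, p_value = 0.01, aic = 90))
  base <- recommend_model(do.call(stub_suite, fits))
  for (perm in list(c(4, 3, 2, 1), c(2, 4, 1, 3), c(3, 1, 4, 2))) {
    r <- recommend_model(do.call(stub_suite, fits[perm]))
    expect_equal(r$recommended, base$recommended)
    expect_equal(r$rationale, base$rationale)
  }
  # removing a model that was not recommended changes nothing
  pruned <- recommend_model(do.call(stub_suite, fits[c(1, 2, 4)]))
  expect_equal(pruned$recommended, base$recommended)
  expect_equal(pruned$rationale, base$rationale)
})

test_that("recommendation report tidiers summarize the table", {
  suite <- stub_suite(
    stub_fit("A", bmd = 60, bmdl = 40, p_value = 0.5, aic = 101),
    stub_fit("B", bmd = 55, bmdl = 35, p_value = 0.02, aic = 100))
  r <- recommend_model(suite)
  gl <- glance(r)
  expect_equal(gl$n_models, 2L)
  expect_equal(gl$n_viable, 1L)
  td <- tidy(r)
  expect_equal(sum(td$recommended), 1L)
  expect_equal(td$model[td$recommended], "A")
})
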