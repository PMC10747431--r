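test_that("autoplot builds dose-response plots with BMD guides", {
  f <- fit_quantal(adenoma_data(), "quantal_linear", compute_bmdl = FALSE)
  p <- autoplot(f)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gte(length(built$data), 2)  # curve + points (+ guides when defined)

  fc <- fit_continuous(body_weight_subset(), "linear", compute_bmdl = FALSE)
  pc <- autoplot(fc)
  expect_s3_class(pc, "ggplot")
  expect_no_error(ggplot2::ggplot_build(pc))
})
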