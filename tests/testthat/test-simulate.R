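test_that("simulation is reproducible under a fixed seed", {
  a <- simulate_quantal("quantal_linear", c(g = 0.1, b = 0.002),
                        doses = c(0, 75, 150, 300), size = 50,
                        n_rep = 3, seed = 99)
  b <- simulate_quantal("quantal_linear", c(g = 0.1, b = 0.002),
                        doses = c(0, 75, 150, 300), size = 50,
                        n_rep = 3, seed = 99)
  expect_identical(lapply(a, tibble::as_tibble), lapply(b, tibble::as_tibble))

  ca <- simulate_continuous("power", c(g = 352, v = -45 / 600^0.8, n = 0.8),
                            doses = c(0, 150, 300, 600), size = 10,
                            sigma = 7, n_rep = 2, seed = 12)
  cb <- simulate_continuous("power", c(g = 352, v = -45 / 600^0.8, n = 0.8),
                            doses = c(0, 150, 300, 600), size = 10,
                            sigma = 7, n_rep = 2, seed = 12)
  expect_identical(lapply(ca, tibble::as_tibble), lapply(cb, tibble::as_tibble))
})

test_that("simulated incidences follow the generating probabilities", {
  # degenerate probabilities give deterministic counts
  z <- simulate_quantal("quantal_linear", c(g = 0, b = 0),
                        doses = c(0, 10, 100), size = 30, n_rep = 5, seed = 1)
  expect_true(all(vapply(z, function(d) all(d$affected == 0), logical(1))))

  # empirical incidence within 3 binomial SEs of truth over many replicates
  p_true <- quantal_probability("quantal_linear", c(g = 0.15, b = 0.004),
                                c(0, 75, 150, 300))
  sims <- simulate_quantal("quantal_linear", c(g = 0.15, b = 0.004),
                           doses = c(0, 75, 150, 300), size = 50,
                           n_rep = 2000, seed = 3)
  inc <- colMeans(do.call(rbind, lapply(sims, function(d) d$affected / d$n)))
  se <- sqrt(p_true * (1 - p_true) / (50 * 2000))
  expect_true(all(abs(inc - p_true) <= 3 * se))
})

test_that("continuous group summaries collapse to the mean curve as sigma -> 0", {
  m_true <- continuous_mean("linear", c(g = 100, v = -0.05), c(0, 100, 200, 400))
  sims <- simulate_continuous("linear", c(g = 100, v = -0.05),
                              doses = c(0, 100, 200, 400), size = 6,
                              sigma = 1e-8, n_rep = 1, seed = 8)
  expect_equal(sims[[1]]$mean, m_true, tolerance = 1e-6)
})

test_that("the grid-scan oracle agrees with the analytic inversion", {
  # closed-form anchor
  expect_equal(true_bmd("quantal_linear", c(g = 0, b = -log(0.9)),
                        max_dose = 5, n_grid = 1e5),
               1, tolerance = 1e-6)
  # relative-deviation anchor: linear closed form bmrf * g / |v|
  expect_equal(true_bmd("linear", c(g = 352, v = -0.0802),
                        risk_type = "relative_deviation", max_dose = 600,
                        n_grid = 1e5),
               0.1 * 352 / 0.0802, tolerance = 1e-5)

  # deterministic sweep of parameter draws across families
  draws <- expand.grid(fam = c("quantal_linear", "gamma", "weibull",
                               "log_logistic", "log_probit"),
                       i = 1:10, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(draws))) {
    fam <- draws$fam[r]; i <- draws$i[r]
    par <- switch(fam,
      quantal_linear = c(0.02 * i, 0.001 + 0.0015 * i),
      gamma = c(0.02 * i, 0.5 + 0.2 * i, 0.002 + 0.001 * i),
      weibull = c(0.02 * i, 0.4 + 0.2 * i, 0.004 + 0.002 * i),
      log_logistic = c(0.02 * i, -4 + 0.3 * i, 0.6 + 0.1 * i),
      log_probit = c(0.02 * i, -3 + 0.25 * i, 0.5 + 0.1 * i))
    exact <- bmd_extra_risk(fam, par, bmrf = 0.1)
    expect_false(is.na(exact), label = paste(fam, i))
    oracle <- true_bmd(fam, par, bmrf = 0.1, max_dose = 300, n_grid = 2e5)
    expect_equal(oracle, exact, tolerance = 1e-5, label = paste(fam, i))
  }
})

test_that("fitting recovers the generating BMD at the study design scale", {
  true_b <- -log(0.9) / 50  # true BMD = 50
  sims <- simulate_quantal("quantal_linear", c(g = 0.15, b = true_b),
                           doses = c(0, 75, 150, 300), size = 50,
                           n_rep = 100, seed = 21)
  bmds <- vapply(sims, function(d) {
    fit_quantal(d, "quantal_linear", compute_bmdl = FALSE)$bmd
  }, numeric(1))
  expect_lt(abs(stats::median(bmds) - 50) / 50, 0.15)
})
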