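test_that("sufficient-statistic likelihood equals the individual-data likelihood", {
  set.seed(11)
  doses <- c(0, 50, 100, 200)
  m_true <- 100 - 0.1 * doses
  ys <- lapply(m_true, function(m) rnorm(8, m, 5))
  d <- continuous_data(doses, rep(8, 4),
                       vapply(ys, mean, 0), vapply(ys, sd, 0))
  # likelihood of an arbitrary mean vector, shared ML variance
  m_model <- 101 - 0.11 * doses
  ll_suff <- benchdose:::.cont_loglik(m_model, d$n, d$mean, d$sd)
  resid <- unlist(Map(function(y, m) y - m, ys, m_model))
  sig2 <- mean(resid^2)
  ll_indiv <- sum(stats::dnorm(resid, 0, sqrt(sig2), log = TRUE))
  expect_equal(ll_suff, ll_indiv, tolerance = 1e-6)
})

test_that("nested mean models have monotone log-likelihoods", {
  bw <- body_weight_subset()
  f1 <- fit_continuous(bw, "linear", compute_bmdl = FALSE)
  f2 <- fit_continuous(bw, "polynomial", degree = 2, restricted = FALSE,
                       compute_bmdl = FALSE)
  f3 <- fit_continuous(bw, "polynomial", degree = 3, restricted = FALSE,
                       compute_bmdl = FALSE)
  expect_lte(f1$loglik, f2$loglik + 1e-6)
  expect_lte(f2$loglik, f3$loglik + 1e-6)
})

test_that("relative-deviation BMD has closed forms and round-trips", {
  # linear: B = bmrf * g / |v|
  expect_equal(bmd_relative_deviation("linear", c(g = 352, v = -0.0802)),
               0.1 * 352 / 0.0802)
  # flat model never attains the deviation
  expect_true(is.na(bmd_relative_deviation("power", c(g = 352, v = 0, n = 1))))
  # wrong-direction trend never attains it either
  expect_true(is.na(bmd_relative_deviation("linear", c(g = 352, v = 0.5))))

  cases <- list(
    list("power", c(350, -40, 1.3), NULL),
    list("hill", c(350, -60, 120, 2), NULL),
    list("exponential3", c(350, 0.002, 1.4), NULL),
    list("exponential5", c(350, 0.004, 0.7, 1.2), NULL),
    list("polynomial", c(350, -0.05, -2e-4), 2)
  )
  for (cs in cases) {
    b <- bmd_relative_deviation(cs[[1]], cs[[2]], bmrf = 0.1,
                                direction = "down", degree = cs[[3]])
    m0 <- continuous_mean(cs[[1]], cs[[2]], 0, degree = cs[[3]])
    mb <- continuous_mean(cs[[1]], cs[[2]], b, degree = cs[[3]])
    expect_equal((m0 - mb) / m0, 0.1, tolerance = 1e-6, label = cs[[1]])
  }
})

test_that("fits recover generating parameters from near-noiseless data", {
  sims <- simulate_continuous("linear", c(g = 100, v = -0.05),
                              doses = c(0, 100, 200, 400), size = 10,
                              sigma = 0.01, n_rep = 1, seed = 5)
  f <- fit_continuous(sims[[1]], "linear", compute_bmdl = FALSE)
  expect_equal(unname(f$params[["v"]]), -0.05, tolerance = 0.01)
  expect_equal(unname(f$params[["g"]]), 100, tolerance = 0.001)
})

test_that("adverse direction is taken from the configuration", {
  bw <- body_weight_subset()
  f <- fit_continuous(bw, "power", restricted = FALSE)
  expect_lt(predict(f, 600), predict(f, 0))
  expect_lt(f$bmdl, f$bmd)
  # saturated comparison: LR statistic and df
  expect_equal(f$gof$df, 1L)
  expect_error(
    fit_continuous(bw, "power", config = bmd_config(risk_type = "extra_risk")),
    "relative_deviation")
})

test_that("flat power model predicts the control mean everywhere", {
  expect_equal(continuous_mean("power", c(g = 352, v = 0, n = 1),
                               c(0, 100, 600)),
               rep(352, 3))
  # linear is power with the exponent pinned at 1
  expect_equal(continuous_mean("linear", c(g = 10, v = -0.02), 250),
               continuous_mean("power", c(g = 10, v = -0.02, n = 1), 250))
})
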