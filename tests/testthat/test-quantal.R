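# Unit and property tests of the quantal model machinery. Heavier suite
# fits against the published tables live in test-acceptance.R.

test_that("predicted probabilities match the closed forms", {
  # null multistage model is identically zero
  expect_equal(
    quantal_probability("multistage", c(g = 0, b1 = 0), c(0, 10, 100), degree = 1),
    rep(0, 3))
  # quantal linear: 1 - exp(-b d)
  expect_equal(
    quantal_probability("quantal_linear", c(g = 0, b = -log(0.9)), 1), 0.1)
  # log-dose families return the background at dose 0
  expect_equal(
    quantal_probability("log_probit", c(g = 0.2, a = 0, b = 1), 0), 0.2)
  expect_equal(
    quantal_probability("dichotomous_hill", c(g = 0.1, v = 0.5, a = 0, b = 1), 0),
    0.1)
  # out-of-bound parameters are rejected
  expect_error(
    quantal_probability("quantal_linear", c(g = 1.5, b = 1), 1), "\\[0, 1\\]")
})

test_that("benchmark-dose inversion is exact and round-trips", {
  # closed form for quantal linear
  expect_equal(bmd_extra_risk("quantal_linear", c(0.37, -log(0.9))), 1)
  # model nesting: degree-2 multistage with b2 = 0 equals quantal linear
  expect_equal(
    bmd_extra_risk("multistage", c(0.1, 0.02, 0), degree = 2),
    bmd_extra_risk("quantal_linear", c(0.1, 0.02)))
  # the smallest positive root is returned for a non-monotone multistage
  par_nm <- c(g = 0.48, b1 = 2.5, b2 = -2.1)
  b <- bmd_extra_risk("multistage", par_nm, degree = 2)
  er <- function(d) {
    p <- quantal_probability("multistage", par_nm, d, degree = 2)
    (p - par_nm[["g"]]) / (1 - par_nm[["g"]])
  }
  expect_equal(er(b), 0.1, tolerance = 1e-6)
  expect_true(all(er(seq(1e-6, b * 0.999, length.out = 50)) < 0.1))

  # inversion round-trip across families: extra risk at the BMD equals bmrf
  cases <- list(
    list("gamma", c(0.1, 1.6, 2.3), NULL),
    list("weibull", c(0.05, 1.3, 0.8), NULL),
    list("log_logistic", c(0.2, -1, 1.4), NULL),
    list("log_probit", c(0.1, -0.5, 0.7), NULL),
    list("logistic", c(-2, 1.5), NULL),
    list("probit", c(-1.2, 0.9), NULL),
    list("dichotomous_hill", c(0.1, 0.6, -0.5, 1.2), NULL),
    list("multistage", c(0.1, 0.4, 0.9), 2)
  )
  for (cs in cases) {
    b <- bmd_extra_risk(cs[[1]], cs[[2]], bmrf = 0.1, degree = cs[[3]])
    p0 <- quantal_probability(cs[[1]], cs[[2]], 0, degree = cs[[3]])
    pb <- quantal_probability(cs[[1]], cs[[2]], b, degree = cs[[3]])
    expect_equal((pb - p0) / (1 - p0), 0.1, tolerance = 1e-6,
                 label = cs[[1]])
  }
})

test_that("multistage degree 1 and quantal linear fits coincide", {
  d <- carcinoma_data()
  f_ms <- fit_quantal(d, "multistage", degree = 1, restricted = FALSE)
  f_ql <- fit_quantal(d, "quantal_linear")
  expect_equal(f_ms$loglik, f_ql$loglik, tolerance = 1e-6)
  expect_equal(f_ms$bmd, f_ql$bmd, tolerance = 1e-4)
  expect_equal(f_ms$bmdl, f_ql$bmdl, tolerance = 1e-3)
})

test_that("restricted fits never beat unrestricted fits", {
  d <- adenoma_data()
  for (fm in c("gamma", "weibull", "log_logistic", "log_probit")) {
    fr <- fit_quantal(d, fm, restricted = TRUE, compute_bmdl = FALSE)
    fu <- fit_quantal(d, fm, restricted = FALSE, compute_bmdl = FALSE)
    expect_lte(fr$loglik, fu$loglik + 1e-6)
  }
  fr <- fit_quantal(d, "multistage", degree = 2, restricted = TRUE,
                    compute_bmdl = FALSE)
  fu <- fit_quantal(d, "multistage", degree = 2, restricted = FALSE,
                    compute_bmdl = FALSE)
  expect_lte(fr$loglik, fu$loglik + 1e-6)
})

test_that("optimizer matches a dense grid search on a two-parameter model", {
  d <- quantal_data(c(0, 100, 200), c(20, 20, 20), c(2, 7, 13))
  f <- fit_quantal(d, "quantal_linear", compute_bmdl = FALSE)
  gs <- expand.grid(g = seq(0, 0.4, length.out = 201),
                    b = seq(1e-4, 0.02, length.out = 401))
  ll <- mapply(function(g, b) {
    p <- quantal_probability("quantal_linear", c(g, b), d$dose)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(d$affected * log(p) + (d$n - d$affected) * log(1 - p))
  }, gs$g, gs$b)
  expect_gte(f$loglik, max(ll) - 1e-3)
})

test_that("profile BMDL sits below the BMD and AIC follows its definition", {
  d <- adenoma_data()
  f <- fit_quantal(d, "multistage", degree = 2, restricted = FALSE)
  expect_lt(f$bmdl, f$bmd)
  expect_equal(f$aic, -2 * f$loglik + 2 * f$n_params)
  expect_equal(AIC(f), f$aic)
  # recomputation agrees with the stored value
  expect_equal(profile_bmdl(f), f$bmdl, tolerance = 1e-4)
  # a confidence level closer to 0.5 gives a bound closer to the BMD
  expect_gt(profile_bmdl(f, confidence = 0.75), f$bmdl)
})

test_that("goodness of fit follows the Pearson construction", {
  # perfect agreement gives a zero statistic and p = 1
  gof <- benchdose:::.gof_quantal(y = c(2, 5, 9), n = c(20, 20, 20),
                                  p = c(0.1, 0.25, 0.45), k_free = 1)
  expect_equal(gof$statistic, 0)
  expect_equal(gof$p_value, 1)
  expect_equal(gof$df, 2L)

  # saturating parameter count leaves no degrees of freedom
  d <- adenoma_data()
  f <- fit_quantal(d, "multistage", degree = 3, restricted = FALSE,
                   compute_bmdl = FALSE)
  expect_true(is.na(f$gof$p_value) || f$gof$df >= 1)

  # residuals: (y - np) / sqrt(np(1-p))
  f2 <- fit_quantal(d, "quantal_linear", compute_bmdl = FALSE)
  p <- predict(f2)
  expect_equal(f2$gof$residuals,
               (d$affected - d$n * p) / sqrt(d$n * p * (1 - p)))
})

test_that("cancer slope factor is the BMRF/BMDL ratio", {
  expect_equal(cancer_slope_factor(0.1, 8), 0.0125)
  expect_equal(cancer_slope_factor(0.1, 0.1), 1)
  expect_true(cancer_slope_factor(0.1, 10) < cancer_slope_factor(0.1, 5))
  expect_error(cancer_slope_factor(0.1, 0), "> 0")
})

test_that("fits expose broom-style views and reports", {
  d <- adenoma_data()
  f <- fit_quantal(d, "multistage", degree = 2, restricted = TRUE,
                   compute_bmdl = FALSE)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "on_bound"))
  expect_equal(td$term, c("g", "b1", "b2"))
  expect_true(td$on_bound[td$term == "b2"])  # collapses onto the bound
  ag <- augment(f)
  expect_equal(ag$observed, d$affected / d$n)
  gl <- glance(f)
  expect_equal(gl$n_params, 2L)

  suite <- stub_suite(
    stub_fit("A", bmd = 50, bmdl = 30, p_value = 0.5, aic = 100),
    stub_fit("B", bmd = 60, bmdl = 40, p_value = 0.02, aic = 99))
  rep <- fit_report(classify_fits(suite), digits = "display")
  expect_equal(rep$bmd, c(50, 60))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fit_report(suite, path)
  expect_true(file.exists(path))
})
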