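# Study datasets built in code (same values as the bundled CSVs) plus small
# synthetic helpers used across the test files.

adenoma_data <- function() {
  quantal_data(c(0, 75, 150, 300), rep(50, 4), c(24, 35, 37, 33),
               label = "hepatocellular adenoma")
}

carcinoma_data <- function() {
  quantal_data(c(0, 75, 150, 300), rep(50, 4), c(8, 18, 19, 18),
               label = "hepatocellular carcinoma")
}

combined_data <- function() {
  quantal_data(c(0, 75, 150, 300), rep(50, 4), c(28, 43, 43, 43),
               label = "adenoma and carcinoma combined")
}

sarcoma_data <- function() {
  quantal_data(c(0, 75, 150, 300), c(49, 50, 50, 50), c(0, 1, 1, 4),
               label = "histiocytic sarcoma")
}

atrophy_female_data <- function() {
  quantal_data(c(0, 37.5, 75, 150, 300, 600), rep(10, 6),
               c(0, 1, 2, 2, 5, 6), label = "olfactory atrophy, female rats")
}

body_weight_data <- function() {
  continuous_data(c(0, 37.5, 75, 150, 300, 600), rep(10, 6),
                  c(352, 325, 334, 336, 326, 307), c(8, 3, 6, 7, 6, 7),
                  label = "terminal body weight, male rats")
}

body_weight_subset <- function() drop_dose_groups(body_weight_data(), c(37.5, 75))

# a minimal fake fit for exercising classification/recommendation logic
# without the cost of real model fits
stub_fit <- function(model, bmd, bmdl, p_value, aic,
                     family = "quantal_linear", degree = NA_integer_,
                     restricted = FALSE, residuals = rep(0, 4),
                     converged = TRUE, flags = character(0),
                     doses = c(0, 75, 150, 300)) {
  data <- quantal_data(doses, rep(50, length(doses)),
                       rep(0, length(doses)), label = "stub")
  structure(
    list(data = data, config = bmd_config(), family = family,
         degree = degree, restricted = restricted, model = model,
         converged = converged, loglik = -aic / 2, n_params = 2L, aic = aic,
         bmd = bmd, bmdl = bmdl,
         gof = list(statistic = 1, df = 2L, p_value = p_value,
                    residuals = residuals),
         flags = flags),
    class = c("quantal_fit", "bmd_fit")
  )
}

stub_suite <- function(...) {
  fits <- list(...)
  tibble::tibble(
    model = vapply(fits, `[[`, "", "model"),
    family = vapply(fits, `[[`, "", "family"),
    degree = vapply(fits, `[[`, NA_integer_, "degree"),
    restricted = vapply(fits, `[[`, NA, "restricted"),
    fit = fits,
    loglik = vapply(fits, `[[`, 0, "loglik"),
    n_params = vapply(fits, `[[`, 0L, "n_params"),
    aic = vapply(fits, `[[`, 0, "aic"),
    p_value = vapply(fits, function(f) f$gof$p_value, 0),
    gof_df = vapply(fits, function(f) f$gof$df, 0L),
    bmd = vapply(fits, `[[`, 0, "bmd"),
    bmdl = vapply(fits, `[[`, 0, "bmdl"),
    flags = lapply(fits, `[[`, "flags")
  )
}
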