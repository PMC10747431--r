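# Seeded simulation of summarized dose-response datasets from known model
# parameters, plus an independent grid-scan benchmark-dose oracle. These
# exist so that fitting, BMD inversion and BMDL coverage can be checked
# against a known truth without any external data.

#' Simulate quantal dose-response datasets
#'
#' Draws affected counts binomially per dose group from the true response
#' probabilities of a quantal model, for a number of replicate studies.
#' Identical seeds give identical datasets.
#'
#' @inheritParams quantal_probability
#' @param doses Dose levels (first must be 0, the control).
#' @param size Group size(s): a single integer or one per dose.
#' @param n_rep Number of replicate datasets.
#' @param seed Integer seed for the global RNG; `NULL` leaves the RNG state
#'   alone.
#' @param label Label attached to each dataset.
#' @return A list of `n_rep` [quantal_data()] objects. The seed and true
#'   parameters are attached as attributes `scenario`.
#' @examples
#' sims <- simulate_quantal("quantal_linear", c(g = 0.48, b = 0.0123),
#'                          doses = c(0, 75, 150, 300), size = 50,
#'                          n_rep = 2, seed = 1)
#' sims[[1]]
#' @export
simulate_quantal <- function(family, params, doses, size, n_rep = 1,
                             seed = NULL, degree = NULL, label = "simulated") {
  p <- quantal_probability(family, params, doses, degree = degree)
  size <- .recycle_size(size, doses)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(n_rep), function(i) {
    quantal_data(doses, size, rbinom(length(doses), size, p), label = label)
  })
  attr(out, "scenario") <- list(family = family, params = params,
                                doses = doses, size = size, seed = seed)
  out
}

#' Simulate continuous dose-response datasets
#'
#' Draws individual responses from `Normal(m(d), sigma)` and summarizes them
#' to per-group (n, mean, sd), the data shape the continuous fitting
#' consumes.
#'
#' @inheritParams continuous_mean
#' @param doses Dose levels (first must be 0).
#' @param size Group size(s), at least 2 per group.
#' @param sigma Common residual standard deviation (> 0).
#' @param n_rep,seed,label As in [simulate_quantal()].
#' @return A list of `n_rep` [continuous_data()] objects.
#' @export
simulate_continuous <- function(family, params, doses, size, sigma,
                                n_rep = 1, seed = NULL, degree = NULL,
                                direction = "down", label = "simulated") {
  if (sigma <= 0) abort("`sigma` must be > 0.")
  m <- continuous_mean(family, params, doses, degree = degree,
                       direction = direction)
  size <- .recycle_size(size, doses)
  if (any(size < 2)) abort("Group sizes must be >= 2 to yield an SD.")
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(n_rep), function(i) {
    ys <- lapply(seq_along(doses), function(j) rnorm(size[j], m[j], sigma))
    continuous_data(doses, size,
                    vapply(ys, mean, numeric(1)),
                    vapply(ys, sd, numeric(1)),
                    label = label)
  })
  attr(out, "scenario") <- list(family = family, params = params,
                                doses = doses, size = size, sigma = sigma,
                                seed = seed)
  out
}

.recycle_size <- function(size, doses) {
  size <- as.integer(size)
  if (length(size) == 1) size <- rep(size, length(doses))
  if (length(size) != length(doses)) {
    abort("`size` must have length 1 or length(doses).")
  }
  if (any(size < 1)) abort("Group sizes must be positive.")
  size
}

#' Grid-scan benchmark-dose oracle
#'
#' Computes the benchmark dose by a dense grid scan over (0, 10 x max_dose]
#' followed by local refinement: the smallest grid interval where the
#' benchmark response is first crossed is rescanned at increasing
#' resolution. Entirely independent of the closed-form/bisection inversion
#' used by the fitting code, so it serves as an oracle in tests.
#'
#' @inheritParams quantal_probability
#' @param bmrf Benchmark response factor.
#' @param risk_type `"extra_risk"` (quantal parameters) or
#'   `"relative_deviation"` (continuous parameters).
#' @param direction Adverse direction for relative deviation.
#' @param max_dose Upper end of the scanned range is `10 * max_dose`.
#' @param n_grid Number of grid points (default 1e6).
#' @return The benchmark dose, or `NA` if the response is never crossed.
#' @examples
#' true_bmd("quantal_linear", c(g = 0, b = -log(0.9)), max_dose = 5)
#' @export
true_bmd <- function(family, params, bmrf = 0.1,
                     risk_type = c("extra_risk", "relative_deviation"),
                     degree = NULL, direction = "down", max_dose,
                     n_grid = 1e6) {
  risk_type <- match.arg(risk_type)
  params <- as.numeric(params)
  if (risk_type == "extra_risk") {
    fam <- quantal_family(family, degree = degree)
    p0 <- fam$prob(params, 0)
    resp <- function(d) (fam$prob(params, d) - p0) / (1 - p0)
  } else {
    fam <- continuous_family(family, degree = degree, direction = direction)
    m0 <- fam$mean(params, 0)
    sgn <- if (direction == "down") -1 else 1
    resp <- function(d) sgn * (fam$mean(params, d) - m0) / abs(m0)
  }
  hi <- 10 * max_dose
  grid <- seq(0, hi, length.out = n_grid + 1)
  vals <- resp(grid)
  cross <- which(vals[-1] >= bmrf & vals[-length(vals)] < bmrf)
  if (!length(cross)) return(NA_real_)
  lo_i <- cross[1]
  lo <- grid[lo_i]; up <- grid[lo_i + 1]
  for (r in 1:6) {
    g2 <- seq(lo, up, length.out = 1001)
    v2 <- resp(g2)
    c2 <- which(v2[-1] >= bmrf & v2[-length(v2)] < bmrf)
    if (!length(c2)) break
    lo <- g2[c2[1]]; up <- g2[c2[1] + 1]
    if (up - lo < 1e-14 * (1 + up)) break
  }
  (lo + up) / 2
}
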