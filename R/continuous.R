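# Continuous dose-response families fitted to group summary statistics
# (n, mean, sd) under a normal likelihood with a single shared variance.
#
# Internally doses are scaled to [0, 1] and responses to units of the
# control mean; parameters are converted back afterwards. The variance is
# profiled out analytically (sigma^2_hat = SS / N), so the optimizer only
# sees the mean-model parameters.

.continuous_families <- c("exponential3", "exponential5", "hill",
                          "polynomial", "power", "linear")
.continuous_restrictable <- c("exponential3", "exponential5", "hill",
                              "polynomial", "power")

continuous_family <- function(family, degree = NULL, restricted = FALSE,
                              direction = "down") {
  family <- match.arg(family, .continuous_families)
  if (family == "polynomial") {
    if (is.null(degree)) abort("`degree` is required for the polynomial family.")
    degree <- as.integer(degree)
    if (degree < 1) abort("`degree` must be >= 1.")
  } else {
    if (!is.null(degree) && !is.na(degree)) {
      abort(sprintf("`degree` only applies to the polynomial family, not %s.", family))
    }
    degree <- NA_integer_
  }
  s <- if (direction == "down") -1 else 1
  f <- switch(family,
    linear = .cf_poly(1L, restricted = FALSE, s = s, label_linear = TRUE),
    polynomial = .cf_poly(degree, restricted, s = s),
    power = .cf_power(restricted, s),
    hill = .cf_hill(restricted, s),
    exponential3 = .cf_exp3(restricted, s),
    exponential5 = .cf_exp5(restricted, s)
  )
  f$family <- family
  f$degree <- degree
  f$restricted <- isTRUE(restricted) && family %in% .continuous_restrictable
  f$direction <- direction
  f
}

# smallest positive root of sum_i v_i B^i = s * bmrf * g
.poly_dev_root <- function(g, v, bmrf, s) {
  co <- c(-s * bmrf * g, v)
  while (length(co) > 1 && abs(co[length(co)]) < 1e-14) co <- co[-length(co)]
  if (length(co) < 2) return(NA_real_)
  r <- polyroot(co)
  r <- Re(r)[abs(Im(r)) < 1e-7 * (1 + abs(Re(r))) & Re(r) > 1e-12]
  if (!length(r)) NA_real_ else min(r)
}

.cf_poly <- function(k, restricted, s, label_linear = FALSE) {
  v_lo <- if (restricted && s < 0) -50 else if (restricted) 0 else -50
  v_hi <- if (restricted && s < 0) 0 else 50
  list(
    par_names = if (label_linear) c("g", "v") else c("g", paste0("v", seq_len(k))),
    bounds = list(lower = c(0.02, rep(v_lo, k)), upper = c(50, rep(v_hi, k))),
    structural = c(list(numeric(0)),
                   rep(list(if (restricted) 0 else numeric(0)), k)),
    mean = function(par, d) {
      as.vector(par[1] + outer(d, seq_len(k), "^") %*% par[-1])
    },
    bmd = function(par, bmrf) .poly_dev_root(par[1], par[-1], bmrf, s),
    starts = function(x, m) {
      X <- outer(x, seq_len(k), "^")
      v0 <- tryCatch(stats::coef(stats::lm(I(m - m[1]) ~ X - 1)),
                     error = function(e) rep(s * 0.1, k))
      v0[!is.finite(v0)] <- 0
      v0 <- .clamp(v0, v_lo, v_hi)
      lapply(c(1, 0.4, 2), function(f) c(m[1], v0 * f))
    },
    profile_reduce = function(par) par[-2],
    profile_expand = function(red, B, bmrf) {
      g <- red[1]; vrest <- if (k >= 2) red[-1] else numeric(0)
      v1 <- (s * bmrf * g - if (k >= 2) sum(vrest * B^(2:k)) else 0) / B
      pen <- 0
      if (restricted) {
        viol <- if (s < 0) max(v1, 0) else min(v1, 0)
        pen <- 1e6 * viol^2
      }
      list(par = c(g, v1, vrest), pen = pen)
    },
    profile_bounds = function(bounds) {
      list(lower = bounds$lower[-2], upper = bounds$upper[-2])
    },
    profile_starts = function(red_hat, B, bmrf) {
      if (k < 2) return(list())
      dev <- s * bmrf * red_hat[1]
      ws <- list(c(1, 0), c(0, 1), c(0.5, 0.5), c(0.3, 0.7), c(0.8, 0.2))
      lapply(ws, function(w) c(red_hat[1], dev * w[seq_len(k - 1)] / B^(2:k)))
    },
    unscale = function(par, dmax, r) c(par[1] * r, par[-1] * r / dmax^seq_len(k))
  )
}

.cf_power <- function(restricted, s) {
  n_lo <- if (restricted) 1 else 1e-2
  list(
    par_names = c("g", "v", "n"),
    bounds = list(lower = c(0.02, -50, n_lo), upper = c(50, 50, 18)),
    structural = list(numeric(0), numeric(0),
                      c(if (restricted) 1 else numeric(0), 18)),
    mean = function(par, d) par[1] + par[2] * d^par[3],
    bmd = function(par, bmrf) {
      if (sign(par[2]) != s || par[2] == 0) return(NA_real_)
      (bmrf * par[1] / abs(par[2]))^(1 / par[3])
    },
    starts = function(x, m) {
      v0 <- m[length(m)] - m[1]
      out <- list()
      for (n0 in c(0.7, 1, 1.5, 2.5)) for (vf in c(1, 0.5)) {
        out[[length(out) + 1]] <- c(m[1], v0 * vf, max(n0, n_lo))
      }
      out
    },
    profile_reduce = function(par) par[-2],
    profile_expand = function(red, B, bmrf) {
      list(par = c(red[1], s * bmrf * red[1] / B^red[2], red[2]), pen = 0)
    },
    profile_bounds = function(bounds) {
      list(lower = bounds$lower[-2], upper = bounds$upper[-2])
    },
    unscale = function(par, dmax, r) c(par[1] * r, par[2] * r / dmax^par[3], par[3])
  )
}

.cf_hill <- function(restricted, s) {
  n_lo <- if (restricted) 1 else 1e-2
  list(
    par_names = c("g", "v", "k", "n"),
    bounds = list(lower = c(0.02, -50, 1e-4, n_lo), upper = c(50, 50, 30, 18)),
    structural = list(numeric(0), numeric(0), numeric(0),
                      c(if (restricted) 1 else numeric(0), 18)),
    mean = function(par, d) {
      dn <- d^par[4]
      par[1] + par[2] * dn / (par[3]^par[4] + dn)
    },
    bmd = function(par, bmrf) {
      v <- par[2]
      if (sign(v) != s || abs(v) <= bmrf * par[1]) return(NA_real_)
      par[3] * (bmrf * par[1] / (abs(v) - bmrf * par[1]))^(1 / par[4])
    },
    starts = function(x, m) {
      v0 <- m[length(m)] - m[1]
      out <- list()
      for (k0 in c(0.2, 0.5, 1)) for (n0 in c(1, 2)) {
        out[[length(out) + 1]] <- c(m[1], v0, k0, max(n0, n_lo))
      }
      out
    },
    profile_reduce = function(par) par[-2],
    profile_expand = function(red, B, bmrf) {
      g <- red[1]; k <- red[2]; nn <- red[3]
      v <- s * bmrf * g * (k^nn + B^nn) / B^nn
      if (abs(v) > 50) return(NULL)
      list(par = c(g, v, k, nn), pen = 0)
    },
    profile_bounds = function(bounds) {
      list(lower = bounds$lower[-2], upper = bounds$upper[-2])
    },
    unscale = function(par, dmax, r) c(par[1] * r, par[2] * r, par[3] * dmax, par[4])
  )
}

.cf_exp3 <- function(restricted, s) {
  c_lo <- if (restricted) 1 else 1e-2
  dev_pow <- function(bmrf) if (s < 0) -log1p(-bmrf) else log1p(bmrf)
  list(
    par_names = c("a", "b", "c"),
    bounds = list(lower = c(0.02, 1e-9, c_lo), upper = c(50, 50, 18)),
    structural = list(numeric(0), numeric(0),
                      c(if (restricted) 1 else numeric(0), 18)),
    mean = function(par, d) par[1] * exp(s * (par[2] * d)^par[3]),
    bmd = function(par, bmrf) dev_pow(bmrf)^(1 / par[3]) / par[2],
    starts = function(x, m) {
      xl <- x[length(x)]
      out <- list()
      for (c0 in unique(pmax(c(1, 1.6, 2.5), c_lo))) {
        b0 <- (abs(log(max(m[length(m)], 0.05))))^(1 / c0) / xl
        for (bf in c(1, 0.5, 2)) {
          out[[length(out) + 1]] <- c(m[1], max(b0 * bf, 1e-8), c0)
        }
      }
      out
    },
    profile_reduce = function(par) par[-2],
    profile_expand = function(red, B, bmrf) {
      b <- dev_pow(bmrf)^(1 / red[2]) / B
      list(par = c(red[1], b, red[2]), pen = 0)
    },
    profile_bounds = function(bounds) {
      list(lower = bounds$lower[-2], upper = bounds$upper[-2])
    },
    unscale = function(par, dmax, r) c(par[1] * r, par[2] / dmax, par[3])
  )
}

.cf_exp5 <- function(restricted, s) {
  p_lo <- if (restricted) 1 else 1e-2
  c_bounds <- if (s < 0) c(1e-9, 1 - 1e-9) else c(1 + 1e-9, 50)
  list(
    par_names = c("a", "b", "c", "p"),
    bounds = list(lower = c(0.02, 1e-9, c_bounds[1], p_lo),
                  upper = c(50, 50, c_bounds[2], 18)),
    structural = list(numeric(0), numeric(0), numeric(0),
                      c(if (restricted) 1 else numeric(0), 18)),
    mean = function(par, d) {
      par[1] * (par[3] - (par[3] - 1) * exp(-(par[2] * d)^par[4]))
    },
    bmd = function(par, bmrf) {
      cc <- par[3]
      if (s < 0) {
        if (cc >= 1 - bmrf) return(NA_real_)
        E <- (1 - bmrf - cc) / (1 - cc)
      } else {
        if (cc <= 1 + bmrf) return(NA_real_)
        E <- (cc - 1 - bmrf) / (cc - 1)
      }
      (-log(E))^(1 / par[4]) / par[2]
    },
    starts = function(x, m) {
      ml <- m[length(m)]
      c0 <- if (s < 0) .clamp(ml - 0.05, 0.05, 0.9) else max(ml + 0.05, 1.1)
      out <- list()
      mid <- ceiling(length(x) / 2)
      for (p0 in c(max(1, p_lo), 2)) {
        E <- .clamp((m[mid] - c0) / (1 - c0), 0.05, 0.95)
        b0 <- (-log(E))^(1 / p0) / x[mid]
        for (bf in c(1, 0.4, 2.5)) {
          out[[length(out) + 1]] <- c(m[1], max(b0 * bf, 1e-8), c0, p0)
        }
      }
      out
    },
    profile_reduce = function(par) par[-2],
    profile_expand = function(red, B, bmrf) {
      cc <- red[2]
      if (s < 0) {
        if (cc >= 1 - bmrf * (1 + 1e-9)) return(NULL)
        E <- (1 - bmrf - cc) / (1 - cc)
      } else {
        if (cc <= 1 + bmrf * (1 + 1e-9)) return(NULL)
        E <- (cc - 1 - bmrf) / (cc - 1)
      }
      b <- (-log(E))^(1 / red[3]) / B
      list(par = c(red[1], b, cc, red[3]), pen = 0)
    },
    profile_bounds = function(bounds) {
      list(lower = bounds$lower[-2], upper = bounds$upper[-2])
    },
    unscale = function(par, dmax, r) c(par[1] * r, par[2] / dmax, par[3], par[4])
  )
}

# ---- likelihood ---------------------------------------------------------

# full normal log-likelihood from sufficient statistics, shared variance
# profiled out; equals the individual-data likelihood for data with
# matching n, mean and sd
.cont_loglik <- function(m, n, ybar, sdev) {
  ss <- sum((n - 1) * sdev^2 + n * (ybar - m)^2)
  N <- sum(n)
  sig2 <- ss / N
  -0.5 * N * (log(2 * pi * sig2) + 1)
}

.saturated_loglik_c <- function(n, ybar, sdev) .cont_loglik(ybar, n, ybar, sdev)

#' Predicted mean response of a continuous model
#'
#' @param family One of `"exponential3"`, `"exponential5"`, `"hill"`,
#'   `"polynomial"`, `"power"`, `"linear"`.
#' @param params Numeric parameter vector in the family's parameterization.
#' @param dose Doses (>= 0).
#' @param degree Polynomial degree (polynomial only).
#' @param direction Adverse direction, `"down"` or `"up"` (sign convention
#'   of the exponential families).
#' @return Mean responses in response units.
#' @examples
#' continuous_mean("power", c(g = 352, v = 0, n = 1), dose = c(0, 300))
#' @export
continuous_mean <- function(family, params, dose, degree = NULL,
                            direction = "down") {
  fam <- continuous_family(family, degree = degree, direction = direction)
  fam$mean(as.numeric(params), dose)
}

#' Benchmark dose at a given relative deviation
#'
#' Returns the smallest positive dose at which the mean response deviates
#' from the control mean `m(0)` by `bmrf * |m(0)|` in the adverse direction.
#'
#' @inheritParams continuous_mean
#' @param bmrf Benchmark response factor (relative deviation), in (0, 1).
#' @param max_dose If given, a BMD beyond `10 * max_dose` is reported as
#'   `NA` rather than extrapolated.
#' @return The benchmark dose, or `NA` when the deviation is never attained
#'   in the adverse direction.
#' @examples
#' # linear m(d) = 352 - 0.0802 d: BMD = 0.1 * 352 / 0.0802
#' bmd_relative_deviation("linear", c(g = 352, v = -0.0802), bmrf = 0.1)
#' @export
bmd_relative_deviation <- function(family, params, bmrf = 0.1,
                                   direction = "down", degree = NULL,
                                   max_dose = NULL) {
  fam <- continuous_family(family, degree = degree, direction = direction)
  b <- unname(fam$bmd(as.numeric(params), bmrf))
  if (is.na(b) || b <= 0) return(NA_real_)
  if (!is.null(max_dose) && b > 10 * max_dose) return(NA_real_)
  b
}

#' Fit a continuous dose-response model by maximum likelihood
#'
#' Maximizes the normal log-likelihood computed from the group sufficient
#' statistics (n, mean, sd) with a single shared (constant) variance, then
#' computes the relative-deviation benchmark dose, its profile-likelihood
#' lower limit, the likelihood-ratio goodness of fit against the saturated
#' model and the AIC. The adverse direction is taken from the configuration
#' (`"down"` for body weight), not auto-detected.
#'
#' @param data A [continuous_data()] object.
#' @param family Model family (see [continuous_mean()]).
#' @param degree Polynomial degree; defaults to one less than the number of
#'   dose groups, capped at the configured maximum.
#' @param restricted Fit the restricted form (power/shape parameters >= 1;
#'   polynomial coefficients constrained to the adverse direction's sign)?
#' @param config A [bmd_config()] with `risk_type = "relative_deviation"`.
#' @param compute_bmdl Set `FALSE` to skip the profile BMDL.
#' @return An object of class `continuous_fit`/`bmd_fit`.
#' @examples
#' d <- continuous_data(c(0, 150, 300, 600), rep(10, 4),
#'                      c(352, 336, 326, 307), c(8, 7, 6, 7))
#' fit <- fit_continuous(d, "power", restricted = FALSE)
#' glance(fit)
#' @export
fit_continuous <- function(data, family, degree = NULL, restricted = FALSE,
                           config = NULL, compute_bmdl = TRUE) {
  stopifnot(inherits(data, "continuous_data"))
  config <- config %||% .default_config(data)
  if (config$risk_type != "relative_deviation") {
    abort("Continuous models use `risk_type = \"relative_deviation\"`.")
  }
  if (family == "polynomial" && is.null(degree)) {
    degree <- max_model_degree(data, config)
  }
  if (family == "polynomial" && degree > max_model_degree(data, config)) {
    abort(sprintf(
      "Polynomial degree %d exceeds the maximum for %d dose groups (%d).",
      degree, nrow(data), max_model_degree(data, config)))
  }
  fam <- continuous_family(family, degree = degree, restricted = restricted,
                           direction = config$adverse_direction)

  dmax <- max(data$dose)
  rscale <- data$mean[1]
  x <- data$dose / dmax
  n <- data$n
  m_obs <- data$mean / rscale
  s_obs <- data$sd / rscale
  N <- sum(n)

  nll <- function(par) {
    m <- fam$mean(par, x)
    if (any(!is.finite(m))) return(1e10)
    -.cont_loglik(m, n, m_obs, s_obs)
  }

  best <- .mle_optim(nll, fam$starts(x, m_obs), fam$bounds$lower, fam$bounds$upper)

  out <- list(
    data = data, config = config,
    family = fam$family, degree = fam$degree, restricted = fam$restricted,
    model = .model_label(fam$family, fam$degree, fam$restricted),
    dose_scale = dmax, response_scale = rscale
  )
  class(out) <- c("continuous_fit", "bmd_fit")

  if (is.null(best)) {
    out$converged <- FALSE
    out$flags <- "nonconverged"
    out[c("loglik", "aic", "bmd", "bmdl", "sigma2")] <- NA_real_
    out$n_params <- NA_integer_
    out$gof <- list(statistic = NA_real_, df = NA_integer_,
                    p_value = NA_real_, residuals = rep(NA_real_, nrow(data)))
    return(out)
  }

  par_s <- setNames(best$par, fam$par_names)
  bs <- .bound_status(par_s, fam$bounds, fam$structural)
  flags <- character(0)
  if (any(bs$structural) || any(bs$guard)) flags <- c(flags, "boundary_hit")

  m_hat <- fam$mean(par_s, x)
  ss <- sum((n - 1) * s_obs^2 + n * (m_obs - m_hat)^2)
  sig2_scaled <- ss / N
  loglik <- -best$value - N * log(rscale)   # back to original response units
  k_mean_free <- sum(!bs$structural)
  k_free <- k_mean_free + 1L                # + shared variance

  # likelihood-ratio GOF against the saturated means model
  lr <- 2 * (.saturated_loglik_c(n, m_obs, s_obs) - (-best$value))
  df <- nrow(data) - k_mean_free
  p_value <- if (df >= 1) pchisq(max(lr, 0), df, lower.tail = FALSE) else NA_real_
  residuals <- (m_obs - m_hat) * rscale / (data$sd / sqrt(n))

  bmd_s <- unname(fam$bmd(par_s, config$bmrf))
  if (is.na(bmd_s) || bmd_s <= 0 || bmd_s > config$bmd_bracket_factor) {
    bmd <- NA_real_
    flags <- c(flags, "bmd_undefined")
  } else {
    bmd <- bmd_s * dmax
    if (bmd > dmax) flags <- c(flags, "bmd_above_highest_dose")
  }

  bmdl <- NA_real_
  if (compute_bmdl && !is.na(bmd)) {
    pll <- .make_pll(nll, fam, fam$bounds, fam$profile_reduce(par_s), config$bmrf)
    bmdl_s <- .profile_lower(bmd_s, -best$value, .bmdl_drop(config$confidence),
                             pll, tol = max(1e-7, bmd_s * 1e-6))
    if (is.na(bmdl_s)) {
      flags <- c(flags, "bmdl_undefined")
    } else {
      bmdl <- bmdl_s * dmax
      if (bmdl > dmax) flags <- c(flags, "bmdl_above_highest_dose")
    }
  } else if (compute_bmdl && is.na(bmd)) {
    flags <- c(flags, "bmdl_undefined")
  }

  out$converged <- TRUE
  out$params <- setNames(fam$unscale(par_s, dmax, rscale), fam$par_names)
  out$params_scaled <- par_s
  out$params_on_bound <- setNames(bs$structural, fam$par_names)
  out$sigma2 <- sig2_scaled * rscale^2
  out$loglik <- loglik
  out$n_params <- k_free
  out$n_params_total <- length(par_s) + 1L
  out$aic <- -2 * loglik + 2 * k_free
  out$bmd <- bmd
  out$bmdl <- bmdl
  out$gof <- list(statistic = lr, df = as.integer(df), p_value = p_value,
                  residuals = residuals)
  out$flags <- flags
  out
}

#' @export
predict.continuous_fit <- function(object, dose = NULL, ...) {
  dose <- dose %||% object$data$dose
  continuous_mean(object$family, object$params, dose,
                  degree = if (is.na(object$degree)) NULL else object$degree,
                  direction = object$config$adverse_direction)
}

#' Fit the full continuous model suite
#'
#' Fits the continuous families to a dataset: exponential 3 and 5
#' (restricted form, the form the standard software offers), Hill, power and
#' polynomial in restricted and unrestricted form, and the linear model.
#' Polynomials are fitted at every degree from 2 up to one less than the
#' number of dose groups, capped at 3 (degree 1 is the linear model).
#'
#' @inheritParams fit_continuous
#' @param restriction Which forms to fit where both are offered.
#' @param families Families to include (default: all).
#' @return A tibble with the same columns as [fit_quantal_suite()].
#' @export
fit_continuous_suite <- function(data, config = NULL,
                                 restriction = c("both", "restricted", "unrestricted"),
                                 families = NULL, compute_bmdl = TRUE) {
  stopifnot(inherits(data, "continuous_data"))
  config <- config %||% .default_config(data)
  restriction <- match.arg(restriction)
  families <- families %||% .continuous_families
  kmax <- max_model_degree(data, config)

  both <- switch(restriction, both = c(TRUE, FALSE), restricted = TRUE,
                 unrestricted = FALSE)
  specs <- purrr::map_dfr(families, function(fm) {
    forms <- if (fm %in% c("hill", "power", "polynomial")) {
      both
    } else if (fm %in% c("exponential3", "exponential5")) {
      # offered in restricted form only
      if (identical(both, FALSE)) return(NULL) else TRUE
    } else {
      FALSE
    }
    degs <- if (fm == "polynomial") {
      if (kmax < 2) return(NULL) else 2:kmax
    } else {
      NA_integer_
    }
    tidyr::expand_grid(family = fm, degree = degs, restricted = forms)
  })

  fits <- purrr::pmap(specs, function(family, degree, restricted) {
    fit_continuous(data, family,
                   degree = if (is.na(degree)) NULL else degree,
                   restricted = restricted, config = config,
                   compute_bmdl = compute_bmdl)
  })
  .suite_tibble(specs, fits)
}
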