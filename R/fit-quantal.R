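# Maximum-likelihood fitting of quantal dose-response models, benchmark dose
# inversion and profile-likelihood lower confidence limits.

# binomial log-likelihood without the combinatorial constant, the convention
# under which an AIC of -2*loglik + 2*k matches the reference software
.binom_loglik <- function(p, y, n) {
  p <- .clamp(p, 1e-12, 1 - 1e-12)
  sum(y * log(p) + (n - y) * log1p(-p))
}

.saturated_loglik_q <- function(y, n) .binom_loglik(y / n, y, n)

# multi-start bounded quasi-Newton; deterministic (no RNG anywhere in fitting)
.mle_optim <- function(nll, starts, lower, upper) {
  best <- NULL
  for (s in starts) {
    s <- .clamp(as.numeric(s), lower, upper)
    o <- tryCatch(
      optim(s, nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 1000, factr = 1e4)),
      error = function(e) NULL
    )
    if (is.null(o) && length(s) > 1) {
      o <- tryCatch({
        nm <- optim(s, function(p) nll(.clamp(p, lower, upper)),
                    method = "Nelder-Mead", control = list(maxit = 800))
        optim(.clamp(nm$par, lower, upper), nll, method = "L-BFGS-B",
              lower = lower, upper = upper,
              control = list(maxit = 1000, factr = 1e4))
      }, error = function(e) NULL)
    }
    if (is.null(o) && length(s) == 1) {
      o <- tryCatch({
        op <- optimize(function(p) nll(.clamp(p, lower, upper)),
                       c(lower, upper), tol = 1e-10)
        list(par = op$minimum, value = op$objective)
      }, error = function(e) NULL)
    }
    if (!is.null(o) && is.finite(o$value) &&
        (is.null(best) || o$value < best$value)) {
      best <- o
    }
  }
  best
}

# which parameters sit on a bound that encodes a model restriction (those are
# not counted as estimated), and whether any parameter sits on a purely
# numerical guard bound
.bound_status <- function(par, bounds, structural) {
  on_struct <- vapply(seq_along(par), function(i) {
    any(abs(par[i] - structural[[i]]) < 1e-6 * (1 + abs(structural[[i]])))
  }, logical(1))
  on_box <- (abs(par - bounds$lower) < 1e-8 * (1 + abs(bounds$lower))) |
    (abs(par - bounds$upper) < 1e-8 * (1 + abs(bounds$upper)))
  list(structural = on_struct, guard = on_box & !on_struct)
}

# profile-likelihood lower limit on the benchmark dose: bisection on the
# constrained dose with an inner constrained optimization, cut at the
# chi-square(1) drop for a one-sided lower bound
.profile_lower <- function(bmd, loglik_hat, drop, pll, tol) {
  target <- function(B) 2 * (loglik_hat - pll(B)) - 2 * drop
  # walk down from the BMD so the warm-started inner optimization tracks the
  # profile path, then bisect inside the bracketing step
  hi <- bmd
  lo <- bmd
  ok <- FALSE
  for (i in 1:260) {
    lo <- lo * 0.92
    t <- target(lo)
    if (is.finite(t) && t > 0) { ok <- TRUE; break }
    hi <- lo
  }
  if (!ok) return(NA_real_)
  tryCatch(uniroot(target, c(lo, hi), tol = tol, maxiter = 100)$root,
           error = function(e) NA_real_)
}

# profile log-likelihood at a pinned BMD via the family's parameter
# elimination; warm-started along the profile path
.make_pll <- function(nll, fam, bounds, red_hat, bmrf) {
  rb <- fam$profile_bounds(bounds)
  warm <- new.env(parent = emptyenv())
  warm$red <- NULL
  function(B) {
    obj <- function(red) {
      ex <- fam$profile_expand(red, B, bmrf)
      if (is.null(ex)) return(1e10)
      v <- nll(ex$par) + ex$pen
      if (is.finite(v)) v else 1e10
    }
    starts <- list(red_hat,
                   .clamp(red_hat * 0.8, rb$lower, rb$upper),
                   .clamp(red_hat * 1.25 + 0.01, rb$lower, rb$upper))
    if (!is.null(fam$profile_starts)) {
      starts <- c(starts, fam$profile_starts(red_hat, B, bmrf))
    }
    if (!is.null(warm$red)) starts <- c(list(warm$red), starts)
    best <- NULL
    if (length(rb$lower) == 1) {
      op <- tryCatch(optimize(obj, c(rb$lower, rb$upper), tol = 1e-10),
                     error = function(e) NULL)
      if (!is.null(op)) best <- list(par = op$minimum, value = op$objective)
    }
    cand <- .mle_optim(obj, starts, rb$lower, rb$upper)
    if (!is.null(cand) && (is.null(best) || cand$value < best$value)) best <- cand
    if (is.null(best)) return(-Inf)
    warm$red <- best$par
    -best$value
  }
}

#' Predicted response probability of a quantal model
#'
#' Evaluates a quantal dose-response family at given parameter values. At
#' dose 0 the log-dose families return the background parameter `g` (their
#' zero-dose limit).
#'
#' @param family One of `"multistage"`, `"quantal_linear"`, `"gamma"`,
#'   `"weibull"`, `"log_logistic"`, `"logistic"`, `"probit"`,
#'   `"log_probit"`, `"dichotomous_hill"`.
#' @param params Named or positional numeric parameter vector in the
#'   family's parameterization (see the package vignette), on the same dose
#'   scale as `dose`.
#' @param dose Vector of doses (>= 0).
#' @param degree Multistage degree (multistage only).
#' @return Probabilities in \[0, 1\].
#' @examples
#' quantal_probability("quantal_linear", c(g = 0, b = -log(0.9)), dose = 1)
#' @export
quantal_probability <- function(family, params, dose, degree = NULL) {
  fam <- quantal_family(family, degree = degree)
  if (any(dose < 0)) abort("`dose` must be >= 0.")
  p <- fam$prob(as.numeric(params), dose)
  if (any(p < -1e-8 | p > 1 + 1e-8)) {
    abort("Parameters yield probabilities outside [0, 1].")
  }
  .clamp(p, 0, 1)
}

#' Benchmark dose at a given extra risk
#'
#' Returns the smallest positive dose at which the extra risk
#' `(p(d) - p(0)) / (1 - p(0))` reaches `bmrf`. Inversion is exact
#' (closed form per family; smallest positive polynomial root for the
#' multistage family, which covers non-monotone unrestricted fits).
#'
#' @inheritParams quantal_probability
#' @param bmrf Benchmark response factor (extra risk), in (0, 1).
#' @param max_dose If given, a BMD beyond `10 * max_dose` is reported as
#'   `NA` (undefined) rather than extrapolated.
#' @return The benchmark dose, or `NA` if the extra risk is never attained.
#' @examples
#' bmd_extra_risk("quantal_linear", c(g = 0.3, b = -log(0.9)), bmrf = 0.1)
#' @export
bmd_extra_risk <- function(family, params, bmrf = 0.1, degree = NULL,
                           max_dose = NULL) {
  fam <- quantal_family(family, degree = degree)
  b <- unname(fam$bmd(as.numeric(params), bmrf))
  if (is.na(b) || b <= 0) return(NA_real_)
  if (!is.null(max_dose) && b > 10 * max_dose) return(NA_real_)
  b
}

#' Cancer slope factor
#'
#' Linear extrapolation slope from the point of departure to the origin:
#' the ratio between the benchmark response factor and the BMDL.
#'
#' @param bmrf Benchmark response factor.
#' @param bmdl Benchmark dose lower confidence limit (> 0).
#' @return Risk per unit dose.
#' @examples
#' cancer_slope_factor(0.1, 8)
#' @export
cancer_slope_factor <- function(bmrf, bmdl) {
  if (any(bmdl <= 0)) abort("`bmdl` must be > 0.")
  bmrf / bmdl
}

#' Fit a quantal dose-response model by maximum likelihood
#'
#' Maximizes the binomial log-likelihood of a quantal model family over its
#' (optionally restricted) parameter space, then computes the benchmark dose
#' at the configured extra risk, its profile-likelihood lower confidence
#' limit (BMDL), the Pearson chi-square goodness of fit and the AIC.
#'
#' Restricted fits constrain shape/slope parameters to >= 1 (gamma, Weibull,
#' log-logistic, log-probit, dichotomous Hill) or the multistage
#' coefficients to be non-negative; unrestricted multistage fits relax the
#' coefficient signs but keep predicted probabilities inside \[0, 1\] across
#' the observed dose range. Parameters that land on a restriction bound are
#' not counted as estimated for the AIC and the goodness-of-fit degrees of
#' freedom, the convention of the EPA BMDS software.
#'
#' Fitting uses a deterministic multi-start bounded quasi-Newton scheme on
#' doses rescaled to \[0, 1\]; there is no randomness, so refits are
#' reproducible to machine precision.
#'
#' @param data A [quantal_data()] object.
#' @param family Model family (see [quantal_probability()]).
#' @param degree Multistage degree; defaults to one less than the number of
#'   dose groups, capped at the configured maximum.
#' @param restricted Fit the restricted form? Ignored (with identical
#'   behavior) by families without a restricted form.
#' @param config A [bmd_config()] with `risk_type = "extra_risk"`; defaults
#'   to the standard quantal settings.
#' @param compute_bmdl Set `FALSE` to skip the (comparatively expensive)
#'   profile BMDL.
#' @return An object of class `quantal_fit`/`bmd_fit`; see [glance()],
#'   [tidy()], [augment()] and [autoplot()] methods.
#' @examples
#' d <- quantal_data(c(0, 75, 150, 300), rep(50, 4), c(24, 35, 37, 33))
#' fit <- fit_quantal(d, "multistage", degree = 2, restricted = FALSE)
#' glance(fit)
#' @export
fit_quantal <- function(data, family, degree = NULL, restricted = FALSE,
                        config = NULL, compute_bmdl = TRUE) {
  stopifnot(inherits(data, "quantal_data"))
  config <- config %||% .default_config(data)
  if (config$risk_type != "extra_risk") {
    abort("Quantal models use `risk_type = \"extra_risk\"`.")
  }
  if (family == "multistage" && is.null(degree)) {
    degree <- max_model_degree(data, config)
  }
  if (family == "multistage" && degree > max_model_degree(data, config)) {
    abort(sprintf(
      "Multistage degree %d exceeds the maximum for %d dose groups (%d).",
      degree, nrow(data), max_model_degree(data, config)))
  }
  fam <- quantal_family(family, degree = degree, restricted = restricted)

  dmax <- max(data$dose)
  x <- data$dose / dmax
  y <- data$affected
  n <- data$n

  nll <- function(par) {
    p <- fam$prob(par, x)
    pen <- 0
    if (isTRUE(fam$penalize_prob)) {
      pen <- 1e6 * sum(pmax(0, -p)^2 + pmax(0, p - 1)^2)
    }
    -.binom_loglik(p, y, n) + pen
  }

  best <- .mle_optim(nll, fam$starts(x, y, n), fam$bounds$lower, fam$bounds$upper)

  out <- list(
    data = data, config = config,
    family = fam$family, degree = fam$degree, restricted = fam$restricted,
    model = .model_label(fam$family, fam$degree, fam$restricted),
    dose_scale = dmax
  )
  class(out) <- c("quantal_fit", "bmd_fit")

  if (is.null(best)) {
    out$converged <- FALSE
    out$flags <- "nonconverged"
    out[c("loglik", "aic", "bmd", "bmdl")] <- NA_real_
    out$n_params <- NA_integer_
    out$gof <- list(statistic = NA_real_, df = NA_integer_,
                    p_value = NA_real_, residuals = rep(NA_real_, nrow(data)))
    return(out)
  }

  par_s <- setNames(best$par, fam$par_names)
  bs <- .bound_status(par_s, fam$bounds, fam$structural)
  flags <- character(0)
  if (any(bs$structural) || any(bs$guard)) flags <- c(flags, "boundary_hit")

  loglik <- -best$value  # penalty is ~0 at any accepted optimum
  k_free <- sum(!bs$structural)
  p_hat <- .clamp(fam$prob(par_s, x), 0, 1)
  gof <- .gof_quantal(y, n, p_hat, k_free)
  if (gof$degenerate) flags <- c(flags, "degenerate_fitted_probability")

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
    bmdl_s <- .profile_lower(bmd_s, loglik, .bmdl_drop(config$confidence),
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
  out$params <- setNames(fam$unscale(par_s, dmax), fam$par_names)
  out$params_scaled <- par_s
  out$params_on_bound <- setNames(bs$structural, fam$par_names)
  out$loglik <- loglik
  out$n_params <- k_free
  out$n_params_total <- length(par_s)
  out$aic <- -2 * loglik + 2 * k_free
  out$bmd <- bmd
  out$bmdl <- bmdl
  out$gof <- gof[c("statistic", "df", "p_value", "residuals")]
  out$flags <- flags
  out
}

.gof_quantal <- function(y, n, p, k_free) {
  expected <- n * p
  denom <- n * p * (1 - p)
  degenerate <- any(denom < 1e-12 & abs(y - expected) > 1e-9)
  res <- ifelse(denom < 1e-12,
                ifelse(abs(y - expected) <= 1e-9, 0, NA_real_),
                (y - expected) / sqrt(denom))
  statistic <- sum(res^2)
  df <- length(y) - k_free
  p_value <- if (df >= 1 && is.finite(statistic)) {
    pchisq(statistic, df, lower.tail = FALSE)
  } else {
    NA_real_
  }
  list(statistic = statistic, df = as.integer(df), p_value = p_value,
       residuals = res, degenerate = degenerate)
}

#' Goodness of fit of a fitted dose-response model
#'
#' For quantal fits: Pearson chi-square against the observed incidences with
#' per-group scaled residuals `(y - n p) / sqrt(n p (1 - p))`. For
#' continuous fits: likelihood-ratio test against the saturated model (one
#' free mean per group, shared constant variance). Degrees of freedom are
#' the number of dose groups minus the number of estimated parameters
#' (mean-model parameters for the continuous test); with df <= 0 the
#' p-value is undefined.
#'
#' @param fit A `quantal_fit` or `continuous_fit`.
#' @return A list with `statistic`, `df`, `p_value` and (quantal)
#'   `residuals`.
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "bmd_fit"))
  fit$gof
}

#' Recompute the profile-likelihood BMDL of a fit
#'
#' The BMDL is the largest dose below the BMD at which the log-likelihood,
#' re-maximized subject to the benchmark dose being pinned at that value,
#' has dropped by half the chi-square(1) quantile corresponding to a
#' one-sided lower confidence bound (1.352771 at 95%).
#'
#' @param fit A converged `bmd_fit` with a defined BMD.
#' @param confidence Overrides the confidence level of `fit$config`.
#' @return The BMDL (same dose units as the data), or `NA` when the profile
#'   cannot be bracketed.
#' @export
profile_bmdl <- function(fit, confidence = NULL) {
  stopifnot(inherits(fit, "bmd_fit"))
  if (!isTRUE(fit$converged) || is.na(fit$bmd)) {
    abort("`fit` must be converged with a defined BMD.")
  }
  confidence <- confidence %||% fit$config$confidence
  cfg <- fit$config
  if (inherits(fit, "quantal_fit")) {
    f2 <- fit
    f2$config$confidence <- confidence
    refit <- fit_quantal(fit$data, fit$family,
                         degree = if (is.na(fit$degree)) NULL else fit$degree,
                         restricted = fit$restricted, config = f2$config)
    refit$bmdl
  } else {
    cfg$confidence <- confidence
    refit <- fit_continuous(fit$data, fit$family,
                            degree = if (is.na(fit$degree)) NULL else fit$degree,
                            restricted = fit$restricted, config = cfg)
    refit$bmdl
  }
}

#' @export
logLik.bmd_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' @export
predict.quantal_fit <- function(object, dose = NULL, ...) {
  dose <- dose %||% object$data$dose
  quantal_probability(object$family, object$params, dose,
                      degree = if (is.na(object$degree)) NULL else object$degree)
}

#' @export
print.bmd_fit <- function(x, ...) {
  cat(sprintf("<%s> %s\n", class(x)[1], x$model))
  lab <- endpoint_label(x)
  if (!is.na(lab)) cat(sprintf("  endpoint: %s\n", lab))
  if (!isTRUE(x$converged)) {
    cat("  did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("  loglik %.4f  AIC %.2f  (%d estimated parameter%s)\n",
              x$loglik, x$aic, x$n_params, if (x$n_params == 1) "" else "s"))
  pv <- x$gof$p_value
  cat(sprintf("  GOF p %s (df %s)   BMD %s   BMDL %s\n",
              ifelse(is.na(pv), "-", sprintf("%.3f", pv)), x$gof$df,
              ifelse(is.na(x$bmd), "undefined", sprintf("%.4g", x$bmd)),
              ifelse(is.na(x$bmdl), "undefined", sprintf("%.4g", x$bmdl))))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

.family_display <- c(
  multistage = "Multistage", quantal_linear = "Quantal Linear",
  gamma = "Gamma", weibull = "Weibull", log_logistic = "Log-Logistic",
  logistic = "Logistic", probit = "Probit", log_probit = "Log-Probit",
  dichotomous_hill = "Dichotomous Hill",
  exponential3 = "Exponential 3", exponential5 = "Exponential 5",
  hill = "Hill", polynomial = "Polynomial", power = "Power", linear = "Linear"
)

.model_label <- function(family, degree, restricted) {
  nm <- .family_display[[family]]
  if (!is.na(degree)) nm <- sprintf("%s Degree %d", nm, degree)
  restrictable <- family %in% c(.quantal_restrictable,
                                "exponential3", "exponential5", "hill",
                                "polynomial", "power")
  if (restrictable) {
    nm <- sprintf("%s (%s)", nm, if (restricted) "restricted" else "unrestricted")
  }
  nm
}

#' Fit the full quantal model suite
#'
#' Fits every quantal family to a dataset, in restricted and unrestricted
#' form where both are offered (gamma, Weibull, log-logistic, log-probit,
#' multistage, dichotomous Hill; logistic, probit and quantal-linear have a
#' single form). Multistage models are fitted at every degree from 1 up to
#' one less than the number of dose groups, capped at 3.
#'
#' @inheritParams fit_quantal
#' @param restriction Which forms to fit: `"both"` (default), or only the
#'   `"restricted"` / `"unrestricted"` form of each family.
#' @param families Character vector of families to include (default: all).
#' @return A tibble with one row per fitted model: `model`, `family`,
#'   `degree`, `restricted`, the `fit` object (list column), `loglik`,
#'   `n_params`, `aic`, `p_value`, `gof_df`, `bmd`, `bmdl` and `flags`.
#' @examples
#' \donttest{
#' d <- quantal_data(c(0, 75, 150, 300), rep(50, 4), c(24, 35, 37, 33))
#' suite <- fit_quantal_suite(d)
#' dplyr::select(suite, model, p_value, aic, bmd, bmdl)
#' }
#' @export
fit_quantal_suite <- function(data, config = NULL,
                              restriction = c("both", "restricted", "unrestricted"),
                              families = NULL, compute_bmdl = TRUE) {
  stopifnot(inherits(data, "quantal_data"))
  config <- config %||% .default_config(data)
  restriction <- match.arg(restriction)
  families <- families %||% .quantal_families
  kmax <- max_model_degree(data, config)

  specs <- purrr::map_dfr(families, function(fm) {
    forms <- if (fm %in% .quantal_restrictable) {
      switch(restriction, both = c(TRUE, FALSE), restricted = TRUE,
             unrestricted = FALSE)
    } else {
      FALSE
    }
    degs <- if (fm == "multistage") seq_len(kmax) else NA_integer_
    tidyr::expand_grid(family = fm, degree = degs, restricted = forms)
  })

  fits <- purrr::pmap(specs, function(family, degree, restricted) {
    fit_quantal(data, family,
                degree = if (is.na(degree)) NULL else degree,
                restricted = restricted, config = config,
                compute_bmdl = compute_bmdl)
  })
  .suite_tibble(specs, fits)
}

.suite_tibble <- function(specs, fits) {
  tibble::tibble(
    model = purrr::map_chr(fits, "model"),
    family = specs$family,
    degree = specs$degree,
    restricted = specs$restricted,
    fit = fits,
    loglik = purrr::map_dbl(fits, ~ .x$loglik %||% NA_real_),
    n_params = purrr::map_int(fits, ~ as.integer(.x$n_params %||% NA_integer_)),
    aic = purrr::map_dbl(fits, ~ .x$aic %||% NA_real_),
    p_value = purrr::map_dbl(fits, ~ .x$gof$p_value %||% NA_real_),
    gof_df = purrr::map_int(fits, ~ as.integer(.x$gof$df %||% NA_integer_)),
    bmd = purrr::map_dbl(fits, ~ .x$bmd %||% NA_real_),
    bmdl = purrr::map_dbl(fits, ~ .x$bmdl %||% NA_real_),
    flags = purrr::map(fits, "flags")
  )
}
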