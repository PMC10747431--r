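# Quantal dose-response model families, EPA BMDS parameterizations.
#
# Every function here is scale-free in dose: parameters are interpreted in
# whatever dose units `d` carries. Fitting works on doses scaled to [0, 1]
# (d / dmax) for optimizer conditioning and converts parameters back to the
# original scale at the end (see .qf_unscale).
#
# A family object carries:
#   prob(par, d)          response probability, vectorized over d
#   bmd(par, bmrf)        closed-form benchmark dose at extra risk `bmrf`
#   bounds                box constraints (scaled-dose space)
#   structural            per-parameter bound values that are model
#                         restrictions (parameters landing there are treated
#                         as not estimated, the convention of the reference
#                         software)
#   starts(x, y, n)       deterministic multi-start list
#   profile_*             reparameterization that pins the BMD at a value B
#                         by eliminating one parameter, for the profile BMDL

.quantal_families <- c("multistage", "quantal_linear", "gamma", "weibull",
                       "log_logistic", "logistic", "probit", "log_probit",
                       "dichotomous_hill")

# families where the restricted/unrestricted switch changes the parameter
# space; the remainder accept either flag with identical behavior
.quantal_restrictable <- c("multistage", "gamma", "weibull", "log_logistic",
                           "log_probit", "dichotomous_hill")

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# empirical summaries used for start values
.q_emp <- function(x, y, n) {
  pobs <- (y + 0.5) / (n + 1)
  g0 <- .clamp(pobs[1], 0.01, 0.95)
  er <- .clamp((pobs - g0) / (1 - g0), 0.005, 0.99)
  list(pobs = pobs, g0 = g0, er = er)
}

.q_logreg <- function(tvals, x) {
  # regress transformed extra risk on log dose (positive doses only)
  pos <- x > 0
  lx <- log(x[pos]); t <- tvals[pos]
  if (length(unique(lx)) < 2) return(c(a = 0, b = 1))
  co <- stats::coef(stats::lm(t ~ lx))
  c(a = unname(co[1]), b = unname(co[2]))
}

quantal_family <- function(family, degree = NULL, restricted = FALSE) {
  family <- match.arg(family, .quantal_families)
  if (family == "multistage") {
    if (is.null(degree)) abort("`degree` is required for the multistage family.")
    degree <- as.integer(degree)
    if (degree < 1) abort("`degree` must be >= 1.")
  } else {
    if (!is.null(degree) && !is.na(degree)) {
      abort(sprintf("`degree` only applies to the multistage family, not %s.", family))
    }
    degree <- NA_integer_
  }
  f <- switch(family,
    multistage = .qf_multistage(degree, restricted),
    quantal_linear = .qf_quantal_linear(),
    gamma = .qf_gamma(restricted),
    weibull = .qf_weibull(restricted),
    log_logistic = .qf_log_logistic(restricted),
    log_probit = .qf_log_probit(restricted),
    logistic = .qf_logistic(),
    probit = .qf_probit(),
    dichotomous_hill = .qf_dhill(restricted)
  )
  f$family <- family
  f$degree <- degree
  f$restricted <- isTRUE(restricted)
  f
}

# ---- individual families ------------------------------------------------

.qf_multistage <- function(k, restricted) {
  prob <- function(par, d) {
    g <- par[1]; b <- par[-1]
    S <- outer(d, seq_len(k), "^") %*% b
    as.vector(g + (1 - g) * (1 - exp(-S)))
  }
  list(
    par_names = c("g", paste0("b", seq_len(k))),
    bounds = list(lower = c(0, rep(if (restricted) 0 else -200, k)),
                  upper = c(1, rep(200, k))),
    structural = c(list(c(0, 1)),
                   rep(list(if (restricted) 0 else numeric(0)), k)),
    penalize_prob = !restricted,
    prob = prob,
    bmd = function(par, bmrf) {
      C <- -log1p(-bmrf)
      b <- par[-1]
      while (length(b) > 1 && abs(b[length(b)]) < 1e-14) b <- b[-length(b)]
      if (all(abs(b) < 1e-14)) return(NA_real_)
      r <- polyroot(c(-C, b))
      r <- Re(r)[abs(Im(r)) < 1e-7 * (1 + abs(Re(r))) & Re(r) > 1e-12]
      if (!length(r)) NA_real_ else min(r)
    },
    starts = function(x, y, n) {
      e <- .q_emp(x, y, n)
      z <- -log(.clamp((1 - e$pobs) / (1 - e$g0), 1e-6, 1))
      X <- outer(x, seq_len(k), "^")
      b0 <- tryCatch(qr.solve(X[-1, , drop = FALSE], z[-1]),
                     error = function(e2) rep(0.5, k))
      if (restricted) b0 <- pmax(b0, 1e-3)
      out <- list()
      for (f in c(1, 0.3, 3, 0.1)) for (gf in c(1, 0.5)) {
        out[[length(out) + 1]] <- c(e$g0 * gf, b0 * f)
      }
      out
    },
    profile_reduce = function(par) par[-2],
    profile_expand = function(red, B, bmrf) {
      C <- -log1p(-bmrf)
      brest <- if (k >= 2) red[-1] else numeric(0)
      b1 <- (C - if (k >= 2) sum(brest * B^(2:k)) else 0) / B
      pen <- if (restricted && b1 < 0) 1e6 * b1^2 else 0
      list(par = c(red[1], b1, brest), pen = pen)
    },
    profile_bounds = function(bounds) {
      list(lower = bounds$lower[-2], upper = bounds$upper[-2])
    },
    profile_starts = function(red_hat, B, bmrf) {
      # redistribute the benchmark response mass C = sum_i b_i B^i across
      # the higher-order coefficients; b1 picks up the remainder
      if (k < 2) return(list())
      C <- -log1p(-bmrf)
      ws <- list(c(1, 0), c(0, 1), c(0.5, 0.5), c(0.3, 0.7), c(0.8, 0.2))
      out <- list()
      for (w in ws) {
        b <- C * w[seq_len(k - 1)] / B^(2:k)
        out[[length(out) + 1]] <- c(red_hat[1], b)
      }
      out
    },
    unscale = function(par, dmax) c(par[1], par[-1] / dmax^seq_len(k))
  )
}

.qf_quantal_linear <- function() {
  list(
    par_names = c("g", "b"),
    bounds = list(lower = c(0, 1e-9), upper = c(1, 1e4)),
    structural = list(c(0, 1), numeric(0)),
    penalize_prob = FALSE,
    prob = function(par, d) par[1] + (1 - par[1]) * (-expm1(-par[2] * d)),
    bmd = function(par, bmrf) -log1p(-bmrf) / par[2],
    starts = function(x, y, n) {
      e <- .q_emp(x, y, n)
      mid <- max(2, which.max(x > 0))
      b0 <- -log1p(-e$er[mid]) / x[mid]
      lapply(c(1, 0.3, 3, 10, 0.03), function(f) c(e$g0, b0 * f))
    },
    profile_reduce = function(par) par[1],
    profile_expand = function(red, B, bmrf) {
      list(par = c(red, -log1p(-bmrf) / B), pen = 0)
    },
    profile_bounds = function(bounds) {
      list(lower = bounds$lower[1], upper = bounds$upper[1])
    },
    unscale = function(par, dmax) c(par[1], par[2] / dmax)
  )
}

.qf_weibull <- function(restricted) {
  a_lo <- if (restricted) 1 else 0.2
  prob <- function(par, d) {
    g <- par[1]; a <- par[2]; b <- par[3]
    s <- ifelse(d > 0, pmin(exp(log(b) + a * log(d)), 700), 0)
    g + (1 - g) * (-expm1(-s))
  }
  list(
    par_names = c("g", "a", "b"),
    bounds = list(lower = c(0, a_lo, 1e-9), upper = c(1, 18, 1e4)),
    structural = list(c(0, 1), c(a_lo, 18), numeric(0)),
    penalize_prob = FALSE,
    prob = prob,
    bmd = function(par, bmrf) (-log1p(-bmrf) / par[3])^(1 / par[2]),
    starts = function(x, y, n) {
      e <- .q_emp(x, y, n)
      co <- .q_logreg(log(-log1p(-e$er)), x)
      a0 <- .clamp(co["b"], a_lo, 18)
      b0 <- .clamp(exp(co["a"]), 1e-8, 1e3)
      out <- list()
      for (af in c(1, 0.6, 1.8)) for (bf in c(1, 0.3, 3)) {
        out[[length(out) + 1]] <- c(e$g0, .clamp(a0 * af, a_lo, 18), b0 * bf)
      }
      out[1:8]
    },
    profile_reduce = function(par) par[-3],
    profile_expand = function(red, B, bmrf) {
      list(par = c(red, -log1p(-bmrf) / B^red[2]), pen = 0)
    },
    profile_bounds = function(bounds) {
      list(lower = bounds$lower[-3], upper = bounds$upper[-3])
    },
    unscale = function(par, dmax) c(par[1], par[2], par[3] / dmax^par[2])
  )
}

.qf_gamma <- function(restricted) {
  a_lo <- if (restricted) 1 else 0.2
  list(
    par_names = c("g", "a", "b"),
    bounds = list(lower = c(0, a_lo, 1e-9), upper = c(1, 18, 1e4)),
    structural = list(c(0, 1), c(a_lo, 18), numeric(0)),
    penalize_prob = FALSE,
    prob = function(par, d) par[1] + (1 - par[1]) * pgamma(par[3] * d, shape = par[2]),
    bmd = function(par, bmrf) qgamma(bmrf, shape = par[2]) / par[3],
    starts = function(x, y, n) {
      e <- .q_emp(x, y, n)
      mid <- max(2, which.max(x > 0))
      out <- list()
      for (a0 in unique(.clamp(c(1, 2, 0.5, 4), a_lo, 18))) {
        b0 <- qgamma(e$er[mid], shape = a0) / x[mid]
        for (bf in c(1, 0.3, 3)) out[[length(out) + 1]] <- c(e$g0, a0, b0 * bf)
      }
      out[seq_len(min(9, length(out)))]
    },
    profile_reduce = function(par) par[-3],
    profile_expand = function(red, B, bmrf) {
      list(par = c(red, qgamma(bmrf, shape = red[2]) / B), pen = 0)
    },
    profile_bounds = function(bounds) {
      list(lower = bounds$lower[-3], upper = bounds$upper[-3])
    },
    unscale = function(par, dmax) c(par[1], par[2], par[3] / dmax)
  )
}

.qf_log_logistic <- function(restricted) {
  b_lo <- if (restricted) 1 else 1e-9
  list(
    par_names = c("g", "a", "b"),
    bounds = list(lower = c(0, -40, b_lo), upper = c(1, 40, 18)),
    structural = list(c(0, 1), numeric(0),
                      c(if (restricted) 1 else numeric(0), 18)),
    penalize_prob = FALSE,
    prob = function(par, d) {
      p <- par[1] + (1 - par[1]) * plogis(par[2] + par[3] * log(pmax(d, 1e-300)))
      ifelse(d <= 0, par[1], p)
    },
    bmd = function(par, bmrf) exp((qlogis(bmrf) - par[2]) / par[3]),
    starts = function(x, y, n) {
      e <- .q_emp(x, y, n)
      co <- .q_logreg(qlogis(e$er), x)
      b0 <- .clamp(co["b"], max(b_lo, 0.2), 18)
      out <- list()
      for (bf in c(1, 0.5, 2, 4)) for (gf in c(1, 0.5)) {
        b <- .clamp(b0 * bf, b_lo, 18)
        out[[length(out) + 1]] <- c(e$g0 * gf, co["a"], b)
      }
      out
    },
    profile_reduce = function(par) par[-2],
    profile_expand = function(red, B, bmrf) {
      list(par = c(red[1], qlogis(bmrf) - red[2] * log(B), red[2]), pen = 0)
    },
    profile_bounds = function(bounds) {
      list(lower = bounds$lower[-2], upper = bounds$upper[-2])
    },
    unscale = function(par, dmax) c(par[1], par[2] - par[3] * log(dmax), par[3])
  )
}

.qf_log_probit <- function(restricted) {
  b_lo <- if (restricted) 1 else 1e-9
  list(
    par_names = c("g", "a", "b"),
    bounds = list(lower = c(0, -30, b_lo), upper = c(1, 30, 18)),
    structural = list(c(0, 1), numeric(0),
                      c(if (restricted) 1 else numeric(0), 18)),
    penalize_prob = FALSE,
    prob = function(par, d) {
      p <- par[1] + (1 - par[1]) * pnorm(par[2] + par[3] * log(pmax(d, 1e-300)))
      ifelse(d <= 0, par[1], p)
    },
    bmd = function(par, bmrf) exp((qnorm(bmrf) - par[2]) / par[3]),
    starts = function(x, y, n) {
      e <- .q_emp(x, y, n)
      co <- .q_logreg(qnorm(e$er), x)
      b0 <- .clamp(co["b"], max(b_lo, 0.2), 18)
      out <- list()
      for (bf in c(1, 0.5, 2, 4)) for (gf in c(1, 0.5)) {
        b <- .clamp(b0 * bf, b_lo, 18)
        out[[length(out) + 1]] <- c(e$g0 * gf, co["a"], b)
      }
      out
    },
    profile_reduce = function(par) par[-2],
    profile_expand = function(red, B, bmrf) {
      list(par = c(red[1], qnorm(bmrf) - red[2] * log(B), red[2]), pen = 0)
    },
    profile_bounds = function(bounds) {
      list(lower = bounds$lower[-2], upper = bounds$upper[-2])
    },
    unscale = function(par, dmax) c(par[1], par[2] - par[3] * log(dmax), par[3])
  )
}

# extra risk of the background-free logistic/probit families, computed with
# upper tails so it stays accurate far out in the tail
.bglink_er <- function(a, bB, S) 1 - S(a + bB) / S(a)

.qf_bglink <- function(F, Q, S, a_rng) {
  # logistic/probit share everything except the link
  list(
    par_names = c("a", "b"),
    bounds = list(lower = c(a_rng[1], 1e-9), upper = c(a_rng[2], 200)),
    structural = list(numeric(0), numeric(0)),
    penalize_prob = FALSE,
    prob = function(par, d) F(par[1] + par[2] * d),
    bmd = function(par, bmrf) {
      q <- F(par[1]) + bmrf * (1 - F(par[1]))
      (Q(q) - par[1]) / par[2]
    },
    starts = function(x, y, n) {
      e <- .q_emp(x, y, n)
      co <- stats::coef(stats::lm(Q(e$pobs) ~ x))
      a0 <- unname(co[1]); b0 <- max(unname(co[2]), 0.2)
      out <- list()
      for (bf in c(1, 0.3, 3, 0.1)) for (as_ in c(a0, a0 - 1)) {
        out[[length(out) + 1]] <- c(as_, b0 * bf)
      }
      out
    },
    profile_reduce = function(par) par[2],
    profile_expand = function(red, B, bmrf) {
      b <- red[1]
      fr <- function(a) .bglink_er(a, b * B, S) - bmrf
      lo <- a_rng[1] + 1e-6; hi <- a_rng[2] - 1e-6
      flo <- fr(lo); fhi <- fr(hi)
      if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NULL)
      a <- uniroot(fr, c(lo, hi), tol = 1e-10)$root
      list(par = c(a, b), pen = 0)
    },
    profile_bounds = function(bounds) {
      list(lower = bounds$lower[2], upper = bounds$upper[2])
    },
    unscale = function(par, dmax) c(par[1], par[2] / dmax)
  )
}

.qf_logistic <- function() {
  .qf_bglink(plogis, qlogis, function(z) plogis(z, lower.tail = FALSE), c(-40, 40))
}

.qf_probit <- function() {
  .qf_bglink(pnorm, qnorm, function(z) pnorm(z, lower.tail = FALSE), c(-30, 30))
}

.qf_dhill <- function(restricted) {
  b_lo <- if (restricted) 1 else 1e-9
  list(
    par_names = c("g", "v", "a", "b"),
    bounds = list(lower = c(0, 1e-9, -40, b_lo), upper = c(1, 1, 40, 18)),
    structural = list(c(0, 1), 1, numeric(0),
                      c(if (restricted) 1 else numeric(0), 18)),
    penalize_prob = FALSE,
    prob = function(par, d) {
      g <- par[1]; v <- par[2]
      p <- g + v * (1 - g) * plogis(par[3] + par[4] * log(pmax(d, 1e-300)))
      ifelse(d <= 0, g, p)
    },
    bmd = function(par, bmrf) {
      if (par[2] <= bmrf) return(NA_real_)
      exp((qlogis(bmrf / par[2]) - par[3]) / par[4])
    },
    starts = function(x, y, n) {
      e <- .q_emp(x, y, n)
      v0 <- .clamp(max(e$er) + 0.1, 0.15, 1)
      co <- .q_logreg(qlogis(.clamp(e$er / v0, 0.01, 0.99)), x)
      b0 <- .clamp(co["b"], max(b_lo, 0.2), 18)
      out <- list()
      for (bf in c(1, 0.5, 2, 4)) for (vf in c(1, 0.8)) {
        out[[length(out) + 1]] <-
          c(e$g0, .clamp(v0 * vf, 0.05, 1), co["a"], .clamp(b0 * bf, b_lo, 18))
      }
      out
    },
    profile_reduce = function(par) par[-3],
    profile_expand = function(red, B, bmrf) {
      v <- red[2]
      if (v <= bmrf * (1 + 1e-9)) return(NULL)
      a <- qlogis(bmrf / v) - red[3] * log(B)
      list(par = c(red[1], v, a, red[3]), pen = 0)
    },
    profile_bounds = function(bounds) {
      lo <- bounds$lower[-3]; hi <- bounds$upper[-3]
      list(lower = lo, upper = hi)
    },
    unscale = function(par, dmax) c(par[1], par[2], par[3] - par[4] * log(dmax), par[4])
  )
}
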