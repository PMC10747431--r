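# broom-style tidiers for fitted dose-response models and recommendations

#' Tidy a fitted dose-response model
#'
#' @param x A `quantal_fit` or `continuous_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate` (on the
#'   original dose/response scale) and `on_bound` (whether the estimate sits
#'   on a restriction bound and is therefore not counted as estimated).
#' @export
tidy.bmd_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    return(tibble::tibble(term = character(0), estimate = numeric(0),
                          on_bound = logical(0)))
  }
  out <- tibble::tibble(term = names(x$params),
                        estimate = unname(x$params),
                        on_bound = unname(x$params_on_bound))
  if (inherits(x, "continuous_fit")) {
    out <- dplyr::bind_rows(out, tibble::tibble(term = "sigma2",
                                                estimate = x$sigma2,
                                                on_bound = FALSE))
  }
  out
}

#' One-row summary of a fitted dose-response model
#'
#' @param x A `quantal_fit` or `continuous_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `family`, `degree`, `restricted`,
#'   `loglik`, `n_params`, `aic`, `p_value`, `gof_df`, `bmd`, `bmdl`,
#'   `flags`.
#' @export
glance.bmd_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, family = x$family, degree = x$degree,
    restricted = x$restricted,
    loglik = x$loglik %||% NA_real_,
    n_params = as.integer(x$n_params %||% NA_integer_),
    aic = x$aic %||% NA_real_,
    p_value = x$gof$p_value %||% NA_real_,
    gof_df = as.integer(x$gof$df %||% NA_integer_),
    bmd = x$bmd %||% NA_real_, bmdl = x$bmdl %||% NA_real_,
    flags = paste(x$flags, collapse = ";")
  )
}

#' Per-group observed and fitted values of a quantal fit
#'
#' @param x A `quantal_fit`.
#' @param ... Unused.
#' @return A tibble with `dose`, `n`, `affected`, `observed` (proportion),
#'   `fitted` (probability), `expected` (count) and `scaled_residual`.
#' @export
augment.quantal_fit <- function(x, ...) {
  d <- tibble::as_tibble(x$data)
  p <- predict(x)
  tibble::tibble(
    dose = d$dose, n = d$n, affected = d$affected,
    observed = d$affected / d$n, fitted = p, expected = d$n * p,
    scaled_residual = x$gof$residuals
  )
}

#' Per-group observed and fitted means of a continuous fit
#'
#' @param x A `continuous_fit`.
#' @param ... Unused.
#' @return A tibble with `dose`, `n`, `mean`, `sd`, `fitted` and
#'   `scaled_residual` (`(mean - fitted) / (sd / sqrt(n))`).
#' @export
augment.continuous_fit <- function(x, ...) {
  d <- tibble::as_tibble(x$data)
  tibble::tibble(
    dose = d$dose, n = d$n, mean = d$mean, sd = d$sd,
    fitted = predict(x),
    scaled_residual = x$gof$residuals
  )
}

#' @export
tidy.bmd_recommendation <- function(x, ...) {
  out <- dplyr::select(x$table, "model", "family", "degree", "restricted",
                       "loglik", "n_params", "aic", "p_value", "gof_df",
                       "bmd", "bmdl", "classification")
  out$recommended <- out$model == (x$recommended %||% NA_character_) &
    !is.na(x$recommended)
  tibble::as_tibble(out)
}

#' @export
glance.bmd_recommendation <- function(x, ...) {
  tibble::tibble(
    label = x$label %||% NA_character_,
    n_models = nrow(x$table),
    n_viable = sum(x$table$classification == "viable"),
    recommended = x$recommended,
    rationale = x$rationale,
    bmd = x$bmd, bmdl = x$bmdl
  )
}

#' @export
tidy.uf_ledger <- function(x, ...) x$components

#' @export
tidy.risk_assessment <- function(x, ...) {
  rows <- tibble::tibble(
    quantity = c("pod", "composite_uf", "adi", "acceptable_daily_amount"),
    value = c(x$pod, x$ledger$composite, x$adi, x$acceptable_daily_amount),
    units = c("ug/kg bw/day", "", "ug/kg bw/day", "ug/day")
  )
  if (!is.null(x$mrl)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      quantity = "mrl", value = x$mrl, units = "ug/kg food"))
  }
  if (!is.null(x$exposures)) {
    rows <- dplyr::bind_rows(
      rows,
      tibble::tibble(quantity = paste0("exposure_", names(x$exposures)),
                     value = unname(x$exposures), units = "ug/kg bw/day"),
      tibble::tibble(quantity = paste0("moe_", names(x$exposures)),
                     value = unname(x$moe), units = "")
    )
  }
  rows
}
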