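# Viability classification and model recommendation, following the
# frequentist recommendation logic of the EPA BMDS software: a model is
# unusable when it did not converge or has no BMD/BMDL, questionable when
# the goodness-of-fit p-value is below 0.10 (or undefined because the model
# saturates the dose groups), when the BMD or BMDL falls more than 10-fold
# below the lowest positive dose, or when a scaled residual exceeds 2 in
# absolute value; viable otherwise. BMDs above the highest dose are
# reported as warnings, not disqualifiers.

.p_floor <- 0.10
.low_dose_ratio <- 10
.residual_limit <- 2

#' Classify a single fit as viable, questionable or unusable
#'
#' @param fit A `bmd_fit`.
#' @param config A [bmd_config()]; defaults to the fit's own.
#' @return A list with `classification` (`"viable"`, `"questionable"` or
#'   `"unusable"`), `reasons` and `warnings` (character vectors).
#' @export
classify_fit <- function(fit, config = NULL) {
  stopifnot(inherits(fit, "bmd_fit"))
  config <- config %||% fit$config
  reasons <- character(0)
  warnings <- character(0)

  if (!isTRUE(fit$converged)) {
    return(list(classification = "unusable", reasons = "did not converge",
                warnings = warnings))
  }
  if (is.na(fit$bmd) || is.na(fit$bmdl)) {
    return(list(classification = "unusable",
                reasons = "BMD or BMDL could not be computed",
                warnings = warnings))
  }

  lowest_pos <- min(fit$data$dose[fit$data$dose > 0])
  highest <- max(fit$data$dose)
  pv <- fit$gof$p_value

  if (is.na(pv)) {
    reasons <- c(reasons, "goodness-of-fit p-value undefined (0 degrees of freedom)")
  } else if (pv < .p_floor) {
    reasons <- c(reasons, sprintf("goodness-of-fit p-value %.3g < %.2f", pv, .p_floor))
  }
  if (fit$bmd < lowest_pos / .low_dose_ratio) {
    reasons <- c(reasons, sprintf("BMD more than %d-fold below the lowest positive dose",
                                  .low_dose_ratio))
  }
  if (fit$bmdl < lowest_pos / .low_dose_ratio) {
    reasons <- c(reasons, sprintf("BMDL more than %d-fold below the lowest positive dose",
                                  .low_dose_ratio))
  }
  resid <- fit$gof$residuals
  if (any(!is.finite(resid)) ||
      any(abs(resid) > .residual_limit, na.rm = TRUE)) {
    reasons <- c(reasons, sprintf("|scaled residual| > %g", .residual_limit))
  }

  if ("bmd_above_highest_dose" %in% fit$flags) {
    warnings <- c(warnings, sprintf("BMD above the highest dose (%g)", highest))
  }
  if ("bmdl_above_highest_dose" %in% fit$flags) {
    warnings <- c(warnings, sprintf("BMDL above the highest dose (%g)", highest))
  }

  list(classification = if (length(reasons)) "questionable" else "viable",
       reasons = reasons, warnings = warnings)
}

#' Classify every fit in a model suite
#'
#' Adds `classification`, `reasons` and `warnings` columns to the tibble
#' returned by [fit_quantal_suite()] or [fit_continuous_suite()].
#'
#' @param suite A suite tibble with a `fit` list column.
#' @param config A [bmd_config()]; defaults to each fit's own.
#' @return The suite tibble with three extra columns.
#' @export
classify_fits <- function(suite, config = NULL) {
  stopifnot(is.data.frame(suite), "fit" %in% names(suite))
  cls <- purrr::map(suite$fit, classify_fit, config = config)
  suite$classification <- purrr::map_chr(cls, "classification")
  suite$reasons <- purrr::map(cls, "reasons")
  suite$warnings <- purrr::map(cls, "warnings")
  suite
}

# fixed family order used as the final tie-break
.family_order <- c("dichotomous_hill", "gamma", "log_logistic", "log_probit",
                   "logistic", "multistage", "probit", "quantal_linear",
                   "weibull", "exponential3", "exponential5", "hill",
                   "linear", "polynomial", "power")

#' Recommend one model from a classified suite
#'
#' Implements the standard recommendation rule: among the viable models, if
#' the BMDLs span a sufficiently narrow range (largest / smallest at most
#' `config$narrow_ratio`, 3 by default), the model with the lowest AIC is
#' recommended; otherwise the model with the lowest BMDL. Ties on the
#' deciding criterion are broken by the lowest BMDL, then by a fixed family
#' order. With a single viable model that model is recommended; with none,
#' no model is recommended.
#'
#' @param suite A suite tibble; classified with [classify_fits()] first if
#'   the classification columns are absent.
#' @param config A [bmd_config()] (for `narrow_ratio`); defaults to the
#'   first fit's config.
#' @param label Endpoint label for the report; defaults to the data label.
#' @return An object of class `bmd_recommendation`: a list with `label`,
#'   `table` (the classified suite), `recommended` (model label or `NA`),
#'   `rationale` (`"lowest_aic"`, `"lowest_bmdl"`, `"only_viable"` or
#'   `"none_viable"`), `bmd`, `bmdl` and `warnings`.
#' @examples
#' \donttest{
#' d <- quantal_data(c(0, 75, 150, 300), rep(50, 4), c(8, 18, 19, 18))
#' recommend_model(fit_quantal_suite(d))
#' }
#' @export
recommend_model <- function(suite, config = NULL, label = NULL) {
  stopifnot(is.data.frame(suite), "fit" %in% names(suite), nrow(suite) >= 1)
  if (!"classification" %in% names(suite)) suite <- classify_fits(suite, config)
  config <- config %||% suite$fit[[1]]$config
  label <- label %||% endpoint_label(suite$fit[[1]]$data)

  ord <- order(match(suite$family, .family_order), suite$degree,
               !suite$restricted)
  suite <- suite[ord, ]
  viable <- dplyr::filter(suite, .data$classification == "viable")

  if (nrow(viable) == 0) {
    rec <- list(label = label, table = suite, recommended = NA_character_,
                rationale = "none_viable", bmd = NA_real_, bmdl = NA_real_,
                warnings = character(0))
  } else {
    if (nrow(viable) == 1) {
      pick <- 1L
      rationale <- "only_viable"
    } else {
      ratio <- max(viable$bmdl) / min(viable$bmdl)
      if (ratio <= config$narrow_ratio) {
        rationale <- "lowest_aic"
        key <- viable$aic
      } else {
        rationale <- "lowest_bmdl"
        key <- viable$bmdl
      }
      near <- which(key <= min(key) + 1e-9)
      pick <- near[which.min(viable$bmdl[near])]
    }
    row <- viable[pick, ]
    rec <- list(label = label, table = suite, recommended = row$model,
                rationale = rationale, bmd = row$bmd, bmdl = row$bmdl,
                warnings = row$warnings[[1]])
  }
  structure(rec, class = "bmd_recommendation")
}

#' @export
print.bmd_recommendation <- function(x, ...) {
  cat("<bmd_recommendation>", if (!is.na(x$label %||% NA)) x$label else "", "\n")
  tab <- dplyr::select(x$table, "model", "p_value", "aic", "bmd", "bmdl",
                       "classification")
  print(tibble::as_tibble(tab), n = nrow(tab))
  if (is.na(x$recommended)) {
    cat("No viable model; nothing recommended.\n")
  } else {
    cat(sprintf("Recommended: %s (%s)  BMD %.4g  BMDL %.4g\n",
                x$recommended, sub("_", " ", x$rationale), x$bmd, x$bmdl))
    if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  }
  invisible(x)
}
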