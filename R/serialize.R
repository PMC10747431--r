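# Report serialization: tabular (TSV) and JSON views of fitted model suites

#' Tabular report of a fitted model suite
#'
#' A table shaped like the result tables of a BMD analysis: model,
#' goodness-of-fit p-value, AIC, BMD, BMDL (and classification when
#' present). `digits = "display"` applies the conventional report rounding
#' (p-values and AIC to 2 decimals, BMD/BMDL to the nearest integer dose);
#' the default keeps full precision.
#'
#' @param suite A tibble from [fit_quantal_suite()] /
#'   [fit_continuous_suite()], optionally classified.
#' @param digits `"full"` (default) or `"display"`.
#' @return A tibble.
#' @export
fit_report <- function(suite, digits = c("full", "display")) {
  digits <- match.arg(digits)
  cols <- intersect(c("model", "p_value", "aic", "bmd", "bmdl",
                      "classification"), names(suite))
  out <- tibble::as_tibble(suite[, cols])
  out$flags <- purrr::map_chr(suite$flags, paste, collapse = ";")
  if (digits == "display") {
    out$p_value <- round(out$p_value, 2)
    out$aic <- round(out$aic, 2)
    out$bmd <- round(out$bmd)
    out$bmdl <- round(out$bmdl)
  }
  out
}

#' Write a fitted model suite to TSV or JSON
#'
#' TSV carries the [fit_report()] table; JSON carries one record per model
#' including the parameter estimates.
#'
#' @inheritParams fit_report
#' @param path Output path.
#' @param format `"tsv"` or `"json"`; guessed from the file extension by
#'   default.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(suite, path, format = NULL,
                             digits = c("full", "display")) {
  format <- format %||% (if (grepl("\\.json$", path, TRUE)) "json" else "tsv")
  if (format == "tsv") {
    readr::write_tsv(fit_report(suite, digits), path, progress = FALSE)
  } else {
    recs <- purrr::map(suite$fit, fit_to_list)
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

# plain-list view of a fit, used for JSON serialization
fit_to_list <- function(fit) {
  list(
    model = fit$model, family = fit$family,
    degree = if (is.na(fit$degree)) NULL else fit$degree,
    restricted = fit$restricted, converged = fit$converged,
    params = as.list(fit$params %||% list()),
    loglik = fit$loglik, n_params = fit$n_params, aic = fit$aic,
    gof = fit$gof[c("statistic", "df", "p_value")],
    bmd = fit$bmd, bmdl = fit$bmdl, flags = as.list(fit$flags)
  )
}
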