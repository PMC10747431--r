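#' Benchmark dose analysis settings
#'
#' Bundles the knobs of a BMD analysis: the benchmark response factor, the
#' confidence level of the lower limit, the risk type, and the conventions
#' used when fitting a whole model suite. The defaults are the standard
#' frequentist settings for quantal data (extra risk of 10%, one-sided 95%
#' lower limit); continuous endpoints use a 10% relative deviation from the
#' control mean instead (`risk_type = "relative_deviation"`).
#'
#' @param risk_type How the benchmark response is defined: `"extra_risk"`
#'   for quantal data, `(p(d) - p(0)) / (1 - p(0))`; `"relative_deviation"`
#'   for continuous data, `|m(d) - m(0)| / |m(0)|`.
#' @param bmrf Benchmark response factor, a fraction in (0, 1). Default 0.1.
#' @param confidence Confidence level of the one-sided lower limit (BMDL),
#'   in (0.5, 1). Default 0.95.
#' @param adverse_direction Direction of the adverse change for continuous
#'   endpoints: `"down"` (e.g. body weight) or `"up"`.
#' @param narrow_ratio Ratio of largest to smallest viable BMDL below which
#'   the viable models are considered to span a "sufficiently narrow range",
#'   so the recommendation falls to the lowest AIC rather than the lowest
#'   BMDL. Default 3.
#' @param max_degree Cap on the multistage/polynomial degree. The degree
#'   actually used for a dataset is one less than its number of dose groups
#'   (control included), but never more than this cap. Default 3.
#' @param bmd_bracket_factor BMDs are only reported up to this multiple of
#'   the highest observed dose; beyond it the BMD is undefined rather than
#'   extrapolated. Default 10.
#' @param distribution,variance Continuous-response distribution and
#'   variance model. Only `"normal"` with `"constant"` variance is
#'   implemented.
#'
#' @return An object of class `bmd_config` (a named list).
#' @examples
#' bmd_config()
#' bmd_config(risk_type = "relative_deviation", adverse_direction = "down")
#' @export
bmd_config <- function(risk_type = c("extra_risk", "relative_deviation"),
                       bmrf = 0.1,
                       confidence = 0.95,
                       adverse_direction = c("down", "up"),
                       narrow_ratio = 3,
                       max_degree = 3L,
                       bmd_bracket_factor = 10,
                       distribution = "normal",
                       variance = "constant") {
  risk_type <- match.arg(risk_type)
  adverse_direction <- match.arg(adverse_direction)
  if (!is.numeric(bmrf) || length(bmrf) != 1 || bmrf <= 0 || bmrf >= 1) {
    abort("`bmrf` must be a single fraction in (0, 1).")
  }
  if (!is.numeric(confidence) || length(confidence) != 1 ||
      confidence <= 0.5 || confidence >= 1) {
    abort("`confidence` must be a single fraction in (0.5, 1).")
  }
  if (!identical(distribution, "normal") || !identical(variance, "constant")) {
    abort("Only the normal distribution with constant variance is implemented.")
  }
  if (narrow_ratio < 1) abort("`narrow_ratio` must be >= 1.")
  max_degree <- as.integer(max_degree)
  if (max_degree < 1) abort("`max_degree` must be a positive integer.")
  structure(
    list(
      risk_type = risk_type,
      bmrf = bmrf,
      confidence = confidence,
      adverse_direction = adverse_direction,
      narrow_ratio = narrow_ratio,
      max_degree = max_degree,
      bmd_bracket_factor = bmd_bracket_factor,
      distribution = distribution,
      variance = variance
    ),
    class = "bmd_config"
  )
}

#' @export
print.bmd_config <- function(x, ...) {
  cat("<bmd_config>\n")
  cat(sprintf("  risk type:         %s\n", x$risk_type))
  cat(sprintf("  BMRF:              %g\n", x$bmrf))
  cat(sprintf("  confidence:        %g (one-sided lower limit)\n", x$confidence))
  cat(sprintf("  adverse direction: %s\n", x$adverse_direction))
  cat(sprintf("  narrow BMDL ratio: %g\n", x$narrow_ratio))
  cat(sprintf("  max degree:        %d\n", x$max_degree))
  invisible(x)
}

# default config for a dataset kind when the user passes NULL
.default_config <- function(data) {
  if (inherits(data, "continuous_data")) {
    bmd_config(risk_type = "relative_deviation", adverse_direction = "down")
  } else {
    bmd_config(risk_type = "extra_risk")
  }
}

#' Maximum multistage or polynomial degree for a dataset
#'
#' One less than the number of dose groups (control included), capped by the
#' configured maximum (3 by default).
#'
#' @param data A `quantal_data` or `continuous_data` object.
#' @param config A [bmd_config()].
#' @return An integer degree >= 1.
#' @export
max_model_degree <- function(data, config = NULL) {
  config <- config %||% .default_config(data)
  max(1L, min(nrow(data) - 1L, config$max_degree))
}
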