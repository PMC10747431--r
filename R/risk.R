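# Deterministic risk-assessment arithmetic: from a point of departure (POD)
# through an uncertainty-factor ledger to the acceptable daily intake (ADI),
# and on to maximum residue levels (MRL), margins of exposure (MOE) and
# exposure unit conversions. All values are plain products and quotients of
# doubles; any rounding is presentation-only.

#' Uncertainty-factor ledger
#'
#' Collects the multiplicative safety factors applied to a point of
#' departure, e.g. 100 for inter/intraspecies extrapolation, 2 for using a
#' LOAEL instead of a NOAEL, 5 for severity of the effect and study
#' deficiencies. The composite factor is their exact product.
#'
#' @param ... Named positive factors, e.g.
#'   `uf_ledger(interspecies_intraspecies = 100, severity = 5)`.
#' @return An object of class `uf_ledger` with `components` (a tibble of
#'   label and factor) and `composite`.
#' @examples
#' uf_ledger(interspecies_intraspecies = 100, severity = 5)
#' @export
uf_ledger <- function(...) {
  fac <- c(...)
  if (!length(fac)) abort("At least one uncertainty factor is required.")
  if (is.null(names(fac)) || any(names(fac) == "")) {
    abort("Every uncertainty factor must be named.")
  }
  if (!is.numeric(fac) || any(fac <= 0)) {
    abort("Uncertainty factors must be positive numbers.")
  }
  structure(
    list(components = tibble::tibble(label = names(fac), factor = unname(fac)),
         composite = prod(fac)),
    class = "uf_ledger"
  )
}

#' @export
print.uf_ledger <- function(x, ...) {
  cat("<uf_ledger> composite =", x$composite, "\n")
  for (i in seq_len(nrow(x$components))) {
    cat(sprintf("  %-32s %g\n", x$components$label[i], x$components$factor[i]))
  }
  invisible(x)
}

#' Acceptable daily intake from a point of departure
#'
#' `ADI = POD / composite uncertainty factor`, in the POD's units
#' (conventionally ug/kg bw/day).
#'
#' @param pod Point of departure (> 0), e.g. a BMDL converted to
#'   ug/kg bw/day.
#' @param ledger A [uf_ledger()], or a single composite factor >= 1.
#' @return The ADI in the same units as `pod`.
#' @examples
#' derive_adi(8000, uf_ledger(interspecies_intraspecies = 100, severity = 5))
#' @export
derive_adi <- function(pod, ledger) {
  if (!is.numeric(pod) || pod <= 0) abort("`pod` must be > 0.")
  composite <- if (inherits(ledger, "uf_ledger")) ledger$composite else ledger
  if (!is.numeric(composite) || composite < 1) {
    abort("The composite uncertainty factor must be >= 1.")
  }
  pod / composite
}

#' Maximum residue level from an acceptable daily intake
#'
#' Back-calculates the permitted residue concentration in a food commodity:
#' `MRL = allocation * ADI * body_weight / daily_food_intake`, i.e. the
#' residue level at which eating `daily_food_intake` kg of the commodity per
#' day exhausts the allocated share of the total acceptable intake.
#'
#' @param adi Acceptable daily intake (ug/kg bw/day, > 0).
#' @param body_weight Consumer body weight in kg (default 60, the JECFA
#'   convention; EFSA uses 70).
#' @param daily_food_intake Daily intake of the commodity in kg/day (> 0).
#' @param allocation Fraction of the acceptable intake allocated to this
#'   commodity, in (0, 1].
#' @return MRL in ug per kg of food.
#' @examples
#' derive_mrl(16, body_weight = 60, daily_food_intake = 0.3, allocation = 0.4)
#' @export
derive_mrl <- function(adi, body_weight = 60, daily_food_intake, allocation) {
  if (adi <= 0 || body_weight <= 0) abort("`adi` and `body_weight` must be > 0.")
  if (daily_food_intake <= 0) abort("`daily_food_intake` must be > 0.")
  if (allocation <= 0 || allocation > 1) abort("`allocation` must be in (0, 1].")
  allocation * adi * body_weight / daily_food_intake
}

#' Exposure unit conversions
#'
#' `per_capita_to_per_kg()` converts a per-capita daily amount (ug/day) to a
#' body-weight-normalized dose (ug/kg bw/day); `per_kg_to_per_capita()` is
#' the inverse, e.g. the total acceptable daily amount implied by an ADI.
#'
#' @param amount Per-capita amount in ug/day.
#' @param amount_per_kg Dose in ug/kg bw/day.
#' @param body_weight Body weight in kg (> 0), default 60.
#' @return The converted value.
#' @examples
#' per_capita_to_per_kg(117, 60)   # 1.95
#' per_kg_to_per_capita(16, 60)    # 960
#' @export
per_capita_to_per_kg <- function(amount, body_weight = 60) {
  if (any(body_weight <= 0)) abort("`body_weight` must be > 0.")
  amount / body_weight
}

#' @rdname per_capita_to_per_kg
#' @export
per_kg_to_per_capita <- function(amount_per_kg, body_weight = 60) {
  if (any(body_weight <= 0)) abort("`body_weight` must be > 0.")
  amount_per_kg * body_weight
}

#' Total exposure from components
#'
#' Sums exposure components on a common scale (ug/kg bw/day), e.g. dietary
#' plus consumer-product exposure.
#'
#' @param components Numeric vector of exposure components (>= 0).
#' @return Their sum.
#' @examples
#' total_exposure(c(food = 1.95, consumer_products = 0.4))
#' @export
total_exposure <- function(components) {
  if (any(components < 0)) abort("Exposure components must be >= 0.")
  sum(components)
}

#' Margin of exposure
#'
#' The ratio between the point of departure and the estimated exposure
#' level, on a common dose scale.
#'
#' @param pod Point of departure (ug/kg bw/day).
#' @param exposure Estimated exposure (ug/kg bw/day, > 0).
#' @return `pod / exposure`.
#' @examples
#' margin_of_exposure(8000, 2.35)
#' @export
margin_of_exposure <- function(pod, exposure) {
  if (any(exposure <= 0)) abort("`exposure` must be > 0.")
  pod / exposure
}

#' Full risk assessment from a point of departure
#'
#' Chains the risk arithmetic: composite uncertainty factor, ADI, the total
#' acceptable per-capita amount, an MRL for a food commodity (when intake
#' and allocation are given), exposure totals per region/source and margins
#' of exposure.
#'
#' @param pod Point of departure in ug/kg bw/day (> 0).
#' @param pod_type Provenance of the POD: `"bmdl"`, `"loael"` or `"noael"`.
#' @param ledger A [uf_ledger()].
#' @param body_weight Body weight in kg (default 60).
#' @param exposures Named numeric vector of exposure components or totals in
#'   ug/kg bw/day (optional).
#' @param daily_food_intake,allocation MRL inputs (optional; both or
#'   neither).
#' @return An object of class `risk_assessment` with fields `pod`,
#'   `pod_type`, `ledger`, `adi`, `acceptable_daily_amount`, `mrl`,
#'   `exposures`, `moe` and the inputs.
#' @examples
#' assess_risk(8000, "bmdl",
#'             uf_ledger(interspecies_intraspecies = 100, severity = 5),
#'             exposures = c(europe = 2.35, usa = 1.12),
#'             daily_food_intake = 0.3, allocation = 0.4)
#' @export
assess_risk <- function(pod, pod_type = c("bmdl", "loael", "noael"), ledger,
                        body_weight = 60, exposures = NULL,
                        daily_food_intake = NULL, allocation = NULL) {
  pod_type <- match.arg(pod_type)
  stopifnot(inherits(ledger, "uf_ledger"))
  adi <- derive_adi(pod, ledger)
  mrl <- NULL
  if (!is.null(daily_food_intake) || !is.null(allocation)) {
    if (is.null(daily_food_intake) || is.null(allocation)) {
      abort("Provide both `daily_food_intake` and `allocation`, or neither.")
    }
    mrl <- derive_mrl(adi, body_weight, daily_food_intake, allocation)
  }
  moe <- if (!is.null(exposures)) margin_of_exposure(pod, exposures) else NULL
  structure(
    list(pod = pod, pod_type = pod_type, ledger = ledger, adi = adi,
         body_weight = body_weight,
         acceptable_daily_amount = per_kg_to_per_capita(adi, body_weight),
         daily_food_intake = daily_food_intake, allocation = allocation,
         mrl = mrl, exposures = exposures, moe = moe),
    class = "risk_assessment"
  )
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat("<risk_assessment>\n")
  cat(sprintf("  POD (%s):          %g ug/kg bw/day\n", toupper(x$pod_type), x$pod))
  cat(sprintf("  composite UF:        %g\n", x$ledger$composite))
  cat(sprintf("  ADI:                 %g ug/kg bw/day\n", x$adi))
  cat(sprintf("  acceptable amount:   %g ug/day (at %g kg bw)\n",
              x$acceptable_daily_amount, x$body_weight))
  if (!is.null(x$mrl)) {
    cat(sprintf("  MRL:                 %g ug/kg food (%g%% allocation, %g kg/day)\n",
                x$mrl, 100 * x$allocation, x$daily_food_intake))
  }
  if (!is.null(x$exposures)) {
    for (nm in names(x$exposures)) {
      cat(sprintf("  exposure %-10s  %g ug/kg bw/day  (MOE %.4g)\n",
                  nm, x$exposures[[nm]], x$moe[[nm]]))
    }
  }
  invisible(x)
}

#' Read a risk-assessment configuration and run it
#'
#' Reads a YAML (or JSON) file with fields `pod`, `pod_type`,
#' `uncertainty_factors` (a named map), and optionally `body_weight`,
#' `exposures` (named map), `daily_food_intake`, `allocation`, then calls
#' [assess_risk()].
#'
#' @param path Path to a YAML or JSON file.
#' @return A `risk_assessment` object.
#' @export
read_assessment <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  for (req in c("pod", "pod_type", "uncertainty_factors")) {
    if (is.null(cfg[[req]])) abort(sprintf("Missing field `%s` in %s.", req, path))
  }
  ledger <- do.call(uf_ledger, as.list(unlist(cfg$uncertainty_factors)))
  assess_risk(
    pod = cfg$pod, pod_type = cfg$pod_type, ledger = ledger,
    body_weight = cfg$body_weight %||% 60,
    exposures = if (!is.null(cfg$exposures)) unlist(cfg$exposures) else NULL,
    daily_food_intake = cfg$daily_food_intake,
    allocation = cfg$allocation
  )
}
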