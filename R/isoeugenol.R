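# Bundled isoeugenol endpoints (NTP gavage studies) and the end-to-end
# case-study pipeline built on them.

.iso_endpoints <- tibble::tibble(
  name = c("adenoma", "carcinoma", "adenoma_carcinoma",
           "histiocytic_sarcoma", "thymoma", "mammary_carcinoma",
           "olfactory_atrophy_female", "olfactory_atrophy_male",
           "body_weight"),
  kind = c(rep("quantal", 8), "continuous"),
  file = c("hepatocellular_adenoma_mouse_male_2yr.csv",
           "hepatocellular_carcinoma_mouse_male_2yr.csv",
           "hepatocellular_adenoma_carcinoma_mouse_male_2yr.csv",
           "histiocytic_sarcoma_mouse_female_2yr.csv",
           "thymoma_rat_male_2yr.csv",
           "mammary_gland_carcinoma_rat_male_2yr.csv",
           "olfactory_atrophy_rat_female_3mo.csv",
           "olfactory_atrophy_rat_male_3mo.csv",
           "body_weight_rat_male_3mo.csv"),
  label = c("hepatocellular adenoma (male mice, 2 yr)",
            "hepatocellular carcinoma (male mice, 2 yr)",
            "hepatocellular adenoma and carcinoma combined (male mice, 2 yr)",
            "histiocytic sarcoma (female mice, 2 yr)",
            "thymoma (male rats, 2 yr)",
            "mammary gland carcinoma (male rats, 2 yr)",
            "atrophied olfactory epithelium (female rats, 3 mo)",
            "atrophied olfactory epithelium (male rats, 3 mo)",
            "terminal body weight (male rats, 3 mo)")
)

#' Bundled isoeugenol study endpoints
#'
#' The summarized dose-response endpoints of the NTP isoeugenol gavage
#' studies that ship with the package: neoplastic liver lesions, other
#' neoplastic lesions with a positive trend, nose lesions and terminal body
#' weight. `isoeugenol_endpoints()` lists them;
#' `isoeugenol_endpoint(name)` loads one as a validated dataset.
#'
#' @param name One of the names listed by `isoeugenol_endpoints()`.
#' @return A tibble of endpoints, or a [quantal_data()] /
#'   [continuous_data()] object.
#' @examples
#' isoeugenol_endpoints()
#' isoeugenol_endpoint("adenoma")
#' @export
isoeugenol_endpoints <- function() .iso_endpoints

#' @rdname isoeugenol_endpoints
#' @export
isoeugenol_endpoint <- function(name) {
  row <- .iso_endpoints[.iso_endpoints$name == name, ]
  if (nrow(row) != 1) {
    abort(sprintf("Unknown endpoint `%s`; see isoeugenol_endpoints().", name))
  }
  path <- system.file("extdata", row$file, package = "benchdose",
                      mustWork = TRUE)
  if (row$kind == "quantal") {
    read_quantal(path, label = row$label)
  } else {
    read_continuous(path, label = row$label)
  }
}

#' End-to-end isoeugenol case study
#'
#' Reproduces the benchmark-dose case study the package was validated
#' against: each bundled endpoint is fitted with the model chosen in that
#' assessment (with the documented dose-group exclusions: the 300 mg/kg
#' bw/day group dropped from the combined liver endpoint, the 37.5 and 75
#' mg/kg bw/day groups dropped from body weight), and the liver-adenoma
#' BMDL is carried through the risk arithmetic to the ADI, MRL and margins
#' of exposure.
#'
#' @param compute_bmdl Set `FALSE` to skip the profile BMDLs (faster).
#' @return A list with `bmd_table` (one row per endpoint: model, BMD, BMDL,
#'   published BMDL for comparison, flags) and `risk` (a
#'   [assess_risk()] object driven by the computed adenoma BMDL).
#' @examples
#' \donttest{
#' cs <- isoeugenol_case_study()
#' cs$bmd_table
#' cs$risk
#' }
#' @export
isoeugenol_case_study <- function(compute_bmdl = TRUE) {
  plan <- tibble::tribble(
    ~name, ~family, ~degree, ~restricted, ~drop, ~published_bmdl,
    "adenoma", "multistage", 2L, FALSE, list(NULL), 8,
    "carcinoma", "multistage", 2L, FALSE, list(NULL), 18,
    "adenoma_carcinoma", "gamma", NA_integer_, TRUE, list(300), 8,
    "histiocytic_sarcoma", "multistage", 3L, TRUE, list(NULL), 239,
    "thymoma", "multistage", 3L, TRUE, list(NULL), 307,
    "mammary_carcinoma", "multistage", 3L, TRUE, list(NULL), 311,
    "olfactory_atrophy_female", "log_probit", NA_integer_, FALSE, list(NULL), 5,
    "body_weight", "power", NA_integer_, FALSE, list(c(37.5, 75)), 372
  )
  rows <- purrr::pmap(plan, function(name, family, degree, restricted, drop,
                                     published_bmdl) {
    data <- isoeugenol_endpoint(name)
    if (!is.null(drop[[1]])) data <- drop_dose_groups(data, drop[[1]])
    deg <- if (is.na(degree)) NULL else degree
    fit <- if (inherits(data, "quantal_data")) {
      fit_quantal(data, family, degree = deg, restricted = restricted,
                  compute_bmdl = compute_bmdl)
    } else {
      fit_continuous(data, family, degree = deg, restricted = restricted,
                     compute_bmdl = compute_bmdl)
    }
    tibble::tibble(endpoint = endpoint_label(data), model = fit$model,
                   bmd = fit$bmd, bmdl = fit$bmdl,
                   published_bmdl = published_bmdl,
                   flags = paste(fit$flags, collapse = ";"))
  })
  bmd_table <- dplyr::bind_rows(rows)

  # the POD is the adenoma BMDL rounded to the nearest integer mg/kg bw/day
  # (the reporting convention), converted to ug
  pod <- 1000 * round(bmd_table$bmdl[bmd_table$endpoint ==
                                       "hepatocellular adenoma (male mice, 2 yr)"])
  risk <- if (length(pod) == 1 && is.finite(pod)) {
    assess_risk(
      pod = pod, pod_type = "bmdl",
      ledger = uf_ledger(interspecies_intraspecies = 100,
                         severity_and_study_deficiencies = 5),
      body_weight = 60,
      exposures = c(europe = 2.35, usa = 1.12),
      daily_food_intake = 0.3, allocation = 0.4
    )
  } else {
    NULL
  }
  list(bmd_table = bmd_table, risk = risk)
}
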