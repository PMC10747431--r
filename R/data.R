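#' Summarized quantal (incidence) dose-response data
#'
#' Builds a validated dose-response dataset of dose groups with the number of
#' animals examined and the number affected, the data shape of the incidence
#' tables in toxicology bioassay reports. Groups are sorted by ascending dose;
#' a control group (dose 0) is required.
#'
#' @param dose Dose per group (e.g. mg/kg bw/day), non-negative, no
#'   duplicates, exactly one zero (the control).
#' @param n Animals examined per group (positive integers).
#' @param affected Animals with the lesion per group (non-negative integers,
#'   at most `n`).
#' @param label Optional endpoint label carried through reports.
#'
#' @return A tibble of class `quantal_data` with columns `dose`, `n`,
#'   `affected`, sorted by dose.
#' @examples
#' quantal_data(
#'   dose = c(0, 75, 150, 300),
#'   n = rep(50, 4),
#'   affected = c(24, 35, 37, 33),
#'   label = "hepatocellular adenoma"
#' )
#' @export
quantal_data <- function(dose, n, affected, label = NULL) {
  .check_doses(dose, lengths = list(n = n, affected = affected))
  n <- .check_count(n, "n", min = 1)
  affected <- .check_count(affected, "affected", min = 0)
  bad <- which(affected > n)
  if (length(bad)) {
    abort(sprintf("`affected` exceeds `n` in row %d (%g > %g).",
                  bad[1], affected[bad[1]], n[bad[1]]))
  }
  dose <- as.numeric(dose)
  affected <- as.numeric(affected)
  ord <- order(dose)
  out <- tibble::tibble(dose = dose[ord], n = n[ord], affected = affected[ord])
  .as_dose_response(out, "quantal_data", label)
}

#' Summarized continuous dose-response data
#'
#' Dose groups with group size, mean response and standard deviation (e.g.
#' terminal body weights). Groups are sorted by ascending dose; a control
#' group (dose 0) is required and all standard deviations must be positive.
#'
#' @param dose Dose per group; non-negative, no duplicates, exactly one zero.
#' @param n Group sizes (positive integers).
#' @param mean Group mean responses (response units, e.g. grams).
#' @param sd Group standard deviations (same units, strictly positive).
#' @param label Optional endpoint label.
#'
#' @return A tibble of class `continuous_data` with columns `dose`, `n`,
#'   `mean`, `sd`, sorted by dose.
#' @examples
#' continuous_data(
#'   dose = c(0, 150, 300, 600),
#'   n = rep(10, 4),
#'   mean = c(352, 336, 326, 307),
#'   sd = c(8, 7, 6, 7),
#'   label = "terminal body weight"
#' )
#' @export
continuous_data <- function(dose, n, mean, sd, label = NULL) {
  .check_doses(dose, lengths = list(n = n, mean = mean, sd = sd))
  n <- .check_count(n, "n", min = 1)
  if (!is.numeric(mean)) abort("`mean` must be numeric.")
  if (!is.numeric(sd)) abort("`sd` must be numeric.")
  bad <- which(!is.finite(sd) | sd <= 0)
  if (length(bad)) {
    abort(sprintf("`sd` must be > 0; offending row %d (sd = %g).",
                  bad[1], sd[bad[1]]))
  }
  dose <- as.numeric(dose)
  mean <- as.numeric(mean)
  sd <- as.numeric(sd)
  ord <- order(dose)
  out <- tibble::tibble(dose = dose[ord], n = n[ord],
                        mean = mean[ord], sd = sd[ord])
  .as_dose_response(out, "continuous_data", label)
}

.as_dose_response <- function(tbl, cls, label) {
  structure(tbl,
            class = c(cls, "dose_response_data", class(tbl)),
            label = label %||% NA_character_)
}

.check_doses <- function(dose, lengths) {
  if (!is.numeric(dose) || length(dose) < 3) {
    abort("At least 3 dose groups are required.")
  }
  for (nm in names(lengths)) {
    if (length(lengths[[nm]]) != length(dose)) {
      abort(sprintf("`%s` must have the same length as `dose`.", nm))
    }
  }
  bad <- which(!is.finite(dose) | dose < 0)
  if (length(bad)) {
    abort(sprintf("Doses must be finite and >= 0; offending row %d (dose = %g).",
                  bad[1], dose[bad[1]]))
  }
  if (anyDuplicated(dose)) {
    d <- dose[duplicated(dose)][1]
    abort(sprintf("Duplicate dose value %g.", d))
  }
  if (sum(dose == 0) != 1) {
    abort("Exactly one control group (dose 0) is required.")
  }
  invisible(dose)
}

.check_count <- function(x, nm, min) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < min) ||
      any(x != round(x))) {
    bad <- which(!is.finite(x) | x < min | x != round(x))[1]
    abort(sprintf("`%s` must be integers >= %d; offending row %s.",
                  nm, min, bad %||% "?"))
  }
  as.numeric(x)
}

#' Endpoint label of a dataset or fit
#'
#' @param x A dose-response dataset or a fitted model.
#' @return A length-one character (possibly `NA`).
#' @export
endpoint_label <- function(x) {
  if (inherits(x, "bmd_fit")) attr(x$data, "label") else attr(x, "label")
}

#' @export
print.dose_response_data <- function(x, ...) {
  kind <- if (inherits(x, "quantal_data")) "quantal" else "continuous"
  lab <- attr(x, "label")
  cat(sprintf("<%s dose-response data>%s\n", kind,
              if (is.na(lab)) "" else paste0(" ", lab)))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Read summarized dose-response data from CSV
#'
#' Reads a comma-separated file with a header row into a validated dataset.
#' Column names default to `dose`, `n`, `affected` (quantal) or `dose`, `n`,
#' `mean`, `sd` (continuous); pass `dialect` to map other headers, e.g.
#' `c(dose = "Dose", affected = "Incidence")` for NTP-style exports.
#'
#' @param path Path to a CSV file.
#' @param dialect Named character vector mapping the standard column names to
#'   the names used in the file. Unmapped columns keep the standard name.
#' @param label Optional endpoint label; defaults to the file name.
#' @return A [quantal_data()] or [continuous_data()] object.
#' @export
read_quantal <- function(path, dialect = NULL, label = NULL) {
  df <- .read_dr_csv(path, dialect, c("dose", "n", "affected"))
  quantal_data(df$dose, df$n, df$affected,
               label = label %||% .path_label(path))
}

#' @rdname read_quantal
#' @export
read_continuous <- function(path, dialect = NULL, label = NULL) {
  df <- .read_dr_csv(path, dialect, c("dose", "n", "mean", "sd"))
  continuous_data(df$dose, df$n, df$mean, df$sd,
                  label = label %||% .path_label(path))
}

.path_label <- function(path) sub("\\.[^.]*$", "", basename(path))

.read_dr_csv <- function(path, dialect, cols) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  wanted <- setNames(cols, cols)
  if (!is.null(dialect)) {
    unknown <- setdiff(names(dialect), cols)
    if (length(unknown)) {
      abort(sprintf("Unknown dialect entries: %s", paste(unknown, collapse = ", ")))
    }
    wanted[names(dialect)] <- dialect
  }
  missing <- wanted[!wanted %in% names(df)]
  if (length(missing)) {
    abort(sprintf("Missing column(s) in %s: %s", basename(path),
                  paste(missing, collapse = ", ")))
  }
  out <- df[, unname(wanted)]
  names(out) <- names(wanted)
  for (nm in names(out)) {
    if (!is.numeric(out[[nm]])) {
      abort(sprintf("Column `%s` (file column `%s`) is not numeric.",
                    nm, wanted[[nm]]))
    }
  }
  out
}

#' Write summarized dose-response data to CSV
#'
#' Writes the same dialect [read_quantal()] and [read_continuous()] read, so
#' a write/read cycle round-trips the dataset exactly.
#'
#' @param data A dose-response dataset.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(data, path) {
  stopifnot(inherits(data, "dose_response_data"))
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Serialize a dataset to JSON (and back)
#'
#' @param data A dose-response dataset.
#' @param json A JSON string produced by `dose_response_json()`.
#' @return `dose_response_json()` returns a JSON string;
#'   `dose_response_from_json()` the reconstructed dataset.
#' @export
dose_response_json <- function(data) {
  stopifnot(inherits(data, "dose_response_data"))
  kind <- if (inherits(data, "quantal_data")) "quantal" else "continuous"
  jsonlite::toJSON(
    c(list(kind = kind, label = attr(data, "label")),
      as.list(tibble::as_tibble(data))),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
}

#' @rdname dose_response_json
#' @export
dose_response_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  lab <- if (is.null(x$label)) NULL else x$label
  if (identical(x$kind, "quantal")) {
    quantal_data(x$dose, x$n, x$affected, label = lab)
  } else {
    continuous_data(x$dose, x$n, x$mean, x$sd, label = lab)
  }
}

#' Drop non-control dose groups
#'
#' Removes the given dose groups from a dataset, e.g. to omit the highest
#' dose group when no model fits the full design adequately, or to exclude
#' low dose levels without a dose-response relationship. The control group
#' can never be dropped and at least three groups must remain.
#'
#' @param data A dose-response dataset.
#' @param drop Numeric vector of dose values to remove (possibly empty).
#' @return A dataset of the same kind without those groups.
#' @examples
#' d <- quantal_data(c(0, 75, 150, 300), rep(50, 4), c(28, 43, 43, 43))
#' drop_dose_groups(d, 300)
#' @export
drop_dose_groups <- function(data, drop) {
  stopifnot(inherits(data, "dose_response_data"))
  if (!length(drop)) return(data)
  if (any(drop == 0)) abort("The control group (dose 0) cannot be dropped.")
  missing <- setdiff(drop, data$dose)
  if (length(missing)) {
    abort(sprintf("Dose value(s) not in the dataset: %s",
                  paste(missing, collapse = ", ")))
  }
  keep <- !(data$dose %in% drop)
  if (sum(keep) < 3) abort("At least 3 dose groups must remain.")
  out <- tibble::as_tibble(data)[keep, ]
  .as_dose_response(out,
                    if (inherits(data, "quantal_data")) "quantal_data" else "continuous_data",
                    attr(data, "label"))
}
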