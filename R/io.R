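#' Read a pesticide record table from CSV
#'
#' Expects a comma-delimited file (decimal point ".") with header columns
#' `name`, `persistency_days`, `aeq`, `ld50_ug_per_bee`, `likely_exposure`,
#' `mrl_mg_per_kg`; `aeq` may be omitted or left blank row-wise when a
#' `dose_ml_per_ha` column is present, in which case AEQ is computed from the
#' dose and LD50. Parsing is strict: a missing column, an empty cell or a
#' non-numeric cell is an error naming the offending row and column.
#'
#' @param path Path to the CSV file.
#' @param compute_aeq Fill missing AEQ values from doses (default `TRUE`).
#' @return A tibble of validated pesticide records.
#' @export
read_pesticide_table <- function(path, compute_aeq = TRUE) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path),
                 class = "beesafe_validation_error")
  }
  data <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  )
  if (nrow(data) == 0) {
    rlang::abort(sprintf("no records in %s", path),
                 class = "beesafe_validation_error")
  }
  required <- c("name", "persistency_days", "ld50_ug_per_bee",
                "likely_exposure", "mrl_mg_per_kg")
  missing_cols <- setdiff(required, names(data))
  has_dose <- "dose_ml_per_ha" %in% names(data)
  if (!"aeq" %in% names(data) && !has_dose) {
    missing_cols <- c(missing_cols, "aeq (or dose_ml_per_ha)")
  }
  if (length(missing_cols)) {
    rlang::abort(sprintf("missing column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 class = "beesafe_validation_error")
  }

  numeric_cols <- intersect(
    c("persistency_days", "aeq", "ld50_ug_per_bee", "likely_exposure",
      "mrl_mg_per_kg", "dose_ml_per_ha"),
    names(data))
  for (col in numeric_cols) {
    raw <- data[[col]]
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(parsed))
    if (length(bad)) {
      rlang::abort(sprintf("non-numeric value '%s' in column '%s', row %d",
                           raw[bad[1]], col, bad[1]),
                   class = "beesafe_validation_error")
    }
    # blanks are only tolerated in aeq (when a dose can fill them) and dose
    blank <- which(is.na(raw) | raw == "")
    optional <- col %in% c("aeq", "dose_ml_per_ha")
    if (length(blank) && !optional) {
      rlang::abort(sprintf("empty cell in column '%s', row %d", col, blank[1]),
                   class = "beesafe_validation_error")
    }
    data[[col]] <- parsed
  }
  if (anyNA(data$name) || any(data$name == "")) {
    rlang::abort("empty cell in column 'name'",
                 class = "beesafe_validation_error")
  }
  if (!"aeq" %in% names(data)) data$aeq <- NA_real_
  if (compute_aeq && anyNA(data$aeq)) {
    if (!has_dose) {
      rlang::abort(
        sprintf("empty cell in column 'aeq', row %d (no dose column to fill it)",
                which(is.na(data$aeq))[1]),
        class = "beesafe_validation_error")
    }
    data <- add_aeq(data)
  }
  data
}

#' Write assessment results
#'
#' `write_assessment_csv()` writes the flat per-record table (name, safety
#' level point, aggregate degrees, oracle score, verification value).
#' `format_assessment()` renders an aligned-text report for the console or a
#' log file.
#'
#' @param x A `safety_assessment` from [assess()].
#' @param path Output file path.
#' @return The path, invisibly (`write_assessment_csv`); a character vector
#'   of report lines (`format_assessment`).
#' @export
write_assessment_csv <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' @rdname write_assessment_csv
#' @export
format_assessment <- function(x) {
  header <- sprintf("%-16s %12s %8s %10s %9s", "pesticide", "safety_point",
                    "safe", "not_safe", "verified")
  rows <- sprintf("%-16s %12.2f %8.3f %10.3f %9d", x$name,
                  x$safety_level_point, x$safe, x$not_safe,
                  x$verification_value)
  c(header, rows)
}
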