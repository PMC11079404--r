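#' Assess pesticide environmental safety
#'
#' The full pipeline per record: clamp the five crisp inputs to their
#' universes, fuzzify them against the model's membership functions, run
#' Mamdani inference over the weighted rule base, and defuzzify the
#' aggregated consequent by the centroid method onto the 0-10 safety scale.
#' Every record is also scored by the closed-form centroid oracle
#' ([centroid_oracle()]), and the two paths are compared at 2 decimal places
#' (`verification_value` 1 when they agree), mirroring the manual
#' verification calculation.
#'
#' @param data A data frame of pesticide records: a `name` column plus the
#'   five parameter columns (`persistency_days`, `aeq`, `ld50_ug_per_bee`,
#'   `likely_exposure`, `mrl_mg_per_kg` for the default model). A missing
#'   `aeq` is computed from `dose_ml_per_ha` when present.
#' @param model A [safety_model()]; defaults to the calibrated model.
#' @param step Output-universe discretization step for the coded centroid.
#' @param rank Sort results by descending score (ties keep input order)?
#' @param quiet Suppress input-clamping warnings.
#' @return A tibble of class `safety_assessment`, one row per record:
#'   `name`, `safety_level_point` (score rounded to 2 dp), `score` (raw),
#'   `safe` and `not_safe` aggregate degrees, `oracle_score`, and
#'   `verification_value`. The fired-rule trace and the clamped inputs are
#'   attached as attributes and exposed through [tidy()].
#' @examples
#' assess(load_fixture("pesticides"), quiet = TRUE)
#' @export
assess <- function(data, model = default_model(), step = 0.01, rank = TRUE,
                   quiet = FALSE) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) {
    rlang::abort("no records to assess", class = "beesafe_validation_error")
  }
  if (!"name" %in% names(data)) {
    data$name <- as.character(seq_len(nrow(data)))
  }
  if ("dose_ml_per_ha" %in% names(data)) data <- add_aeq(data)
  validate_records(data, model)

  clamped <- clamp_inputs(data, model, quiet = quiet)
  fuzzy <- fuzzify(clamped, model)
  agg <- infer(fuzzy, model, trace = TRUE)

  agg$score <- purrr::map2_dbl(agg$safe, agg$not_safe,
                               ~ defuzzify_centroid(.x, .y, model, step))
  agg$oracle_score <- purrr::map2_dbl(agg$safe, agg$not_safe,
                                      ~ centroid_oracle(.x, .y, model))
  out <- tibble::tibble(
    name = agg$name,
    safety_level_point = round_half_up(agg$score, 2),
    score = agg$score,
    safe = agg$safe,
    not_safe = agg$not_safe,
    oracle_score = agg$oracle_score,
    verification_value = as.integer(round_half_up(agg$score, 2) ==
                                    round_half_up(agg$oracle_score, 2))
  )
  ord <- if (rank) order(-out$score, seq_len(nrow(out))) else seq_len(nrow(out))
  out <- out[ord, ]
  structure(out,
            trace = attr(agg, "trace"), inputs = clamped, step = step,
            class = c("safety_assessment", class(out)))
}

validate_records <- function(data, model) {
  for (par in model$parameters) {
    col <- par$column
    if (!col %in% names(data)) {
      rlang::abort(sprintf("missing required column '%s'", col),
                   class = "beesafe_validation_error")
    }
    bad <- which(is.na(data[[col]]) | !is.finite(data[[col]]))
    if (length(bad)) {
      rlang::abort(
        sprintf("empty or non-finite '%s' for record(s): %s", col,
                paste(data$name[bad], collapse = ", ")),
        class = "beesafe_validation_error")
    }
  }
  invisible(data)
}

# round-half-up at `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Verification report: coded centroid vs closed-form centroid
#'
#' Runs [assess()] and reformats the result as a parity table between the
#' discretized centroid ("result from code") and the exact closed-form
#' centroid ("result centroid calculation"), with a 1/0 verification value
#' per record for agreement at 2 decimal places.
#'
#' @inheritParams assess
#' @return A tibble: `name`, `centroid_calculation`, `code_result`,
#'   `verification_value`.
#' @export
verify <- function(data, model = default_model(), step = 0.01, quiet = FALSE) {
  res <- assess(data, model = model, step = step, rank = FALSE, quiet = quiet)
  tibble::tibble(
    name = res$name,
    centroid_calculation = round_half_up(res$oracle_score, 2),
    code_result = res$safety_level_point,
    verification_value = res$verification_value
  )
}

#' Tidy a safety assessment into its fired-rule trace
#'
#' @param x A `safety_assessment` from [assess()].
#' @param ... Unused.
#' @return A long tibble of every rule with activation > 0: the record name,
#'   the five antecedent categories, the rule's weighted score and
#'   consequent, and its activation degree.
#' @method tidy safety_assessment
#' @export
tidy.safety_assessment <- function(x, ...) {
  dplyr::bind_rows(attr(x, "trace"), .id = "name")
}

#' One-row assessment summary
#'
#' @param x A `safety_assessment` from [assess()].
#' @param ... Unused.
#' @return A one-row tibble: record count, best and worst options with their
#'   scores, and how many records passed centroid verification.
#' @method glance safety_assessment
#' @export
glance.safety_assessment <- function(x, ...) {
  best <- x$name[which.max(x$score)]
  worst <- x$name[which.min(x$score)]
  tibble::tibble(
    n = nrow(x),
    best_option = best,
    best_score = max(x$safety_level_point),
    worst_option = worst,
    worst_score = min(x$safety_level_point),
    n_verified = sum(x$verification_value)
  )
}
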