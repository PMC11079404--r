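#' Assemble a fuzzy safety model
#'
#' Bundles the fuzzy parameters, the expert weights, the generated rule base
#' and the output (consequent) membership functions into one object that the
#' assessment pipeline consumes.
#'
#' @param parameters Named list of [fuzzy_parameter()] objects (names are the
#'   parameter keys used in rule-base columns and fuzzification output).
#' @param weights An [expert_weights()] object whose parameter names match
#'   `names(parameters)`.
#' @param output List with `mfs` (named list with `not_safe` and `safe`
#'   membership functions) and `universe` (length-2 numeric).
#' @return An object of class `safety_model`.
#' @seealso [default_model()] for the calibrated five-parameter model.
#' @export
safety_model <- function(parameters, weights, output = default_output()) {
  if (is.null(names(parameters)) || anyDuplicated(names(parameters))) {
    rlang::abort("parameters must be a uniquely named list",
                 class = "beesafe_config_error")
  }
  for (p in parameters) stopifnot(inherits(p, "fuzzy_parameter"))
  if (!all(c("not_safe", "safe") %in% names(output$mfs))) {
    rlang::abort("output must define 'not_safe' and 'safe' membership functions",
                 class = "beesafe_config_error")
  }
  rules <- rule_base(parameters, weights)
  structure(
    list(parameters = parameters, weights = weights, rules = rules,
         output = output),
    class = "safety_model"
  )
}

default_output <- function() {
  list(mfs = list(not_safe = trapezoid_mf(0, 0, 3, 7),
                  safe = trapezoid_mf(3, 7, 10, 10)),
       universe = c(0, 10))
}

#' The calibrated five-parameter pesticide safety model
#'
#' Builds the default model: soil persistency (days), the agroecology
#' environment quality quotient (AEQ), honey-bee contact LD50 (ug/bee), the
#' bee exposure-likelihood score, and the maximum residue limit (mg/kg),
#' weighted by a two-expert panel. Persistency, AEQ and LD50 use
#' trapezoid/triangle membership families with a clear boundary between
#' categories; exposure likelihood and MRL use the smooth z/s saturation
#' pair. Category boundaries follow standard ecotoxicological
#' categorizations (e.g. non-persistent below 30 days; AEQ below 1 high
#' contamination; LD50 below 1 ug/bee highly toxic; MRL boundary 250 mg/kg);
#' interior breakpoints not fixed by a categorization are calibrated so that
#' neighbouring categories hand over smoothly (see the package vignette for
#' the calibration rationale).
#'
#' The symmetric output consequents on \[0, 10\] place the fully-not-safe
#' centroid at 79/30 (2.63) and the fully-safe centroid at 7.37, which bound
#' every attainable score.
#'
#' @param ratings Optional replacement expert rating matrix (parameters x
#'   experts); defaults to the bundled two-expert panel.
#' @return A [safety_model()].
#' @examples
#' m <- default_model()
#' nrow(m$rules)  # 108
#' @export
default_model <- function(ratings = NULL) {
  parameters <- list(
    persistency = fuzzy_parameter(
      name = "persistency", column = "persistency_days",
      universe = c(0, 200), units = "days",
      categories = c("non_persistent", "moderate_persistent", "persistent"),
      mfs = list(
        non_persistent = trapezoid_mf(0, 0, 30, 65),
        moderate_persistent = triangle_mf(15, 65, 150),
        persistent = trapezoid_mf(65, 100, 200, 200)
      ),
      codes = c(non_persistent = 0, moderate_persistent = 0.5, persistent = 1)
    ),
    aeq = fuzzy_parameter(
      name = "aeq", column = "aeq",
      universe = c(0, 20), units = "dimensionless",
      categories = c("low_contaminate", "moderate_contaminate",
                     "high_contaminate"),
      mfs = list(
        low_contaminate = trapezoid_mf(1.5, 2, 20, 20),
        moderate_contaminate = triangle_mf(0.5, 1.5, 2.5),
        high_contaminate = trapezoid_mf(0, 0, 1, 1.25)
      ),
      codes = c(low_contaminate = 0, moderate_contaminate = 0.5,
                high_contaminate = 1)
    ),
    ld50 = fuzzy_parameter(
      name = "ld50", column = "ld50_ug_per_bee",
      universe = c(0, 200), units = "ug/bee",
      categories = c("low_toxicity", "moderate_toxicity", "high_toxicity"),
      mfs = list(
        low_toxicity = trapezoid_mf(50.5, 100, 200, 200),
        moderate_toxicity = triangle_mf(0.5, 50.5, 125),
        high_toxicity = trapezoid_mf(0, 0, 1, 50.5)
      ),
      codes = c(low_toxicity = 0, moderate_toxicity = 0.5, high_toxicity = 1)
    ),
    exposure = fuzzy_parameter(
      name = "exposure", column = "likely_exposure",
      universe = c(0, 4), units = "likelihood score",
      categories = c("no_likely_exposure", "high_exposure"),
      mfs = list(
        no_likely_exposure = z_mf(1, 3),
        high_exposure = s_mf(1, 3)
      ),
      codes = c(no_likely_exposure = 0, high_exposure = 1)
    ),
    mrl = fuzzy_parameter(
      name = "mrl", column = "mrl_mg_per_kg",
      universe = c(0, 400), units = "mg/kg",
      categories = c("high_residue_limit", "low_residue_limit"),
      mfs = list(
        high_residue_limit = s_mf(100, 400),
        low_residue_limit = z_mf(100, 400)
      ),
      # a low legal tolerance flags the more hazardous compound
      codes = c(high_residue_limit = 0, low_residue_limit = 1)
    )
  )
  if (is.null(ratings)) ratings <- default_expert_ratings()
  safety_model(parameters, expert_weights(ratings))
}

default_expert_ratings <- function() {
  matrix(c(2, 3, 5, 4, 1,
           5, 3, 2, 1, 4),
         ncol = 2,
         dimnames = list(c("persistency", "aeq", "ld50", "exposure", "mrl"),
                         c("expert_1", "expert_2")))
}

#' @export
print.safety_model <- function(x, ...) {
  cat("<safety_model>", length(x$parameters), "parameters,",
      nrow(x$rules), "rules\n")
  for (p in x$parameters) print(p)
  cat(sprintf("weights: %s\n",
              paste(sprintf("%s=%.3f", names(x$parameters),
                            x$weights$weights[names(x$parameters)]),
                    collapse = ", ")))
  invisible(x)
}

#' Tidy a safety model into its rule base
#'
#' @param x A [safety_model()].
#' @param ... Unused.
#' @return The rule-base tibble (one row per rule).
#' @method tidy safety_model
#' @export
tidy.safety_model <- function(x, ...) x$rules

#' One-row model summary
#'
#' @param x A [safety_model()].
#' @param ... Unused.
#' @return A one-row tibble: parameter count, rule count, Safe/Not-Safe rule
#'   split, tie count, and the attainable score bounds.
#' @method glance safety_model
#' @export
glance.safety_model <- function(x, ...) {
  tibble::tibble(
    n_parameters = length(x$parameters),
    n_rules = nrow(x$rules),
    n_safe = sum(x$rules$consequent == "safe"),
    n_not_safe = sum(x$rules$consequent == "not_safe"),
    n_ties = sum(abs(x$rules$weighted_score - 0.5) < 1e-12),
    score_min = centroid_oracle(0, 1, x),
    score_max = centroid_oracle(1, 0, x)
  )
}
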