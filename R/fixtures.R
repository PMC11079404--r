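#' Bundled example data: a ten-pesticide assessment case study
#'
#' Small reference tables for a panel of ten common pesticides, used in the
#' examples, tests and vignette: the crisp assessment records, the field
#' doses the AEQ values derive from, the two-expert importance ratings
#' behind the default weights, and the reference safety scores with their
#' hand-calculated centroid cross-check.
#'
#' Available tables:
#' \describe{
#'   \item{`pesticides`}{name, persistency_days, aeq, ld50_ug_per_bee,
#'     likely_exposure, mrl_mg_per_kg for ten pesticides. Two values exceed
#'     their parameter universes on purpose (DDT's 2000-day half-life,
#'     iprodione's LD50 of 400 ug/bee) and exercise input clamping.}
#'   \item{`doses`}{name, dose_ml_per_ha — field doses used to derive AEQ.}
#'   \item{`expert_ratings`}{parameter, expert, rating — the 0-5 importance
#'     scales from the two-expert panel.}
#'   \item{`expected_scores`}{name, safety_level_point — reference safety
#'     scores for the ten records.}
#'   \item{`expected_oracle`}{name, centroid_calculation, code_result,
#'     verification_value — the reference parity check between the
#'     hand-calculated centroid and the coded pipeline.}
#' }
#'
#' The pesticide spelled "Methiodathion" in some listings is
#' normalized to "Methidathion" throughout.
#'
#' @param name One of `"pesticides"`, `"doses"`, `"expert_ratings"`,
#'   `"expected_scores"`, `"expected_oracle"`.
#' @return A tibble.
#' @examples
#' load_fixture("pesticides")
#' @export
load_fixture <- function(name) {
  pesticide_names <- c("Abamectin", "Dodine", "Dimethoate", "Clofentezine",
                       "Iprodione", "DDT", "Fenthion", "Acephate",
                       "Chlorpyrifos", "Methidathion")
  switch(name,
    pesticides = tibble::tibble(
      name = pesticide_names,
      persistency_days = c(28, 20, 7, 40, 14, 2000, 34, 3, 30, 7),
      aeq = c(0.002, 3.267, 0.0081, 6.06, 17.28, 0.198, 1.11, 0.117,
              0.00214, 0.025),
      ld50_ug_per_bee = c(0.03, 145, 0.12, 48, 400, 8.8, 0.22, 1.8,
                          0.072, 0.27),
      likely_exposure = c(3, 3, 3, 3, 3, 3, 3, 3, 3, 3),
      mrl_mg_per_kg = c(0.02, 5, 0.05, 0.05, 10, 0.2, 2, 1, 0.05, 0.5)
    ),
    doses = tibble::tibble(
      name = pesticide_names,
      dose_ml_per_ha = c(750, 2242, 750, 400, 1169, 2242, 10, 780, 1700,
                         535.117)
    ),
    expert_ratings = tibble::tibble(
      parameter = rep(c("persistency", "aeq", "ld50", "exposure", "mrl"), 2),
      expert = rep(c("expert_1", "expert_2"), each = 5),
      rating = c(2, 3, 5, 4, 1, 5, 3, 2, 1, 4)
    ),
    expected_scores = tibble::tibble(
      name = pesticide_names,
      safety_level_point = c(2.63, 7.37, 2.63, 5.44, 7.37, 2.75, 2.93,
                             2.65, 2.63, 2.63)
    ),
    expected_oracle = tibble::tibble(
      name = pesticide_names,
      centroid_calculation = c(2.63, 7.37, 2.63, 5.44, 7.37, 2.75, 2.93,
                               2.65, 2.63, 2.63),
      code_result = c(2.63, 7.37, 2.63, 5.44, 7.37, 2.75, 2.93, 2.65,
                      2.63, 2.63),
      verification_value = rep(1, 10)
    ),
    rlang::abort(sprintf("unknown fixture '%s'", name),
                 class = "beesafe_validation_error")
  )
}
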