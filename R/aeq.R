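#' Agroecology environment quality quotient (AEQ)
#'
#' The AEQ is the reciprocal of the honey-bee toxic unit: an indicator of
#' beehive fitness under contamination by a single pesticide. The chain is
#'
#' \deqn{concentration = dose \times fraction \times unit\_factor / colony}
#' \deqn{TU_{bee} = concentration / LD50_{bee}, \quad AEQ = 1 / TU_{bee}}
#'
#' where `dose` is the field application dose (mL/ha), `fraction` the share
#' of the applied pesticide that misses the target pests and reaches the
#' wider environment (default 0.99), `colony` the bee colony size (default
#' 50,000 individuals) and `ld50` the contact LD50 toward honey bees
#' (ug/bee). `unit_factor` (default 1000) converts the dose volume onto the
#' ug-scale per-bee concentration; it is exposed as a named constant because
#' it is a unit calibration, not a biological quantity. AEQ below 1 indicates
#' high contamination, 1-2 moderate, and 2 or above low/no contamination.
#'
#' @param dose Field dose in mL/ha. Must be positive.
#' @param ld50 Honey-bee contact LD50 in ug/bee. Must be positive.
#' @param fraction Off-target fraction in (0, 1\].
#' @param colony Bee colony size (individuals).
#' @param unit_factor Dose unit conversion factor.
#' @return `compute_aeq()` returns the dimensionless AEQ;
#'   `concentration_per_bee()` the per-bee exposure concentration;
#'   `toxic_unit()` the bee toxic unit.
#' @examples
#' compute_aeq(dose = 400, ld50 = 48)  # ~ 6.06
#' @export
compute_aeq <- function(dose, ld50, fraction = 0.99, colony = 50000,
                        unit_factor = 1000) {
  1 / toxic_unit(concentration_per_bee(dose, fraction, colony, unit_factor),
                 ld50)
}

#' @rdname compute_aeq
#' @export
concentration_per_bee <- function(dose, fraction = 0.99, colony = 50000,
                                  unit_factor = 1000) {
  check_positive(dose = dose, colony = colony, unit_factor = unit_factor)
  if (any(fraction <= 0 | fraction > 1)) {
    rlang::abort("fraction must lie in (0, 1]",
                 class = "beesafe_validation_error")
  }
  dose * fraction * unit_factor / colony
}

#' @rdname compute_aeq
#' @param concentration Per-bee exposure concentration.
#' @export
toxic_unit <- function(concentration, ld50) {
  check_positive(concentration = concentration, ld50 = ld50)
  concentration / ld50
}

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || anyNA(v) || any(v <= 0)) {
      rlang::abort(sprintf("'%s' must be strictly positive", nm),
                   class = "beesafe_validation_error")
    }
  }
  invisible(TRUE)
}

#' Add an AEQ column to a pesticide record table
#'
#' Computes AEQ for records where it is missing, from a `dose_ml_per_ha`
#' column and the honey-bee LD50; rows that already carry an AEQ value are
#' left untouched.
#'
#' @param data A data frame with columns `ld50_ug_per_bee` and
#'   `dose_ml_per_ha` (an existing `aeq` column may be partially filled).
#' @inheritParams compute_aeq
#' @return `data` as a tibble with a complete `aeq` column.
#' @export
add_aeq <- function(data, fraction = 0.99, colony = 50000, unit_factor = 1000) {
  data <- tibble::as_tibble(data)
  if (!"aeq" %in% names(data)) data$aeq <- NA_real_
  fill <- is.na(data$aeq)
  if (!any(fill)) return(data)
  if (!all(c("dose_ml_per_ha", "ld50_ug_per_bee") %in% names(data))) {
    rlang::abort(
      "computing AEQ needs columns dose_ml_per_ha and ld50_ug_per_bee",
      class = "beesafe_validation_error")
  }
  if (anyNA(data$dose_ml_per_ha[fill])) {
    rlang::abort("rows with missing AEQ must carry a dose_ml_per_ha value",
                 class = "beesafe_validation_error")
  }
  data$aeq[fill] <- compute_aeq(data$dose_ml_per_ha[fill],
                                data$ld50_ug_per_bee[fill],
                                fraction, colony, unit_factor)
  data
}
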