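#' Generate the weighted-threshold fuzzy rule base
#'
#' Enumerates every combination of parameter categories (the full Cartesian
#' product, e.g. 3 x 3 x 3 x 2 x 2 = 108 rules for the default five-parameter
#' model) and assigns each combination a consequent by the weighted score
#' \eqn{\sum_i p_i w_i}, where \eqn{p_i} is the categorization code of the
#' antecedent category (0 best, 1 worst) and \eqn{w_i} the parameter weight.
#' A rule is Not Safe when its score exceeds 0.5 and Safe otherwise; an exact
#' tie at 0.5 is Safe. With integer expert ratings the threshold comparison
#' is performed in exact integer arithmetic, so ties are detected reliably.
#'
#' Enumeration order is canonical: parameters in model order, categories
#' best-code-first, with the last parameter varying fastest.
#'
#' @param parameters A list of [fuzzy_parameter()] objects.
#' @param weights An [expert_weights()] object (or a named numeric vector
#'   summing to 1) aligned with the parameter names.
#' @return A tibble with one column per parameter holding the antecedent
#'   category label, plus `weighted_score` and `consequent`
#'   (`"safe"`/`"not_safe"`).
#' @export
rule_base <- function(parameters, weights) {
  w <- resolve_weights(weights, names(parameters))
  if (abs(sum(w$weights) - 1) > 1e-9) {
    rlang::abort("parameter weights must sum to 1",
                 class = "beesafe_config_error")
  }

  cats <- purrr::map(parameters, "categories")
  grid <- rev(expand.grid(rev(cats), stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE))
  names(grid) <- names(parameters)

  codes <- purrr::imap(parameters, function(par, nm) {
    unname(par$codes[grid[[nm]]])
  })
  code_mat <- do.call(cbind, codes)

  if (!is.null(w$numerators)) {
    # exact: 2*code is integer, so compare sum(2*code*num) with den
    total2 <- as.vector(code_mat %*% (2 * w$numerators))
    score <- total2 / (2 * w$denominator)
    not_safe <- round(total2) > w$denominator
  } else {
    score <- as.vector(code_mat %*% w$weights)
    not_safe <- score > 0.5 + 1e-12
  }

  out <- tibble::as_tibble(grid)
  out$weighted_score <- score
  out$consequent <- ifelse(not_safe, "not_safe", "safe")
  out
}

resolve_weights <- function(weights, param_names) {
  if (inherits(weights, "expert_weights")) {
    w <- weights$weights
    num <- weights$numerators
    den <- weights$denominator
  } else if (is.numeric(weights) && !is.null(names(weights))) {
    w <- weights
    num <- NULL
    den <- NULL
  } else {
    rlang::abort("weights must be an expert_weights object or a named numeric",
                 class = "beesafe_config_error")
  }
  if (!setequal(names(w), param_names)) {
    rlang::abort("weight names do not match the model parameters",
                 class = "beesafe_config_error")
  }
  ord <- match(param_names, names(w))
  list(weights = unname(w[ord]),
       numerators = if (!is.null(num)) unname(num[ord]) else NULL,
       denominator = den)
}
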