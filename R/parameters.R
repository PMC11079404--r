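#' Define a fuzzy assessment parameter
#'
#' A parameter (linguistic variable) couples a crisp input column with its
#' universe of discourse, its ordered categories, one membership function per
#' category, and the categorization codes used by the weighted rule-base
#' generator. Codes run from 0 (environmentally best category) to 1 (worst),
#' with 0.5 for the middle category of three-level parameters.
#'
#' @param name Human-readable parameter name.
#' @param column Column name expected in a pesticide record table.
#' @param universe Length-2 numeric, the admissible input range (inputs
#'   outside it are clamped, see [clamp_inputs()]).
#' @param units Unit string, for display only.
#' @param categories Character vector of category labels, ordered best first.
#' @param mfs Named list of [membership][membership] functions, one per category.
#' @param codes Named numeric vector of categorization codes per category;
#'   must be `0`/`0.5`/`1` for three categories and `0`/`1` for two.
#' @return An object of class `fuzzy_parameter`.
#' @export
fuzzy_parameter <- function(name, column, universe, units, categories, mfs, codes) {
  if (length(universe) != 2 || !is.numeric(universe) || universe[1] >= universe[2]) {
    rlang::abort("universe must be a numeric [min, max] with min < max",
                 class = "beesafe_config_error")
  }
  if (!setequal(names(mfs), categories) || !setequal(names(codes), categories)) {
    rlang::abort("mfs and codes must be named by the parameter categories",
                 class = "beesafe_config_error")
  }
  allowed <- if (length(categories) == 2) c(0, 1) else c(0, 0.5, 1)
  if (!setequal(unname(codes), allowed)) {
    rlang::abort(
      sprintf("codes for a %d-category parameter must be {%s}",
              length(categories), paste(allowed, collapse = ", ")),
      class = "beesafe_config_error"
    )
  }
  structure(
    list(name = name, column = column, universe = as.numeric(universe),
         units = units, categories = categories,
         mfs = mfs[categories], codes = codes[categories]),
    class = "fuzzy_parameter"
  )
}

#' @export
print.fuzzy_parameter <- function(x, ...) {
  cat(sprintf("<fuzzy_parameter> %s (%s), universe [%g, %g]\n",
              x$name, x$units, x$universe[1], x$universe[2]))
  for (cat_i in x$categories) {
    bp <- x$mfs[[cat_i]]$breakpoints
    cat(sprintf("  %-22s code %.1f  %s [%s]\n", cat_i, x$codes[[cat_i]],
                x$mfs[[cat_i]]$shape, paste(format(bp, trim = TRUE), collapse = ", ")))
  }
  invisible(x)
}

#' Clamp record values to each parameter's universe
#'
#' Inputs outside a parameter's admissible range are truncated to the nearest
#' bound (e.g. a soil half-life of 2000 days on a 0-200 day universe enters
#' the model as 200). Every truncation is reported as a warning so that
#' out-of-range inputs are visible in the assessment trace.
#'
#' @param data A data frame of pesticide records.
#' @param model A [safety_model()].
#' @param quiet Suppress clamp warnings.
#' @return `data` as a tibble with clamped parameter columns.
#' @export
clamp_inputs <- function(data, model, quiet = FALSE) {
  data <- tibble::as_tibble(data)
  for (par in model$parameters) {
    col <- par$column
    if (!col %in% names(data)) {
      rlang::abort(sprintf("missing parameter column '%s'", col),
                   class = "beesafe_validation_error")
    }
    v <- data[[col]]
    if (!is.numeric(v)) {
      rlang::abort(sprintf("column '%s' must be numeric", col),
                   class = "beesafe_validation_error")
    }
    out <- which(is.finite(v) & (v < par$universe[1] | v > par$universe[2]))
    if (length(out) && !quiet) {
      labels <- if ("name" %in% names(data)) data$name[out] else paste("row", out)
      rlang::warn(sprintf(
        "%s outside [%g, %g], clamped for: %s", par$name,
        par$universe[1], par$universe[2], paste(labels, collapse = ", ")))
    }
    data[[col]] <- pmin(pmax(v, par$universe[1]), par$universe[2])
  }
  data
}

#' Fuzzify pesticide records
#'
#' Converts each crisp parameter value into per-category degrees of truth by
#' evaluating the parameter's membership functions. Values are expected to be
#' clamped already (see [clamp_inputs()]); [assess()] does both steps.
#'
#' @param data A data frame of pesticide records with one column per model
#'   parameter (and optionally a `name` column).
#' @param model A [safety_model()].
#' @return A long tibble with columns `name`, `parameter`, `category`,
#'   `code`, `degree`.
#' @export
fuzzify <- function(data, model) {
  data <- tibble::as_tibble(data)
  nm <- if ("name" %in% names(data)) data$name else as.character(seq_len(nrow(data)))
  purrr::map2_dfr(seq_len(nrow(data)), nm, function(i, id) {
    purrr::map_dfr(model$parameters, function(par) {
      v <- data[[par$column]][i]
      if (is.na(v) || !is.finite(v)) {
        rlang::abort(
          sprintf("empty or non-finite value for '%s' in record '%s'",
                  par$column, id),
          class = "beesafe_validation_error")
      }
      tibble::tibble(
        name = id, parameter = par$name, category = par$categories,
        code = unname(par$codes),
        degree = purrr::map_dbl(par$mfs, mf_eval, x = v)
      )
    })
  })
}
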