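#' Normalize expert importance ratings into parameter weights
#'
#' Each expert rates the importance of each parameter on a 0-5 scale. Per
#' expert, ratings are divided by that expert's rating total so each expert's
#' weights sum to one; the final weight per parameter is the mean across
#' experts. With integer ratings the arithmetic is carried out on exact
#' integer fractions, so downstream tie detection in the rule-base generator
#' (weighted score exactly 0.5) is free of floating-point noise; the printed
#' 2-decimal weights are display rounding only.
#'
#' @param ratings A data frame in long form with columns `parameter`,
#'   `expert`, `rating`, or a numeric matrix with one row per parameter and
#'   one column per expert (rownames = parameter names).
#' @return An object of class `expert_weights`: final weights plus, for
#'   integer ratings, their exact fraction representation (`numerators` over
#'   `denominator`).
#' @examples
#' w <- expert_weights(matrix(c(2, 3, 5, 4, 1, 5, 3, 2, 1, 4), ncol = 2,
#'   dimnames = list(c("persistency", "aeq", "ld50", "exposure", "mrl"), NULL)))
#' round(w$weights, 2)
#' @export
expert_weights <- function(ratings) {
  if (is.data.frame(ratings)) {
    need <- c("parameter", "expert", "rating")
    if (!all(need %in% names(ratings))) {
      rlang::abort("long-form ratings need columns parameter, expert, rating",
                   class = "beesafe_validation_error")
    }
    m <- ratings |>
      tidyr::pivot_wider(names_from = "expert", values_from = "rating")
    params <- m$parameter
    m <- as.matrix(m[-1])
    rownames(m) <- params
  } else {
    m <- as.matrix(ratings)
    if (is.null(rownames(m))) {
      rlang::abort("matrix ratings need parameter rownames",
                   class = "beesafe_validation_error")
    }
  }
  if (anyNA(m) || any(m < 0)) {
    rlang::abort("ratings must be non-negative and complete",
                 class = "beesafe_validation_error")
  }
  totals <- colSums(m)
  if (any(totals == 0)) {
    rlang::abort("an expert's ratings are all zero; cannot normalize",
                 class = "beesafe_validation_error")
  }

  per_expert <- sweep(m, 2, totals, "/")
  weights <- rowMeans(per_expert)

  exact <- all(abs(m - round(m)) < 1e-9)
  numerators <- denominator <- NULL
  if (exact) {
    mi <- round(m)
    ti <- colSums(mi)
    # weight_i = (1/E) * sum_e r_ie / t_e over denominator E * prod(t_e)
    e <- ncol(mi)
    den <- e * prod(ti)
    num <- vapply(seq_len(nrow(mi)), function(i) {
      sum(vapply(seq_len(e), function(j) mi[i, j] * prod(ti[-j]), numeric(1)))
    }, numeric(1))
    g <- Reduce(gcd_int, c(num, den))
    # kept as exact whole numbers in doubles (safe well past any realistic
    # expert-panel size)
    numerators <- stats::setNames(round(num / g), rownames(m))
    denominator <- round(den / g)
  }

  structure(
    list(ratings = m, per_expert = per_expert, weights = weights,
         numerators = numerators, denominator = denominator),
    class = "expert_weights"
  )
}

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { r <- a %% b; a <- b; b <- r }
  a
}

#' @export
print.expert_weights <- function(x, ...) {
  cat("<expert_weights>", nrow(x$ratings), "parameters,",
      ncol(x$ratings), "experts\n")
  print(generics::tidy(x), ...)
  invisible(x)
}

#' Tidy an expert_weights object
#'
#' @param x An [expert_weights()] object.
#' @param ... Unused.
#' @return A tibble with the raw scales, per-expert weights, and the final
#'   averaged weight per parameter.
#' @method tidy expert_weights
#' @export
tidy.expert_weights <- function(x, ...) {
  tb <- tibble::tibble(parameter = rownames(x$ratings))
  for (j in seq_len(ncol(x$ratings))) {
    tb[[paste0("scale_expert_", j)]] <- unname(x$ratings[, j])
    tb[[paste0("weight_expert_", j)]] <- unname(x$per_expert[, j])
  }
  tb$weight <- unname(x$weights)
  tb
}
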