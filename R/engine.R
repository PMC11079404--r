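#' Fuzzy connectives
#'
#' Mamdani connectives: `conjunction()` is the minimum t-norm used to combine
#' the antecedent degrees within one rule; `disjunction()` is the maximum
#' s-norm used to aggregate activations across rules sharing a consequent.
#' An empty disjunction is 0 (no rule fired for that consequent); an empty
#' conjunction is an error.
#'
#' @param degrees Numeric vector of degrees of truth in \[0, 1\].
#' @return A single degree in \[0, 1\].
#' @export
conjunction <- function(degrees) {
  if (length(degrees) == 0) {
    rlang::abort("conjunction of an empty set is undefined",
                 class = "beesafe_validation_error")
  }
  check_degrees(degrees)
  min(degrees)
}

#' @rdname conjunction
#' @export
disjunction <- function(degrees) {
  if (length(degrees) == 0) return(0)
  check_degrees(degrees)
  max(degrees)
}

check_degrees <- function(degrees) {
  if (anyNA(degrees) || any(degrees < 0 | degrees > 1)) {
    rlang::abort("degrees of truth must lie in [0, 1]",
                 class = "beesafe_validation_error")
  }
  invisible(degrees)
}

#' Run Mamdani inference over the rule base
#'
#' For each record, every rule's activation is the conjunction (minimum) of
#' the degrees of its five antecedent categories, and the aggregate degree of
#' each consequent is the disjunction (maximum) of the activations of the
#' rules that conclude it.
#'
#' @param fuzzy The long tibble produced by [fuzzify()].
#' @param model A [safety_model()].
#' @param trace If `TRUE`, attach a `"trace"` attribute: a named list (one
#'   tibble per record) of the rules with activation > 0.
#' @return A tibble with columns `name`, `safe`, `not_safe`.
#' @export
infer <- function(fuzzy, model, trace = FALSE) {
  rules <- model$rules
  pnames <- names(model$parameters)
  records <- unique(fuzzy$name)
  traces <- if (trace) vector("list", length(records))

  out <- purrr::map_dfr(seq_along(records), function(k) {
    f1 <- fuzzy[fuzzy$name == records[k], ]
    lookup <- split(stats::setNames(f1$degree, f1$category), f1$parameter)
    deg <- purrr::map(pnames, function(p) {
      cats <- rules[[p]]
      d <- lookup[[model$parameters[[p]]$name]][cats]
      if (anyNA(d)) {
        rlang::abort(sprintf("rule base references unknown category of '%s'", p),
                     class = "beesafe_config_error")
      }
      unname(d)
    })
    activation <- do.call(pmin, deg)
    if (trace) {
      tr <- rules
      tr$activation <- activation
      traces[[k]] <<- tr[tr$activation > 0, ]
    }
    tibble::tibble(
      name = records[k],
      safe = disjunction(activation[rules$consequent == "safe"]),
      not_safe = disjunction(activation[rules$consequent == "not_safe"])
    )
  })
  if (trace) {
    names(traces) <- records
    attr(out, "trace") <- traces
  }
  out
}

#' Centroid defuzzification of the aggregated consequent
#'
#' Mamdani clipping: each output membership function is capped at its
#' consequent's aggregate degree, the clipped curves are combined by
#' pointwise maximum, and the crisp score is the center of gravity (first
#' moment over area) of the combined curve. `defuzzify_centroid()` integrates
#' on a regular grid; [centroid_oracle()] computes the same center of gravity
#' in closed form from the piecewise-linear geometry and serves as an
#' independent verification path.
#'
#' @param safe,not_safe Aggregate degrees of truth of the two consequents.
#' @param model A [safety_model()] (supplies the output membership functions
#'   and universe).
#' @param step Grid spacing on the output universe.
#' @return The crisp safety score.
#' @export
defuzzify_centroid <- function(safe, not_safe, model, step = 0.01) {
  check_degrees(c(safe, not_safe))
  if (safe == 0 && not_safe == 0) {
    rlang::abort("no rule fired: both aggregate degrees are zero",
                 class = "beesafe_validation_error")
  }
  if (step <= 0) {
    rlang::abort("step must be positive", class = "beesafe_config_error")
  }
  u <- model$output$universe
  x <- seq(u[1], u[2], by = step)
  mu <- pmax(pmin(mf_eval(model$output$mfs$not_safe, x), not_safe),
             pmin(mf_eval(model$output$mfs$safe, x), safe))
  # trapezoidal-rule quadrature for first moment and area
  w <- rep(1, length(x))
  w[c(1, length(x))] <- 0.5
  sum(w * x * mu) / sum(w * mu)
}

#' @rdname defuzzify_centroid
#' @export
centroid_oracle <- function(safe, not_safe, model) {
  check_degrees(c(safe, not_safe))
  if (safe == 0 && not_safe == 0) {
    rlang::abort("no rule fired: both aggregate degrees are zero",
                 class = "beesafe_validation_error")
  }
  u <- model$output$universe
  k1 <- pl_clip(model$output$mfs$not_safe, not_safe, u)
  k2 <- pl_clip(model$output$mfs$safe, safe, u)

  # refine a common knot grid, then add crossings of the two linear pieces
  xs <- sort(unique(c(k1$x, k2$x)))
  y1 <- pl_interp(k1, xs)
  y2 <- pl_interp(k2, xs)
  cross <- c()
  for (i in seq_len(length(xs) - 1)) {
    d0 <- y1[i] - y2[i]
    d1 <- y1[i + 1] - y2[i + 1]
    if (d0 * d1 < 0) {
      cross <- c(cross, xs[i] + d0 / (d0 - d1) * (xs[i + 1] - xs[i]))
    }
  }
  xs <- sort(unique(c(xs, cross)))
  y <- pmax(pl_interp(k1, xs), pl_interp(k2, xs))

  area <- 0
  moment <- 0
  for (i in seq_len(length(xs) - 1)) {
    dx <- xs[i + 1] - xs[i]
    y0 <- y[i]; y1i <- y[i + 1]
    area <- area + dx * (y0 + y1i) / 2
    # exact first moment of a linear segment
    moment <- moment + dx * (xs[i] * (2 * y0 + y1i) + xs[i + 1] * (y0 + 2 * y1i)) / 6
  }
  moment / area
}

# piecewise-linear knots of min(mf(x), h) on the universe; exact only for
# trapezoid/triangle shapes (the output consequents), which is all the
# oracle is for
pl_clip <- function(mf, h, universe) {
  if (!mf$shape %in% c("trapezoid", "triangle")) {
    rlang::abort("centroid_oracle requires piecewise-linear output shapes",
                 class = "beesafe_config_error")
  }
  bp <- mf$breakpoints
  xs <- c(universe, bp)
  if (h > 0 && h < 1) {
    if (mf$shape == "trapezoid") {
      a <- bp[1]; b <- bp[2]; c <- bp[3]; d <- bp[4]
      if (b > a) xs <- c(xs, a + h * (b - a))
      if (d > c) xs <- c(xs, d - h * (d - c))
    } else {
      a <- bp[1]; b <- bp[2]; c <- bp[3]
      if (b > a) xs <- c(xs, a + h * (b - a))
      if (c > b) xs <- c(xs, c - h * (c - b))
    }
  }
  xs <- sort(unique(pmin(pmax(xs, universe[1]), universe[2])))
  tibble::tibble(x = xs, y = pmin(mf_eval(mf, xs), h))
}

pl_interp <- function(knots, x) {
  stats::approx(knots$x, knots$y, xout = x, rule = 2)$y
}
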