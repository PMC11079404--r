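#' Membership function primitives
#'
#' A membership function maps a crisp value on a parameter's universe to a
#' degree of truth in \[0, 1\]. Four shapes are supported: `trapezoid`
#' (breakpoints a, b, c, d: linear rise a to b, plateau at 1 on \[b, c\],
#' linear fall c to d), `triangle` (a, b, c: peak 1 at b), and the smooth
#' quadratic-spline saturation curves `s_shape` (a, b: monotone 0 to 1 with
#' degree 1/2 at the midpoint) and `z_shape` (its mirror, 1 - s).
#'
#' @param a,b,c,d Breakpoints on the parameter universe, non-decreasing.
#' @return An object of class `membership_fn`.
#' @examples
#' np <- trapezoid_mf(0, 0, 30, 65)
#' mf_eval(np, c(10, 40, 80))
#' @name membership
NULL

new_membership_fn <- function(shape, breakpoints) {
  n_expected <- switch(shape,
    trapezoid = 4L, triangle = 3L, z_shape = 2L, s_shape = 2L,
    rlang::abort(paste0("unknown membership shape: ", shape),
                 class = "beesafe_config_error")
  )
  if (length(breakpoints) != n_expected || anyNA(breakpoints) ||
      !is.numeric(breakpoints)) {
    rlang::abort(
      sprintf("%s membership function needs %d numeric breakpoints",
              shape, n_expected),
      class = "beesafe_config_error"
    )
  }
  if (is.unsorted(breakpoints)) {
    rlang::abort("membership breakpoints must be non-decreasing",
                 class = "beesafe_config_error")
  }
  structure(list(shape = shape, breakpoints = as.numeric(breakpoints)),
            class = "membership_fn")
}

#' @rdname membership
#' @export
trapezoid_mf <- function(a, b, c, d) new_membership_fn("trapezoid", c(a, b, c, d))

#' @rdname membership
#' @export
triangle_mf <- function(a, b, c) new_membership_fn("triangle", c(a, b, c))

#' @rdname membership
#' @export
z_mf <- function(a, b) new_membership_fn("z_shape", c(a, b))

#' @rdname membership
#' @export
s_mf <- function(a, b) new_membership_fn("s_shape", c(a, b))

#' @export
print.membership_fn <- function(x, ...) {
  cat(sprintf("<membership_fn> %s [%s]\n", x$shape,
              paste(format(x$breakpoints, trim = TRUE), collapse = ", ")))
  invisible(x)
}

# linear ramp from 0 at `from` to 1 at `to`; a zero-width ramp is a step
# that keeps the plateau closed (degree 1 at the shared breakpoint)
ramp_up <- function(x, from, to) {
  if (to == from) return(as.numeric(x >= to))
  pmin(1, pmax(0, (x - from) / (to - from)))
}

# linear fall from 1 at `from` to 0 at `to`; zero-width falls keep degree 1
# at the breakpoint itself (right-shoulder trapezoids stay saturated at the
# universe edge)
ramp_down <- function(x, from, to) {
  if (to == from) return(as.numeric(x <= to))
  pmin(1, pmax(0, (to - x) / (to - from)))
}

s_curve <- function(x, a, b) {
  if (b == a) return(as.numeric(x >= a))
  m <- (a + b) / 2
  y <- numeric(length(x))
  lo <- x > a & x <= m
  hi <- x > m & x < b
  y[lo] <- 2 * ((x[lo] - a) / (b - a))^2
  y[hi] <- 1 - 2 * ((x[hi] - b) / (b - a))^2
  y[x >= b] <- 1
  y
}

#' Evaluate a membership function
#'
#' @param mf A `membership_fn`.
#' @param x Numeric vector of crisp values (already clamped to the universe).
#' @return Degrees of truth in \[0, 1\], one per element of `x`.
#' @export
mf_eval <- function(mf, x) {
  stopifnot(inherits(mf, "membership_fn"))
  bp <- mf$breakpoints
  switch(mf$shape,
    trapezoid = pmin(ramp_up(x, bp[1], bp[2]), ramp_down(x, bp[3], bp[4])),
    triangle  = pmin(ramp_up(x, bp[1], bp[2]), ramp_down(x, bp[2], bp[3])),
    s_shape   = s_curve(x, bp[1], bp[2]),
    z_shape   = 1 - s_curve(x, bp[1], bp[2])
  )
}

#' Tabulate a membership function over an interval
#'
#' Convenience for plotting and numeric work: evaluates `mf` on a regular
#' grid over `universe`.
#'
#' @param mf A `membership_fn`.
#' @param universe Length-2 numeric, grid bounds.
#' @param n Number of grid points.
#' @return A tibble with columns `x` and `degree`.
#' @export
mf_grid <- function(mf, universe, n = 501L) {
  x <- seq(universe[1], universe[2], length.out = n)
  tibble::tibble(x = x, degree = mf_eval(mf, x))
}
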