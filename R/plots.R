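#' Plot the membership functions of a safety model
#'
#' Draws every input parameter's membership functions (one facet per
#' parameter, one curve per category) plus the output consequents, the usual
#' way fuzzy controllers are inspected before use.
#'
#' @param object A [safety_model()].
#' @param n Grid points per universe.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot safety_model
#' @export
autoplot.safety_model <- function(object, n = 401L, ...) {
  curves <- purrr::imap_dfr(object$parameters, function(par, key) {
    purrr::imap_dfr(par$mfs, function(m, cat_label) {
      g <- mf_grid(m, par$universe, n)
      g$parameter <- sprintf("%s (%s)", par$name, par$units)
      g$category <- cat_label
      g
    })
  })
  out <- purrr::imap_dfr(object$output$mfs, function(m, cat_label) {
    g <- mf_grid(m, object$output$universe, n)
    g$parameter <- "output (safety level point)"
    g$category <- cat_label
    g
  })
  curves <- dplyr::bind_rows(curves, out)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$x, y = .data$degree,
                                       colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "degree of truth", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot assessment results
#'
#' Ranked bar chart of the crisp safety level points, coloured by the
#' dominant consequent; the attainable score bounds (the full Not-Safe and
#' full Safe centroids) are drawn as reference lines.
#'
#' @param object A `safety_assessment` from [assess()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot safety_assessment
#' @export
autoplot.safety_assessment <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$name <- factor(df$name, levels = rev(df$name))
  df$dominant <- ifelse(df$safe >= df$not_safe, "safe", "not safe")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$safety_level_point,
                                   y = .data$name, fill = .data$dominant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = c(79 / 30, 10 - 79 / 30),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_continuous(limits = c(0, 10)) +
    ggplot2::labs(x = "safety level point (0-10)", y = NULL,
                  fill = "dominant consequent") +
    ggplot2::theme_minimal()
}
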