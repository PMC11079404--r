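#' Read and write a safety model configuration
#'
#' The full model definition (universes, membership-function shapes and
#' breakpoints, categorization codes, expert ratings or explicit weights,
#' output consequents) round-trips through a YAML configuration file, so a
#' customized model can be stored alongside an analysis and reloaded
#' bit-exactly.
#'
#' @param model A [safety_model()].
#' @param path File path of the YAML configuration.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns a
#'   [safety_model()].
#' @export
write_model <- function(model, path) {
  cfg <- list(
    parameters = purrr::map(model$parameters, function(p) {
      list(
        name = p$name, column = p$column,
        universe = as.list(p$universe), units = p$units,
        categories = as.list(p$categories),
        mfs = purrr::map(p$mfs, function(m)
          list(shape = m$shape, breakpoints = as.list(m$breakpoints))),
        codes = as.list(p$codes)
      )
    }),
    ratings = list(
      parameters = as.list(rownames(model$weights$ratings)),
      experts = as.list(colnames(model$weights$ratings)),
      values = apply(model$weights$ratings, 1, as.list, simplify = FALSE)
    ),
    output = list(
      universe = as.list(model$output$universe),
      mfs = purrr::map(model$output$mfs, function(m)
        list(shape = m$shape, breakpoints = as.list(m$breakpoints)))
    )
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  parameters <- purrr::map(cfg$parameters, function(p) {
    cats <- as.character(unlist(p$categories))
    fuzzy_parameter(
      name = p$name, column = p$column,
      universe = as.numeric(unlist(p$universe)), units = p$units,
      categories = cats,
      mfs = purrr::map(p$mfs, function(m)
        new_membership_fn(m$shape, as.numeric(unlist(m$breakpoints)))),
      codes = stats::setNames(as.numeric(unlist(p$codes)), names(p$codes))
    )
  })
  ratings <- do.call(rbind, purrr::map(cfg$ratings$values,
                                       ~ as.numeric(unlist(.x))))
  dimnames(ratings) <- list(as.character(unlist(cfg$ratings$parameters)),
                            as.character(unlist(cfg$ratings$experts)))
  output <- list(
    universe = as.numeric(unlist(cfg$output$universe)),
    mfs = purrr::map(cfg$output$mfs, function(m)
      new_membership_fn(m$shape, as.numeric(unlist(m$breakpoints))))
  )
  safety_model(parameters, expert_weights(ratings), output)
}
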