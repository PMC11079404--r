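# Build the calibrated model once per test run; rule-base generation is
# cheap but there is no reason to repeat it in every block.
the_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_model()
    cache
  }
})

# Independent brute-force centroid: dense midpoint sampling of the clipped
# aggregate, no shared code with defuzzify_centroid or centroid_oracle.
brute_centroid <- function(safe, not_safe, model, n = 200001L) {
  u <- model$output$universe
  h <- diff(u) / n
  x <- u[1] + (seq_len(n) - 0.5) * h
  mu <- pmax(pmin(mf_eval(model$output$mfs$not_safe, x), not_safe),
             pmin(mf_eval(model$output$mfs$safe, x), safe))
  sum(x * mu) / sum(mu)
}
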