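test_that("conjunction is min, disjunction is max, empty cases as defined", {
  expect_equal(conjunction(c(1, 1, 1, 1, 1)), 1)
  expect_equal(conjunction(c(0.714, 1, 0.95, 1, 1)), 0.714)
  expect_equal(conjunction(c(0.5, 0.9)), 0.5)
  expect_equal(disjunction(c(0.78, 0.61, 0.38)), 0.78)
  expect_equal(disjunction(c(1, 0.26)), 1)
  expect_equal(disjunction(numeric(0)), 0)
  expect_error(conjunction(numeric(0)), class = "beesafe_validation_error")
  expect_error(conjunction(c(0.5, 1.2)), class = "beesafe_validation_error")
})

test_that("inference aggregates rule activations per consequent", {
  m <- the_model()
  records <- load_fixture("pesticides")

  aba <- fuzzify(clamp_inputs(records[records$name == "Abamectin", ], m), m)
  agg <- infer(aba, m)
  expect_equal(agg$not_safe, 1)
  expect_equal(agg$safe, 0)

  ipr <- fuzzify(clamp_inputs(records[records$name == "Iprodione", ], m,
                              quiet = TRUE), m)
  agg <- infer(ipr, m)
  expect_equal(agg$safe, 1)
  expect_equal(agg$not_safe, 0)
})

test_that("a single active category chain passes its degree through", {
  m <- the_model()
  # one category per parameter at degree d: exactly one rule fires, at d
  d <- 0.37
  fuzzy <- purrr::imap_dfr(m$parameters, function(par, key) {
    tibble::tibble(name = "x", parameter = par$name,
                   category = par$categories,
                   code = unname(par$codes),
                   degree = c(d, rep(0, length(par$categories) - 1)))
  })
  agg <- infer(fuzzy, m, trace = TRUE)
  expect_equal(agg$safe, d)          # the all-best rule is Safe
  expect_equal(agg$not_safe, 0)
  tr <- attr(agg, "trace")$x
  expect_equal(nrow(tr), 1)
  expect_equal(tr$activation, d)
})

test_that("full activations defuzzify to the output centroid bounds", {
  m <- the_model()
  expect_equal(defuzzify_centroid(safe = 0, not_safe = 1, m), 79 / 30,
               tolerance = 1e-4)
  expect_equal(defuzzify_centroid(safe = 1, not_safe = 0, m), 10 - 79 / 30,
               tolerance = 1e-4)
  expect_equal(centroid_oracle(safe = 0, not_safe = 1, m), 79 / 30)
  expect_equal(centroid_oracle(safe = 1, not_safe = 0, m), 10 - 79 / 30)
})

test_that("equal aggregate degrees land on the symmetry point", {
  m <- the_model()
  for (h in c(1, 0.6, 0.25, 0.01)) {
    expect_equal(defuzzify_centroid(h, h, m), 5, tolerance = 1e-9)
    expect_equal(centroid_oracle(h, h, m), 5, tolerance = 1e-12)
  }
})

test_that("oracle matches an independent brute-force integration", {
  m <- the_model()
  set.seed(11)
  for (i in 1:10) {
    s <- runif(1); ns <- runif(1)
    expect_equal(centroid_oracle(s, ns, m), brute_centroid(s, ns, m),
                 tolerance = 1e-6)
  }
  # known mixed case from the bundled study
  expect_equal(round(centroid_oracle(safe = 25 / 35, not_safe = 0.5, m), 2),
               5.44)
})

test_that("discretized and closed-form centroids agree across random loads", {
  m <- the_model()
  set.seed(101)
  s <- runif(1000); ns <- runif(1000)
  keep <- s > 0 | ns > 0
  s <- s[keep]; ns <- ns[keep]
  oracle <- purrr::map2_dbl(s, ns, ~ centroid_oracle(.x, .y, m))
  d1 <- purrr::map2_dbl(s, ns, ~ defuzzify_centroid(.x, .y, m, step = 0.01))
  expect_lt(max(abs(d1 - oracle)), 1e-2)
  d2 <- purrr::map2_dbl(s, ns, ~ defuzzify_centroid(.x, .y, m, step = 0.001))
  expect_lt(max(abs(d2 - oracle)), 1e-3)
  # bounded-output property: scores live between the two full centroids
  expect_true(all(oracle >= 79 / 30 - 1e-9 & oracle <= 10 - 79 / 30 + 1e-9))
  expect_true(all(d1 >= 79 / 30 - 1e-2 & d1 <= 10 - 79 / 30 + 1e-2))
})

test_that("a vanishing consequent degree converges to the other centroid", {
  m <- the_model()
  full_safe <- centroid_oracle(1, 0, m)
  expect_equal(centroid_oracle(1, 1e-9, m), full_safe, tolerance = 1e-6)
})

test_that("zero total activation is an explicit error", {
  m <- the_model()
  expect_error(defuzzify_centroid(0, 0, m), class = "beesafe_validation_error")
  expect_error(centroid_oracle(0, 0, m), class = "beesafe_validation_error")
  expect_error(defuzzify_centroid(1, 0, m, step = -1),
               class = "beesafe_config_error")
})
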