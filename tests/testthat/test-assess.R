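test_that("the ten-pesticide panel reproduces the reference safety scores", {
  res <- assess(load_fixture("pesticides"), the_model(), quiet = TRUE)
  exp <- load_fixture("expected_scores")
  j <- dplyr::left_join(tibble::as_tibble(res), exp, by = "name",
                        suffix = c("", "_expected"))
  dev <- abs(j$safety_level_point - j$safety_level_point_expected)
  expect_true(all(dev <= 0.02))
  expect_gte(sum(dev <= 0.01), 8)
})

test_that("ranking puts dodine and iprodione on top, the organophosphate
           and avermectin group at the bottom", {
  res <- assess(load_fixture("pesticides"), the_model(), quiet = TRUE)
  expect_setequal(res$name[1:2], c("Dodine", "Iprodione"))
  expect_setequal(res$name[res$safety_level_point == min(res$safety_level_point)],
                  c("Abamectin", "Dimethoate", "Chlorpyrifos", "Methidathion"))
  g <- glance(res)
  expect_equal(g$n_verified, 10L)
  expect_true(g$best_option %in% c("Dodine", "Iprodione"))
})

test_that("assessment is deterministic and scores stay within the bounds", {
  rec <- load_fixture("pesticides")
  r1 <- assess(rec, the_model(), quiet = TRUE)
  r2 <- assess(rec, the_model(), quiet = TRUE)
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))
  # bounds hold up to the quadrature error of the 0.01 grid
  expect_true(all(r1$score >= 79 / 30 - 1e-4 &
                  r1$score <= 10 - 79 / 30 + 1e-4))
})

test_that("every centroid parity check passes, including the clamped cases", {
  v <- verify(load_fixture("pesticides"), the_model(), quiet = TRUE)
  expect_equal(v$verification_value, rep(1L, 10))
  expect_equal(v$code_result[v$name == "DDT"], 2.75)
  expect_equal(v$centroid_calculation[v$name == "DDT"], 2.75)
})

test_that("a deliberately coarse discretization trips the verification flag", {
  rec <- load_fixture("pesticides")
  v <- verify(rec, the_model(), step = 2.5, quiet = TRUE)
  expect_true(any(v$verification_value == 0))
})

test_that("out-of-range inputs are clamped, warned about, and traceable", {
  rec <- load_fixture("pesticides")
  w <- capture_warnings(assess(rec, the_model()))
  expect_length(w, 2)  # DDT persistency and iprodione LD50
  expect_match(w, "clamped", all = TRUE)
  res <- assess(rec, the_model(), quiet = TRUE)
  inputs <- attr(res, "inputs")
  expect_equal(inputs$persistency_days[inputs$name == "DDT"], 200)
  expect_equal(inputs$ld50_ug_per_bee[inputs$name == "Iprodione"], 200)
})

test_that("the fired-rule trace explains each aggregate degree", {
  res <- assess(load_fixture("pesticides"), the_model(), quiet = TRUE)
  tr <- tidy(res)
  expect_true(all(tr$activation > 0))
  clo <- dplyr::filter(tr, name == "Clofentezine")
  expect_equal(max(clo$activation[clo$consequent == "safe"]), 25 / 35)
  expect_equal(max(clo$activation[clo$consequent == "not_safe"]), 0.5)
})

test_that("missing values abort with the offending field named", {
  rec <- load_fixture("pesticides")
  rec$aeq[3] <- NA
  expect_error(assess(rec, the_model(), quiet = TRUE), "aeq",
               class = "beesafe_validation_error")
  expect_error(assess(rec[0, ], the_model()),
               class = "beesafe_validation_error")
})

test_that("degrading any one parameter never beats the undegraded baseline", {
  # The crisp centroid is not pointwise monotone along a degradation path:
  # during category hand-over the aggregate degree dips below 1 and the
  # clipped-consequent centroid shifts toward the universe middle, then
  # recovers (a property of every Mamdani controller, not of this model).
  # The safety guarantee that does hold, and is asserted here, is that no
  # amount of single-parameter degradation makes a pesticide score better
  # than its fully-undegraded configuration.
  m <- the_model()
  best <- tibble::tibble(
    name = "probe", persistency_days = 0, aeq = 20, ld50_ug_per_bee = 200,
    likely_exposure = 0, mrl_mg_per_kg = 400)
  baseline <- assess(best, m, quiet = TRUE)$score
  worst_values <- c(persistency_days = 200, aeq = 0, ld50_ug_per_bee = 0,
                    likely_exposure = 4, mrl_mg_per_kg = 0)
  for (col in names(worst_values)) {
    sweep_vals <- seq(best[[col]], worst_values[[col]], length.out = 200)
    grid <- best[rep(1, 200), ]
    grid[[col]] <- sweep_vals
    grid$name <- as.character(seq_len(200))
    res <- assess(grid, m, rank = FALSE, quiet = TRUE)
    expect_true(all(res$score <= baseline + 1e-9),
                label = sprintf("degradation of %s bounded by baseline", col))
  }
})
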