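# Independent oracle: enumerate the category-code product directly and apply
# the weighted threshold with plain arithmetic on the exact 30ths.
enumerate_consequents <- function() {
  codes <- expand.grid(persistency = c(0, 0.5, 1), aeq = c(0, 0.5, 1),
                       ld50 = c(0, 0.5, 1), exposure = c(0, 1),
                       mrl = c(0, 1))
  w30 <- c(7, 6, 7, 5, 5)
  score30x2 <- as.matrix(codes) %*% (2 * w30)  # integer-valued
  ifelse(score30x2 > 30, "not_safe", "safe")
}

test_that("the generated rule base covers the full category product once", {
  m <- the_model()
  rb <- m$rules
  expect_equal(nrow(rb), 108)
  ante <- rb[names(m$parameters)]
  expect_equal(nrow(dplyr::distinct(ante)), 108)
})

test_that("the Safe/Not-Safe partition matches brute-force enumeration", {
  rb <- the_model()$rules
  oracle <- enumerate_consequents()
  expect_equal(sum(rb$consequent == "safe"), sum(oracle == "safe"))
  expect_equal(sum(rb$consequent == "not_safe"), sum(oracle == "not_safe"))
})

test_that("reference example rules get the right consequent and score", {
  rb <- the_model()$rules
  r1 <- dplyr::filter(rb, persistency == "non_persistent",
                      aeq == "high_contaminate", ld50 == "high_toxicity",
                      exposure == "no_likely_exposure",
                      mrl == "low_residue_limit")
  expect_equal(r1$weighted_score, 0.6)
  expect_equal(r1$consequent, "not_safe")

  r2 <- dplyr::filter(rb, persistency == "non_persistent",
                      aeq == "high_contaminate", ld50 == "high_toxicity",
                      exposure == "no_likely_exposure",
                      mrl == "high_residue_limit")
  expect_equal(r2$weighted_score, 13 / 30)
  expect_equal(r2$consequent, "safe")

  best <- dplyr::filter(rb, persistency == "non_persistent",
                        aeq == "low_contaminate", ld50 == "low_toxicity",
                        exposure == "no_likely_exposure",
                        mrl == "high_residue_limit")
  expect_equal(best$weighted_score, 0)
  expect_equal(best$consequent, "safe")
})

test_that("exact 0.5 ties exist and are classified Safe", {
  rb <- the_model()$rules
  ties <- dplyr::filter(rb, abs(weighted_score - 0.5) < 1e-12)
  expect_gt(nrow(ties), 0)
  expect_true(all(ties$consequent == "safe"))
})

test_that("worsening any single antecedent never flips Not-Safe to Safe", {
  m <- the_model()
  rb <- m$rules
  for (p in names(m$parameters)) {
    par <- m$parameters[[p]]
    cats <- par$categories  # best-code-first
    for (k in seq_len(length(cats) - 1)) {
      from <- rb[[p]] == cats[k]
      worse <- rb
      worse[[p]][from] <- cats[k + 1]
      # rejoin against the rule base to look up the worse rule's consequent
      joined <- dplyr::left_join(
        worse[from, names(m$parameters)],
        rb[c(names(m$parameters), "consequent")],
        by = names(m$parameters))
      expect_false(any(rb$consequent[from] == "not_safe" &
                       joined$consequent == "safe"))
    }
  }
})

test_that("the rule set is invariant to parameter enumeration order", {
  m <- the_model()
  rev_params <- rev(m$parameters)
  rb2 <- rule_base(rev_params, m$weights)
  canon <- function(rb) {
    dplyr::arrange(rb[c(sort(names(m$parameters)), "consequent")],
                   dplyr::across(dplyr::everything()))
  }
  expect_equal(canon(m$rules), canon(rb2))
})

test_that("weights that do not sum to one are rejected", {
  m <- the_model()
  bad <- c(persistency = 0.3, aeq = 0.3, ld50 = 0.3, exposure = 0.3,
           mrl = 0.3)
  expect_error(rule_base(m$parameters, bad), class = "beesafe_config_error")
})
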