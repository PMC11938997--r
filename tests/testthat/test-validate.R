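test_that("the identity resample gives exactly zero optimism", {
  dat <- make_interaction_data(n = 300, seed = 2)
  rep <- optimism_range(dat, "y", c("x1", "x2"),
    leaf_count = 2, B = 3, seed = 1, resample = "identity"
  )
  expect_equal(rep$reps$diff, rep(0, 3))
  expect_identical(rep$o_range, 0)
  expect_equal(rep$inflation_pct, 0)
})

test_that("inflation is linear in the optimism at fixed observed range", {
  expect_equal(inflation_percent(0, 5), 0)
  expect_equal(inflation_percent(1, 2), 50)
  o <- runif(5)
  expect_equal(
    inflation_percent(2 * o, 1.3), 2 * inflation_percent(o, 1.3),
    tolerance = 1e-12
  )
  expect_error(inflation_percent(1, 0), "positive")
})

test_that("optimism is positive on null data", {
  cfg <- null_sim_config(n = 160, seed = 7)
  tr <- generate_trial(cfg, tlfb = "none")
  dat <- resolve_missing_outcomes(tr$table, "exclude")
  rep <- optimism_range(dat, "prop_change", c("motivation", "anxiety"),
    leaf_count = 2, B = 60, seed = 3
  )
  expect_gt(nrow(rep$reps), 0)
  expect_gt(rep$o_range, 0)
})

test_that("a tree evaluated on its training outcome reproduces stored effects", {
  dat <- make_interaction_data(n = 400, seed = 9)
  fit <- quint(dat, "y", c("x1", "x2"),
    control = quint_control(boot = 5), seed = 1
  )
  cmp <- cross_outcome_table(list(main = fit), dat, "y")
  expect_equal(cmp$d, fit$leaves$d, tolerance = 1e-12)
  expect_equal(cmp$n_p, fit$leaves$n_p)
})

test_that("Cohen's d is invariant when the evaluated outcome is rescaled", {
  dat <- make_interaction_data(n = 400, seed = 10)
  dat$y2 <- 2 * dat$y
  fit <- quint(dat, "y", c("x1", "x2"), prune = FALSE, seed = 1)
  cmp <- cross_outcome_table(list(m = fit), dat, c("y", "y2"))
  wide <- tidyr::pivot_wider(
    cmp[, c("leaf", "outcome", "d")],
    names_from = outcome, values_from = d
  )
  expect_equal(wide$y, wide$y2, tolerance = 1e-12)
  # delta scales with the outcome
  wided <- tidyr::pivot_wider(
    cmp[, c("leaf", "outcome", "delta")],
    names_from = outcome, values_from = delta
  )
  expect_equal(2 * wided$y, wided$y2, tolerance = 1e-12)
})

test_that("trees trained on either outcome predict concordant leaf effects", {
  agree <- unlist(lapply(1:4, function(s) {
    cfg <- planted_sim_config(n = 500, d0 = 0.8, seed = 60 + s)
    tr <- generate_trial(cfg, tlfb = "none")
    dat <- resolve_missing_outcomes(tr$table, "exclude")
    fits <- lapply(c("prop_change", "raw_change"), function(oc) {
      quint(dat, oc, recovery_predictors, prune = FALSE, seed = s)
    })
    names(fits) <- c("prop_change", "raw_change")
    fits <- Filter(function(f) nrow(f$leaves) > 1, fits)
    if (!length(fits)) {
      return(logical(0))
    }
    cmp <- cross_outcome_table(fits, dat, c("prop_change", "raw_change"))
    wide <- tidyr::pivot_wider(
      cmp[, c("model", "leaf", "outcome", "d")],
      names_from = outcome, values_from = d
    )
    sign(wide$prop_change) == sign(wide$raw_change)
  }))
  expect_gte(mean(agree), 0.9)
})

test_that("exclude and impute outcome strategies both yield comparable reports", {
  cfg <- null_sim_config(n = 200, dropout = 0.1775, seed = 13)
  cfg$dropout_mar <- 1.5 # dropout depends on baseline drinking (MAR)
  cfg$subgroups <- split_subgroups("motivation", 6, c(-0.7, 0.7))
  tr <- generate_trial(cfg, tlfb = "none")
  preds <- c("motivation", "anxiety")
  reports <- lapply(c("exclude", "impute"), function(strat) {
    dat <- resolve_missing_outcomes(
      tr$table,
      strategy = strat, predictors = preds, seed = 1
    )
    optimism_range(dat, "prop_change", preds, leaf_count = 2, B = 40, seed = 5)
  })
  for (rep in reports) {
    expect_s3_class(rep, "optimism_report")
    expect_true(is.finite(rep$o_range))
    expect_equal(rep$scale, "d")
  }
  # the two strategies are comparable on the same optimism scale
  expect_length(unique(vapply(reports, `[[`, "", "outcome")), 1L)
})

test_that("report accessors are internally consistent", {
  dat <- make_interaction_data(n = 300, seed = 11)
  rep <- optimism_range(dat, "y", c("x1", "x2"), leaf_count = 2, B = 10, seed = 2)
  expect_equal(rep$o_range, mean(tidy(rep)$diff))
  g <- glance(rep)
  expect_equal(g$inflation_pct, 100 * g$o_range / g$observed_range)
  expect_equal(nrow(tidy(rep)) + rep$dropped, rep$B)
})
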