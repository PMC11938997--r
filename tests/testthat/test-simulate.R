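test_that("permuted blocks give exact 1:1 balance on full blocks", {
  cfg <- sim_config(n = 100, sites = 1, block_size = 4, seed = 2)
  tr <- generate_trial(cfg, tlfb = "none")
  expect_equal(unname(table(tr$table$arm)), c(50L, 50L), ignore_attr = TRUE)
})

test_that("per-site arm imbalance never exceeds half a block", {
  cfg <- sim_config(n = 338, seed = 5)
  tr <- generate_trial(cfg, tlfb = "none")
  imbalance <- tr$table %>%
    dplyr::count(site, arm) %>%
    tidyr::pivot_wider(names_from = arm, values_from = n, values_fill = 0L) %>%
    dplyr::mutate(gap = abs(placebo - active))
  expect_true(all(imbalance$gap <= cfg$block_size / 2))
})

test_that("the same seed reproduces the trial byte-for-byte", {
  cfg <- sim_config(n = 80, seed = 9)
  a <- generate_trial(cfg)
  b <- generate_trial(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$tlfb, b$tlfb)
  expect_identical(a$truth, b$truth)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(a$table, f1)
  write_trial_table(b$table, f2)
  expect_identical(readBin(f1, "raw", 1e7), readBin(f2, "raw", 1e7))
})

test_that("a single null subgroup yields a near-zero arm difference", {
  cfg0 <- sim_config(
    n = 200,
    subgroups = list(list(name = "all", when = list(), d = 0)),
    dropout = 0, item_missing = c(), na_item_rates = c(), seed = 1
  )
  dhats <- vapply(1:5, function(s) {
    cfg <- cfg0
    cfg$seed <- s
    tr <- generate_trial(cfg, tlfb = "none")
    y <- tr$table$prop_change
    act <- tr$table$arm == "active"
    leaf_effect(y[!act], y[act])$d
  }, numeric(1))
  expect_lt(abs(mean(dhats)), 0.3)
})

test_that("planted subgroup effects are realized in the generated outcomes", {
  cfg <- planted_sim_config(n = 2000, d0 = 0.8, dropout = 0, seed = 21)
  tr <- generate_trial(cfg, tlfb = "none")
  dat <- dplyr::left_join(tr$table, tr$truth, by = "id")
  for (g in unique(dat$subgroup)) {
    sub <- dat[dat$subgroup == g, ]
    dhat <- leaf_effect(
      sub$prop_change[sub$arm == "placebo"],
      sub$prop_change[sub$arm == "active"]
    )$d
    expect_lt(abs(dhat - sub$true_d[1]), 0.15)
  }
})

test_that("per-subgroup effect sizes converge to the configured d", {
  # default effect sizes at n = 10000, seed-averaged so the Monte Carlo error
  # (about 0.028 per subgroup per seed) does not swamp the 0.05 band
  errs <- list()
  for (seed in 33:35) {
    cfg <- sim_config(
      n = 10000,
      dropout = 0, item_missing = c(), na_item_rates = c(), seed = seed
    )
    tr <- generate_trial(cfg, tlfb = "none")
    dat <- dplyr::left_join(tr$table, tr$truth, by = "id")
    for (g in unique(dat$subgroup)) {
      sub <- dat[dat$subgroup == g, ]
      dhat <- leaf_effect(
        sub$prop_change[sub$arm == "placebo"],
        sub$prop_change[sub$arm == "active"]
      )$d
      errs[[g]] <- c(errs[[g]], dhat - sub$true_d[1])
    }
  }
  for (g in names(errs)) {
    expect_lt(abs(mean(errs[[g]])), 0.05)
  }
})

test_that("outcomes from the fast path equal outcomes derived from the TLFB", {
  cfg <- sim_config(
    n = 60, day_missing = 0, item_missing = c(), na_item_rates = c(), seed = 14
  )
  full <- generate_trial(cfg, tlfb = "full")
  fast <- generate_trial(cfg, tlfb = "none")
  derived <- derive_outcomes(full$tlfb)
  joined <- dplyr::left_join(
    fast$table[, c("id", "phdd_base", "prop_change", "raw_change")],
    derived,
    by = "id", suffix = c(".fast", ".tlfb")
  )
  keep <- !is.na(joined$prop_change.fast)
  expect_equal(
    joined$prop_change.fast[keep], joined$prop_change.tlfb[keep],
    tolerance = 1e-12
  )
  expect_equal(
    joined$raw_change.fast[keep], joined$raw_change.tlfb[keep],
    tolerance = 1e-12
  )
  expect_equal(joined$phdd_base.fast, joined$phdd_base.tlfb, tolerance = 1e-12)
})

test_that("TLFB records are internally consistent", {
  cfg <- sim_config(n = 40, seed = 8)
  tr <- generate_trial(cfg)
  expect_false(any(duplicated(tr$tlfb[, c("id", "day")])))
  obs <- tr$tlfb[tr$tlfb$observed, ]
  expect_true(all(obs$drinks >= 0))
  expect_true(all(is.na(tr$tlfb$drinks[!tr$tlfb$observed])))
})

test_that("masking rates behave at the boundaries and at the trial rate", {
  cfg <- null_sim_config(n = 338, seed = 4)
  tr <- generate_trial(cfg, tlfb = "none")
  t0 <- apply_missingness(tr$table, c(motivation = 0), seed = 1)
  expect_identical(t0, tr$table)
  t1 <- apply_missingness(tr$table, c(motivation = 1), seed = 1)
  expect_true(all(is.na(t1$motivation)))
  # 17.75% outcome dropout on 338 participants: observed count within the
  # binomial 95% interval around 60
  t2 <- apply_missingness(tr$table, c(outcome = 0.1775), seed = 6)
  n_missing <- sum(is.na(t2$prop_change))
  ci <- qbinom(c(0.025, 0.975), 338, 0.1775)
  expect_gte(n_missing, ci[1])
  expect_lte(n_missing, ci[2])
  expect_error(
    apply_missingness(tr$table, c(not_a_column = 0.5)),
    "unknown feature"
  )
})

test_that("non-partitioning subgroup predicates are rejected", {
  bad <- list(
    list(name = "low", when = list(list(var = "motivation", op = "<=", value = 4)), d = 0),
    list(name = "high", when = list(list(var = "motivation", op = ">", value = 6)), d = 0)
  )
  cfg <- sim_config(n = 60, subgroups = bad, seed = 1)
  expect_error(generate_trial(cfg, tlfb = "none"), "partition")
})

test_that("MAR dropout increases with baseline drinking", {
  cfg <- null_sim_config(n = 4000, dropout = 0.1775, seed = 12)
  cfg$dropout_mar <- 1.5
  tr <- generate_trial(cfg, tlfb = "none")
  gone <- tr$table$observed_maintenance_days == 0
  hi <- tr$table$drinks_per_week > median(tr$table$drinks_per_week)
  expect_gt(mean(gone[hi]), mean(gone[!hi]))
})
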