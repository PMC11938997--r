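mini_schema <- function() {
  feature_schema(
    c(i1 = "ordinal", i2 = "ordinal", i3 = "ordinal",
      x = "numeric", y = "numeric"),
    scales = list(s = c("i1", "i2", "i3")),
    levels = list(i1 = 0:4, i2 = 0:4, i3 = 0:4)
  )
}

test_that("scale scores are sums of retained items", {
  tbl <- tibble::tibble(i1 = 1, i2 = 2, i3 = 3, x = 0, y = 0)
  out <- score_scales(tbl, mini_schema())
  expect_equal(out$s, 6)
  expect_equal(attr(out, "excluded_items"), character(0))
})

test_that("high-missingness items are dropped from scoring trial-wide", {
  set.seed(1)
  n <- 200
  tbl <- tibble::tibble(
    i1 = rep(1, n), i2 = rep(1, n), i3 = rep(1, n),
    x = rnorm(n), y = rnorm(n)
  )
  tbl$i3[1:50] <- NA # 25% "Not Applicable"
  expect_equal(excluded_items(tbl, mini_schema(), 0.10), "i3")
  out <- score_scales(tbl, mini_schema(), max_missing = 0.10)
  expect_equal(out$s, rep(2, n)) # i3 no longer contributes
  # a 10%-missing item is also dropped at the default threshold
  tbl2 <- tbl
  tbl2$i3 <- 1
  tbl2$i2[1:20] <- NA
  expect_equal(excluded_items(tbl2, mini_schema(), 0.10), "i2")
  # threshold >= 1 switches the policy off
  expect_equal(excluded_items(tbl, mini_schema(), 1.0), character(0))
  out_off <- score_scales(tbl, mini_schema(), max_missing = 1.0)
  expect_true(all(is.na(out_off$s[1:50])))
  expect_error(
    score_scales(tbl, mini_schema(), exclude = c("i1", "i2", "i3")),
    "All items"
  )
})

test_that("imputation is the identity on complete tables", {
  set.seed(2)
  tbl <- tibble::tibble(x = rnorm(20), y = rnorm(20), z = rnorm(20))
  expect_equal(
    impute_predictors(tbl, c("x", "y", "z"), seed = 1),
    tbl,
    ignore_attr = TRUE
  )
})

test_that("a collinear predictor is recovered exactly", {
  set.seed(3)
  x <- rnorm(40)
  tbl <- tibble::tibble(x = x, y = 2 * x, z = rnorm(40))
  tbl$y[7] <- NA
  out <- impute_predictors(tbl, c("x", "y", "z"), seed = 1)
  expect_equal(out$y[7], 2 * x[7], tolerance = 1e-6)
  expect_equal(out$y[-7], tbl$y[-7]) # observed cells untouched
})

test_that("imputation is deterministic and respects legal values", {
  cfg <- sim_config(n = 120, seed = 6)
  tr <- generate_trial(cfg, tlfb = "none")
  preds <- c("motivation", "confidence", "anxiety", "depression")
  a <- impute_predictors(tr$table, preds, default_schema(), seed = 4)
  b <- impute_predictors(tr$table, preds, default_schema(), seed = 4)
  expect_identical(a, b)
  expect_true(all(a$motivation %in% 1:10))
  expect_true(all(a$anxiety %in% 0:63))
  tbl <- tibble::tibble(x = rnorm(10), y = NA_real_)
  expect_error(impute_predictors(tbl, c("x", "y")), "no observed values")
})

test_that("imputation error shrinks when predictors are correlated", {
  rmse_at_rho <- function(rho, seed = 9) {
    set.seed(seed)
    n <- 400
    z <- matrix(rnorm(n * 2), n) %*% chol(matrix(c(1, rho, rho, 1), 2))
    tbl <- tibble::tibble(x = z[, 1], y = z[, 2])
    mask <- sample(n, 80)
    truth <- tbl$y[mask]
    tbl$y[mask] <- NA
    out <- impute_predictors(tbl, c("x", "y"), seed = 1)
    sqrt(mean((out$y[mask] - truth)^2))
  }
  expect_lt(rmse_at_rho(0.8), rmse_at_rho(0))
})

test_that("missing compliance weeks are zero-filled and totals recomputed", {
  tbl <- tibble::tibble(
    comp_01 = c(14, NA, NA), comp_02 = c(12, 10, NA), comp_03 = c(NA, 14, NA)
  )
  out <- handle_compliance(tbl)
  expect_equal(out$comp_01, c(14, 0, 0))
  expect_equal(out$comp_total, c(26, 24, 0))
  full <- tibble::tibble(comp_01 = c(1, 2), comp_02 = c(3, 4))
  expect_equal(handle_compliance(full)$comp_total, c(4, 6))
  expect_error(handle_compliance(tibble::tibble(a = 1)), "compliance")
})

test_that("excluding missing outcomes drops exactly the affected records", {
  set.seed(10)
  tbl <- tibble::tibble(
    id = 1:338, x = rnorm(338), z = rnorm(338),
    prop_change = rnorm(338), raw_change = rnorm(338)
  )
  hole <- sample(338, 60)
  tbl$prop_change[hole] <- NA
  tbl$raw_change[hole] <- NA
  out <- resolve_missing_outcomes(tbl, "exclude")
  expect_equal(nrow(out), 278) # 338 - 60
  expect_equal(attr(out, "dropped_records"), 60)
})

test_that("outcome imputation is deterministic and identity when complete", {
  set.seed(11)
  tbl <- tibble::tibble(
    x = rnorm(60), z = rnorm(60),
    prop_change = rnorm(60), raw_change = rnorm(60)
  )
  expect_equal(
    resolve_missing_outcomes(tbl, "exclude"),
    resolve_missing_outcomes(tbl, "impute", predictors = c("x", "z")),
    ignore_attr = TRUE
  )
  tbl$prop_change[1:10] <- NA
  a <- resolve_missing_outcomes(tbl, "impute", predictors = c("x", "z"), seed = 2)
  b <- resolve_missing_outcomes(tbl, "impute", predictors = c("x", "z"), seed = 2)
  expect_identical(a, b)
  expect_false(anyNA(a$prop_change))
  tbl$prop_change <- NA_real_
  tbl$raw_change <- NA_real_
  expect_error(resolve_missing_outcomes(tbl, "exclude"), "All outcomes")
})

test_that("the pipeline wrapper prepares a generated trial end to end", {
  cfg <- sim_config(n = 150, seed = 17)
  tr <- generate_trial(cfg)
  prep <- prep_trial(tr$table, default_schema(), tlfb = tr$tlfb,
                     missing_outcomes = "exclude", seed = 1)
  log <- attr(prep, "prep_log")
  expect_true("imbibe_parenting" %in% log$excluded_items)
  # the 10%-rate item sits exactly at the exclusion boundary: it is excluded
  # whenever its realized missing fraction reaches the threshold
  frac <- mean(is.na(tr$table$imbibe_marriage))
  expect_equal("imbibe_marriage" %in% log$excluded_items, frac >= 0.10)
  expect_false(anyNA(prep$prop_change))
  expect_false(anyNA(prep$motivation))
  expect_true("imbibe" %in% names(prep))
  expect_true("comp_total" %in% names(prep))
  expect_gt(log$dropped_records, 0)
})
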