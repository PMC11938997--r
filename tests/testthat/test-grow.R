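test_that("a planted single-split interaction is found at the right threshold", {
  dat <- make_interaction_data(n = 600, d0 = 0.8, p_extra = 2, seed = 4)
  fit <- quint(dat, "y", c("x1", "x2", "x3"), prune = FALSE, seed = 1)
  expect_equal(fit$trace$split_var[2], "x1")
  expect_lt(abs(fit$trace$threshold[2]), 0.3)
  # the two sides of the first split carry opposite classes
  first_two <- fit$trace$n_leaves[2]
  expect_equal(first_two, 2L)
})

test_that("data without interaction yields a flagged root-only tree", {
  set.seed(6)
  n <- 200
  dat <- tibble::tibble(
    arm = rep(c("placebo", "active"), n / 2),
    y = rnorm(n), x1 = rnorm(n), x2 = rnorm(n)
  )
  fit <- quint(dat, "y", c("x1", "x2"), seed = 2)
  expect_equal(nrow(fit$leaves), 1L)
  expect_equal(fit$flag, "no qualitative interaction detected")
  expect_equal(fit$leaves$class, "P3")
})

test_that("every record routes to exactly one leaf and counts match", {
  dat <- make_interaction_data(n = 400, seed = 9)
  fit <- quint(dat, "y", c("x1", "x2", "x3"),
    control = quint_control(boot = 5), seed = 3
  )
  memb <- predict(fit, dat)
  expect_false(anyNA(memb$.leaf))
  counts <- table(factor(memb$.leaf, levels = fit$leaves$leaf_id))
  expect_equal(as.integer(counts), fit$leaves$n_p + fit$leaves$n_t)
  expect_equal(sum(counts), nrow(dat))
})

test_that("min_per_arm is respected in every leaf", {
  dat <- make_interaction_data(n = 300, seed = 12)
  ctrl <- quint_control(min_per_arm = 25, boot = 5)
  fit <- quint(dat, "y", c("x1", "x2", "x3"), control = ctrl, seed = 1)
  expect_true(all(fit$leaves$n_p >= 25))
  expect_true(all(fit$leaves$n_t >= 25))
})

test_that("monotone predictor transforms move thresholds, not memberships", {
  dat <- make_interaction_data(n = 350, seed = 15)
  fit1 <- quint(dat, "y", c("x1", "x2"), prune = FALSE, seed = 1)
  dat2 <- dat
  dat2$x1 <- exp(dat$x1)
  dat2$x2 <- exp(dat$x2)
  fit2 <- quint(dat2, "y", c("x1", "x2"), prune = FALSE, seed = 1)
  expect_equal(predict(fit1, dat)$.leaf, predict(fit2, dat2)$.leaf)
  expect_equal(fit1$criterion, fit2$criterion, tolerance = 1e-9)
})

test_that("fitting is deterministic under a fixed seed", {
  dat <- make_interaction_data(n = 300, seed = 18)
  ctrl <- quint_control(boot = 10)
  a <- quint(dat, "y", c("x1", "x2", "x3"), control = ctrl, seed = 7)
  b <- quint(dat, "y", c("x1", "x2", "x3"), control = ctrl, seed = 7)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$leaves, b$leaves)
  expect_identical(a$pruning, b$pruning)
})

test_that("routing sends threshold-equal values left and flags missing features", {
  dat <- make_interaction_data(n = 300, seed = 20)
  fit <- quint(dat, "y", c("x1", "x2"), prune = FALSE, seed = 1)
  thr <- fit$nodes$threshold[!fit$nodes$is_leaf][1]
  var <- fit$nodes$split_var[!fit$nodes$is_leaf][1]
  probe <- dat[1, ]
  probe[[var]] <- thr
  left_leaf <- fit$leaves$leaf_id[
    fit$leaves$node_id == fit$nodes$left[!fit$nodes$is_leaf][1]
  ]
  routed <- predict(fit, probe)
  # value exactly at the threshold goes to the left branch (possibly deeper)
  expect_true(routed$.leaf %in% fit$leaves$leaf_id)
  sub <- fit$nodes[fit$nodes$id == fit$nodes$left[!fit$nodes$is_leaf][1], ]
  if (sub$is_leaf) expect_equal(routed$.leaf, left_leaf)
  probe2 <- probe
  probe2[[var]] <- NA
  expect_error(predict(fit, probe2), "Missing value")
  probe3 <- probe["arm"]
  expect_error(predict(fit, probe3), "missing from")
})

test_that("optimized growth equals the naive reference implementation", {
  ctrl <- quint_control(dmin = 0.3, max_leaves = 3, min_per_arm = 3, boot = 1)
  for (s in 1:12) {
    dat <- make_interaction_data(n = 24, d0 = 1, p_extra = 1, seed = 300 + s)
    fast <- quint(dat, "y", c("x1", "x2"),
      control = ctrl, prune = FALSE, seed = 1
    )
    slow <- naive_quint_grow(dat, "y", c("x1", "x2"), ctrl)
    expect_equal(nrow(fast$leaves), slow$n_leaves)
    expect_equal(fast$criterion, slow$criterion, tolerance = 1e-8)
    if (nrow(slow$trace)) {
      expect_equal(fast$trace$split_var[-1], slow$trace$split_var)
      expect_equal(
        fast$trace$threshold[-1], slow$trace$threshold,
        tolerance = 1e-12
      )
    }
  }
})

test_that("the greedy first split is the global two-leaf optimum", {
  ctrl <- quint_control(min_per_arm = 5, max_leaves = 2, boot = 1)
  for (s in 1:8) {
    dat <- make_interaction_data(n = 80, d0 = 1, p_extra = 1, seed = 500 + s)
    fit <- quint(dat, "y", c("x1", "x2"), control = ctrl, prune = FALSE, seed = 1)
    y <- dat$y
    act <- dat$arm == "active"
    best <- quintree:::root_criterion(ctrl)
    for (v in c("x1", "x2")) {
      xv <- sort(unique(dat[[v]]))
      for (thr in (xv[-1] + xv[-length(xv)]) / 2) {
        L <- which(dat[[v]] <= thr)
        R <- setdiff(seq_len(nrow(dat)), L)
        ndl <- quintree:::leaf_nd(y, act, L)
        ndr <- quintree:::leaf_nd(y, act, R)
        if (min(ndl[c("n_p", "n_t")], ndr[c("n_p", "n_t")]) < 5) next
        if (anyNA(c(ndl["d"], ndr["d"]))) next
        asg <- optimal_assignment(
          tibble::tibble(
            n_p = c(ndl["n_p"], ndr["n_p"]),
            n_t = c(ndl["n_t"], ndr["n_t"]),
            d = c(ndl["d"], ndr["d"])
          ),
          ctrl
        )
        if (!is.null(asg)) best <- max(best, asg$criterion)
      }
    }
    expect_equal(fit$criterion, best, tolerance = 1e-9)
  }
})
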