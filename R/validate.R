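# Bootstrap optimism validation of the effect-size range, and cross-outcome
# model comparison.

#' Bootstrap optimism of the leaf effect-size range
#'
#' The largest risk of bias in a qualitative interaction tree is
#' overestimating the spread between the most extreme leaf effects, because
#' the algorithm actively searches for large positive and negative effects.
#' Following the small-sample validation recipe: `B` bootstrap samples
#' (stratified by arm) are drawn from the data; on each, a tree with the same
#' maximum number of leaves as the primary fit is regrown; the difference
#' between the largest and smallest leaf effect on the resample
#' (`range_boot`) is compared with the range obtained when the same fitted
#' tree is applied back to the original table (`range_orig`). The mean
#' difference `O_range` estimates the optimism: positive values mean the
#' fitted range overstates the true spread, values near zero mean no bias.
#'
#' Replicates whose regrown tree admits no qualitative interaction (fewer
#' than 2 leaves) are dropped and counted. Leaves that cannot be evaluated on
#' the original table (an arm with fewer than 2 participants) are omitted
#' from `range_orig`; a replicate with no evaluable leaf is dropped.
#'
#' @param data Participant data frame with complete outcome and predictors.
#' @param outcome,predictors,arm,control As in [quint()]. `control$max_leaves`
#'   is overridden by `leaf_count`.
#' @param leaf_count Number of leaves of the primary fitted model (bootstrap
#'   refits are grown to at most this size).
#' @param B Number of bootstrap samples (default 1000).
#' @param scale `"d"` (Cohen's d, default) or `"delta"` (mean difference) for
#'   the effect range.
#' @param seed Integer seed.
#' @param resample `"stratified"` (default) or `"identity"` (degenerate
#'   diagnostic bootstrap: every resample is the original table, so every
#'   difference — and `O_range` — is exactly 0).
#' @return An `optimism_report`: list with per-replicate tibble `reps`
#'   (`b`, `size`, `range_boot`, `range_orig`, `diff`), `o_range`,
#'   `observed_range` (range of the apparent fit on the original data),
#'   `inflation_pct` (`100 * o_range / observed_range`), `dropped`, `B`,
#'   `scale`, `outcome`, `leaf_count`, `seed`.
#' @export
optimism_range <- function(data, outcome, predictors, leaf_count,
                           arm = "arm", control = quint_control(),
                           B = 1000, scale = c("d", "delta"), seed = 1L,
                           resample = c("stratified", "identity")) {
  scale <- arg_match(scale)
  resample <- arg_match(resample)
  if (leaf_count < 2) abort("`leaf_count` must be at least 2.")
  dat <- check_fit_data(data, outcome, predictors, arm)
  control$max_leaves <- as.integer(leaf_count)
  set.seed(as.integer(seed))

  apparent <- grow_fit(dat$y, dat$act, dat$X, control)
  observed_range <- fit_range(apparent, dat$y, dat$act, scale)

  reps <- vector("list", B)
  dropped <- 0L
  for (b in seq_len(B)) {
    idx <- resample_rows(dat$act, identity = resample == "identity")
    bfit <- grow_fit(
      dat$y[idx], dat$act[idx], dat$X[idx, , drop = FALSE], control
    )
    kb <- length(bfit$leaves_at)
    if (kb < 2L) {
      dropped <- dropped + 1L
      next
    }
    range_boot <- fit_range(bfit, dat$y[idx], dat$act[idx], scale)
    node_of <- route_matrix(bfit, kb, dat$X)
    eff <- leaf_set_effects(bfit$leaves_at[[kb]], node_of, dat$y, dat$act)
    vals <- eff[[scale]][!is.na(eff$d)]
    if (!length(vals)) {
      dropped <- dropped + 1L
      next
    }
    reps[[b]] <- tibble(
      b = b, size = kb,
      range_boot = range_boot,
      range_orig = max(vals) - min(vals)
    )
  }
  reps <- dplyr::bind_rows(reps) %>%
    mutate(diff = range_boot - range_orig)
  o_range <- if (nrow(reps)) mean(reps$diff) else NA_real_

  structure(
    list(
      reps = reps,
      o_range = o_range,
      observed_range = observed_range,
      inflation_pct = if (!is.na(observed_range) && observed_range > 0) {
        inflation_percent(o_range, observed_range)
      } else {
        NA_real_
      },
      dropped = dropped, B = as.integer(B), scale = scale,
      outcome = outcome, leaf_count = as.integer(leaf_count),
      seed = as.integer(seed)
    ),
    class = "optimism_report"
  )
}

# Effect range of a gfit's final leaves on its own fitting data.
fit_range <- function(gfit, y, act, scale) {
  k <- length(gfit$leaves_at)
  if (k < 2L) {
    return(NA_real_)
  }
  leaf_ids <- gfit$leaves_at[[k]]
  eff <- purrr::map_dfr(leaf_ids, function(v) {
    rows <- gfit$rows_of[[v]]
    leaf_effect(y[rows][!act[rows]], y[rows][act[rows]])
  })
  effect_range(eff, scale)
}

# Leaf effect summaries for routed membership; NA row when an arm has < 2.
leaf_set_effects <- function(leaf_ids, node_of, y, act) {
  purrr::map_dfr(leaf_ids, function(v) {
    rows <- which(node_of == v)
    p <- y[rows][!act[rows]]
    t <- y[rows][act[rows]]
    if (length(p) < 2 || length(t) < 2) {
      tibble(delta = NA_real_, d = NA_real_)
    } else {
      leaf_effect(p, t)[, c(
        "n_p", "n_t", "mean_p", "mean_t", "delta", "se", "s_pool",
        "d", "ci_lo", "ci_hi"
      )]
    }
  })
}

#' @export
print.optimism_report <- function(x, ...) {
  cat(
    "<optimism_report> outcome:", x$outcome,
    " leaves:", x$leaf_count, " B =", x$B, "\n"
  )
  cat(sprintf(
    "  O_range = %.4f on the %s scale (%d replicates, %d dropped)\n",
    x$o_range, x$scale, nrow(x$reps), x$dropped
  ))
  cat(sprintf(
    "  observed range = %.4f; estimated inflation = %.1f%%\n",
    x$observed_range, x$inflation_pct
  ))
  invisible(x)
}

#' Percent inflation of the effect-size range
#'
#' @param o_range Mean bootstrap optimism of the range.
#' @param observed_range Range of leaf effects of the primary fit (> 0).
#' @return `100 * o_range / observed_range`.
#' @examples
#' inflation_percent(0.64, 1.12)
#' @export
inflation_percent <- function(o_range, observed_range) {
  if (!is.numeric(observed_range) || observed_range <= 0) {
    abort("`observed_range` must be positive.")
  }
  100 * o_range / observed_range
}

#' Evaluate fitted trees against every outcome
#'
#' Each fitted tree subdivides the participants; for every (tree, leaf,
#' outcome) combination the observed Cohen's *d* with a 95% confidence
#' interval is computed on that outcome via [leaf_effect()]. Comparing the
#' columns of the result shows whether trees trained on different outcomes
#' predict similar treatment effects.
#'
#' @param trees A named list of `quint_tree` objects (names label the models;
#'   defaults to each tree's training outcome).
#' @param data Participant data frame carrying all `outcomes` and every split
#'   feature.
#' @param outcomes Character vector of outcome columns to evaluate.
#' @return A tibble ordered by (model, leaf, outcome): `model`, `leaf`,
#'   `class`, `outcome`, `n_p`, `n_t`, `delta`, `se`, `d`, `ci_lo`, `ci_hi`.
#'   Leaves with an empty arm on an outcome's complete-case subset keep the
#'   row with `d` omitted (NA).
#' @export
cross_outcome_table <- function(trees, data, outcomes) {
  if (inherits(trees, "quint_tree")) trees <- list(trees)
  if (is.null(names(trees)) || any(!nzchar(names(trees)))) {
    names(trees) <- vapply(trees, `[[`, "", "outcome")
  }
  miss <- setdiff(outcomes, names(data))
  if (length(miss)) {
    abort(paste0("Outcome(s) not in `data`: ", paste(miss, collapse = ", ")))
  }
  purrr::map_dfr(names(trees), function(mod) {
    tree <- trees[[mod]]
    memb <- predict(tree, data)
    purrr::map_dfr(tree$leaves$leaf_id, function(lf) {
      in_leaf <- memb$.leaf == lf
      purrr::map_dfr(outcomes, function(oc) {
        y <- data[[oc]]
        ok <- in_leaf & !is.na(y)
        p <- y[ok & data$arm == "placebo"]
        t <- y[ok & data$arm == "active"]
        base <- tibble(
          model = mod, leaf = lf,
          class = tree$leaves$class[tree$leaves$leaf_id == lf],
          outcome = oc,
          n_p = length(p), n_t = length(t)
        )
        if (length(p) < 2 || length(t) < 2) {
          return(mutate(base,
            delta = NA_real_, se = NA_real_, d = NA_real_,
            ci_lo = NA_real_, ci_hi = NA_real_
          ))
        }
        dplyr::bind_cols(
          base,
          leaf_effect(p, t)[, c("delta", "se", "d", "ci_lo", "ci_hi")]
        )
      })
    })
  }) %>%
    arrange(model, leaf, outcome)
}
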