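#' Two-arm effect summary for one leaf (or any subgroup)
#'
#' Computes the per-leaf comparison statistics reported for a qualitative
#' interaction tree: arm sample sizes, means and SDs, the mean difference
#' `delta = mean_p - mean_t` (placebo minus active, the tables' "\\u0394Mean"
#' convention), the pooled SD, the pooled-variance standard error of the mean
#' difference, Cohen's *d* `(mean_t - mean_p) / s_pool` (positive when the
#' active arm reduces drinking more than placebo) and its normal-theory 95%
#' confidence interval `d \\u00b1 1.96 * se / s_pool`.
#'
#' Pooled variance is `((n_p-1) sd_p^2 + (n_t-1) sd_t^2) / (n_p+n_t-2)` and
#' `se = s_pool * sqrt(1/n_p + 1/n_t)`. No small-sample (Hedges) correction is
#' applied unless `hedges = TRUE`.
#'
#' @param placebo,treatment Numeric vectors of outcome values, one per arm;
#'   each arm needs at least 2 values.
#' @param hedges Apply the Hedges small-sample correction factor
#'   `1 - 3/(4(n_p+n_t)-9)` to `d` and its CI? Default `FALSE`.
#' @return A one-row tibble with columns `n_p`, `mean_p`, `sd_p`, `n_t`,
#'   `mean_t`, `sd_t`, `delta`, `s_pool`, `se`, `d`, `ci_lo`, `ci_hi`.
#' @examples
#' leaf_effect(rnorm(20), rnorm(20, 0.5))
#' @export
leaf_effect <- function(placebo, treatment, hedges = FALSE) {
  placebo <- as.numeric(placebo)
  treatment <- as.numeric(treatment)
  if (anyNA(placebo) || anyNA(treatment)) {
    abort("Arm values must be complete (resolve missing outcomes first).")
  }
  if (length(placebo) < 2 || length(treatment) < 2) {
    abort("Degenerate leaf: each arm needs at least 2 values.")
  }
  leaf_effect_from_summary(
    n_p = length(placebo), mean_p = mean(placebo), sd_p = sd(placebo),
    n_t = length(treatment), mean_t = mean(treatment), sd_t = sd(treatment),
    hedges = hedges
  )
}

#' Effect summary from per-arm summary statistics
#'
#' Identical arithmetic to [leaf_effect()] but starting from per-arm `n`,
#' mean and SD — the form in which published per-leaf results are reported —
#' rather than raw outcome values.
#'
#' @param n_p,mean_p,sd_p Placebo-arm size, mean and sample SD (denominator
#'   `n - 1`). Vectorized.
#' @param n_t,mean_t,sd_t Active-arm size, mean and sample SD.
#' @inheritParams leaf_effect
#' @return A tibble, one row per input element; columns as in [leaf_effect()].
#' @examples
#' leaf_effect_from_summary(10, 0.84, 0.24, 11, 0.38, 0.43)
#' @export
leaf_effect_from_summary <- function(n_p, mean_p, sd_p, n_t, mean_t, sd_t,
                                     hedges = FALSE) {
  if (any(n_p < 2) || any(n_t < 2)) {
    abort("Degenerate leaf: each arm needs at least 2 values.")
  }
  s_pool <- sqrt(((n_p - 1) * sd_p^2 + (n_t - 1) * sd_t^2) / (n_p + n_t - 2))
  se <- s_pool * sqrt(1 / n_p + 1 / n_t)
  delta <- mean_p - mean_t
  d <- ifelse(s_pool > 0, (mean_t - mean_p) / s_pool, 0)
  half <- ifelse(s_pool > 0, 1.96 * se / s_pool, 0)
  if (hedges) {
    j <- 1 - 3 / (4 * (n_p + n_t) - 9)
    d <- d * j
    half <- half * j
  }
  tibble(
    n_p = as.integer(n_p), mean_p = mean_p, sd_p = sd_p,
    n_t = as.integer(n_t), mean_t = mean_t, sd_t = sd_t,
    delta = delta, s_pool = s_pool, se = se,
    d = d, ci_lo = d - half, ci_hi = d + half
  )
}

#' Range of leaf effect sizes
#'
#' The spread (max minus min) of per-leaf treatment effects across the leaves
#' of a fitted tree — the statistic whose optimism the bootstrap validation
#' estimates.
#'
#' @param effects A data frame of leaf effect summaries (as produced by
#'   [leaf_effect()] rows or stored in a fitted tree), or a numeric vector of
#'   effect sizes.
#' @param scale `"d"` (Cohen's *d*, default) or `"delta"` (mean difference).
#'   Ignored when `effects` is already a numeric vector.
#' @return A non-negative number; 0 for a single effect.
#' @examples
#' effect_range(c(0.46, -0.59, -0.13, 0.05, 0.53, 0.05))
#' @export
effect_range <- function(effects, scale = c("d", "delta")) {
  scale <- arg_match(scale)
  x <- if (is.numeric(effects)) {
    effects
  } else {
    effects[[scale]]
  }
  x <- x[!is.na(x)]
  if (!length(x)) abort("`effects` must contain at least one effect size.")
  max(x) - min(x)
}

# Per-arm prefix statistics -> effect summaries, used by the split scan and
# by leaf summaries computed in bulk. Returns list of vectors.
arm_stats <- function(y, active) {
  n_t <- sum(active)
  n_p <- length(y) - n_t
  list(
    n_p = n_p, n_t = n_t,
    mean_p = if (n_p) mean(y[!active]) else NA_real_,
    mean_t = if (n_t) mean(y[active]) else NA_real_,
    sd_p = if (n_p > 1) sd(y[!active]) else NA_real_,
    sd_t = if (n_t > 1) sd(y[active]) else NA_real_
  )
}
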