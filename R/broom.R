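#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a fitted qualitative interaction tree
#'
#' @param x A `quint_tree`.
#' @param ... Unused.
#' @return A tibble with one row per leaf: `leaf`, `class`, `rule`, per-arm
#'   `n`/mean/SD, `delta` (placebo minus active mean), `se`, Cohen's `d` and
#'   its 95% CI.
#' @export
tidy.quint_tree <- function(x, ...) {
  x$leaves %>%
    rename(leaf = leaf_id) %>%
    select(-"node_id")
}

#' One-row summary of a fitted qualitative interaction tree
#'
#' @param x A `quint_tree`.
#' @param ... Unused.
#' @return A one-row tibble: sample size, leaf count, class counts, criterion,
#'   outcome name, flag.
#' @export
glance.quint_tree <- function(x, ...) {
  tibble(
    n = x$n,
    n_leaves = nrow(x$leaves),
    n_responder = sum(x$leaves$class == "P1"),
    n_iatrogenic = sum(x$leaves$class == "P2"),
    n_nonresponder = sum(x$leaves$class == "P3"),
    criterion = x$criterion,
    outcome = x$outcome,
    flag = x$flag
  )
}

#' Attach leaf membership to participant data
#'
#' @param x A `quint_tree`.
#' @param data Data frame of participants to route (defaults must be
#'   supplied; the tree does not store its training data).
#' @param ... Unused.
#' @return `data` with `.leaf` and `.class` columns appended.
#' @export
augment.quint_tree <- function(x, data, ...) {
  dplyr::bind_cols(as_tibble(data), predict(x, data))
}

#' Tidy / summarize a bootstrap optimism report
#'
#' @param x An `optimism_report` from [optimism_range()].
#' @param ... Unused.
#' @return `tidy()`: the per-replicate tibble (`b`, `range_boot`,
#'   `range_orig`, `diff`). `glance()`: a one-row summary with `o_range`,
#'   `observed_range`, `inflation_pct`, `B`, `dropped`, `scale`.
#' @export
tidy.optimism_report <- function(x, ...) {
  x$reps
}

#' @rdname tidy.optimism_report
#' @export
glance.optimism_report <- function(x, ...) {
  tibble(
    o_range = x$o_range,
    observed_range = x$observed_range,
    inflation_pct = x$inflation_pct,
    B = x$B,
    dropped = x$dropped,
    scale = x$scale,
    outcome = x$outcome,
    leaf_count = x$leaf_count
  )
}
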