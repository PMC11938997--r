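# Leaf-class palette used throughout: responders green, iatrogenic red,
# nonresponders taupe.
quint_class_colors <- c(
  P1 = "#2e7d32", P2 = "#c62828", P3 = "#b8a78f"
)

#' Plot per-leaf treatment effects of a fitted tree
#'
#' Leaf Cohen's *d* with 95% confidence intervals, colored by leaf class
#' (green = treatment responder, red = iatrogenic responder,
#' taupe = nonresponder). Positive *d* means the active arm is predicted to
#' reduce drinking more than placebo.
#'
#' @param object A `quint_tree`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quint_tree <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(leaf), y = d, color = class
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = ci_lo, ymax = ci_hi)) +
    ggplot2::scale_color_manual(
      values = quint_class_colors,
      labels = c(
        P1 = "treatment responder", P2 = "iatrogenic responder",
        P3 = "nonresponder"
      )
    ) +
    ggplot2::labs(
      x = "leaf", y = "Cohen's d (active vs placebo)",
      color = NULL, title = paste("QUINT leaves:", object$outcome)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cross-outcome model comparison
#'
#' Displays the output of [cross_outcome_table()]: per-leaf Cohen's *d* with
#' 95% CI on each outcome, faceted by the model (training outcome) the tree
#' was fitted to.
#'
#' @param comparison A tibble from [cross_outcome_table()].
#' @return A ggplot object.
#' @export
plot_comparison <- function(comparison) {
  ggplot2::ggplot(comparison, ggplot2::aes(
    x = factor(leaf), y = d,
    color = outcome, shape = outcome
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = ci_lo, ymax = ci_hi),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::facet_wrap(~model, scales = "free_x") +
    ggplot2::labs(
      x = "leaf", y = "Cohen's d (active vs placebo)",
      color = "evaluated outcome", shape = "evaluated outcome"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a bootstrap optimism report
#'
#' Histogram of per-replicate optimism (`range_boot - range_orig`) with the
#' mean optimism `O_range` marked.
#'
#' @param object An `optimism_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.optimism_report <- function(object, ...) {
  ggplot2::ggplot(object$reps, ggplot2::aes(x = diff)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", color = "white") +
    ggplot2::geom_vline(
      xintercept = object$o_range, color = "#c62828", linewidth = 1
    ) +
    ggplot2::labs(
      x = "bootstrap optimism of the effect-size range",
      y = "replicates",
      title = sprintf(
        "O_range = %.3f (observed range %.3f, inflation %.0f%%)",
        object$o_range, object$observed_range, object$inflation_pct
      )
    ) +
    ggplot2::theme_minimal()
}
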