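#' Fit a qualitative interaction tree
#'
#' Greedily partitions a two-arm randomized trial into leaves with homogeneous
#' treatment effects, assigns each leaf a class — P1 treatment responder
#' (active beats placebo), P2 iatrogenic responder (placebo beats active) or
#' P3 nonresponder — by exhaustive search over admissible assignments, and
#' selects the tree size by bias-corrected bootstrap pruning.
#'
#' Candidate splits are midpoints of consecutive distinct observed predictor
#' values; a value equal to the threshold routes left. Splits leaving fewer
#' than `min_per_arm` participants in either arm of either child are
#' inadmissible. Growth stops when no split improves the criterion or
#' `max_leaves` is reached; when no first split admits a qualitative
#' interaction the fit is a root-only tree flagged
#' `"no qualitative interaction detected"`.
#'
#' @param data A data frame with one row per participant: the `arm` column,
#'   the outcome column, and complete numeric predictor columns
#'   (impute predictors and resolve missing outcomes first; see
#'   [impute_predictors()] and [resolve_missing_outcomes()]).
#' @param outcome Name of the outcome column (e.g. `"prop_change"` or
#'   `"raw_change"`).
#' @param predictors Character vector of predictor column names (numeric;
#'   ordinal and binary predictors are treated as numeric).
#' @param arm Name of the arm column; values must be `"placebo"`/`"active"`
#'   (factor or character).
#' @param control A [quint_control()] object.
#' @param seed Integer seed covering growth and bootstrap pruning.
#' @param prune Run bias-corrected bootstrap pruning? Default `TRUE`.
#' @param resample Bootstrap resampling scheme for pruning: `"stratified"`
#'   (by arm, the default) or `"identity"` (degenerate diagnostic mode in
#'   which every resample is the original table, so all optimism is 0).
#' @return An object of class `quint_tree`; see [tidy.quint_tree()],
#'   [glance.quint_tree()], [predict.quint_tree()], [autoplot.quint_tree()],
#'   [write_quint_tree()].
#' @examples
#' trial <- generate_trial(sim_config(n = 240, seed = 7), tlfb = "none")
#' dat <- resolve_missing_outcomes(trial$table, strategy = "exclude")
#' fit <- quint(dat, "prop_change", c("motivation", "anxiety"),
#'   control = quint_control(min_per_arm = 15, boot = 10, max_leaves = 3),
#'   seed = 1
#' )
#' tidy(fit)
#' @export
quint <- function(data, outcome, predictors, arm = "arm",
                  control = quint_control(), seed = 1L,
                  prune = TRUE, resample = c("stratified", "identity")) {
  resample <- arg_match(resample)
  dat <- check_fit_data(data, outcome, predictors, arm)
  set.seed(as.integer(seed))
  gfit <- grow_fit(dat$y, dat$act, dat$X, control)
  if (prune) {
    pr <- prune_fit(gfit, dat$y, dat$act, dat$X, control, resample = resample)
  } else {
    pr <- list(size = length(gfit$leaves_at), table = NULL)
  }
  new_quint_tree(gfit, pr$size, dat, outcome, predictors, control,
    seed = seed, pruning = pr$table
  )
}

check_fit_data <- function(data, outcome, predictors, arm) {
  stopifnot(is.data.frame(data))
  miss <- setdiff(c(outcome, predictors, arm), names(data))
  if (length(miss)) {
    abort(paste0("Column(s) not in `data`: ", paste(miss, collapse = ", ")))
  }
  a <- as.character(data[[arm]])
  if (!setequal(unique(a), c("placebo", "active"))) {
    abort('`arm` must take exactly the two values "placebo" and "active".')
  }
  y <- data[[outcome]]
  if (!is.numeric(y) || anyNA(y)) {
    abort(paste0(
      "Outcome `", outcome, "` must be numeric with no missing values; ",
      "use resolve_missing_outcomes() first."
    ))
  }
  X <- as.matrix(data[predictors])
  if (!is.numeric(X) || anyNA(X)) {
    abort("Predictors must be numeric and complete; impute first.")
  }
  list(y = as.numeric(y), act = a == "active", X = X)
}

# Build the exported tree object from a gfit truncated at `size` leaves,
# with classes re-derived on the full table.
new_quint_tree <- function(gfit, size, dat, outcome, predictors, control,
                           seed, pruning = NULL) {
  leaf_nodes <- subtree_leaves(gfit, size) # depth-first left-first order
  internal <- subtree_internal(gfit, size)
  keep <- sort(c(internal, leaf_nodes))

  nodes <- tibble(
    id = keep,
    parent = gfit$parent[keep],
    depth = gfit$depth[keep],
    is_leaf = keep %in% leaf_nodes,
    split_var = ifelse(keep %in% internal,
      gfit$vars[gfit$split_var[keep]], NA_character_
    ),
    threshold = ifelse(keep %in% internal, gfit$threshold[keep], NA_real_),
    left = ifelse(keep %in% internal, gfit$left[keep], NA_integer_),
    right = ifelse(keep %in% internal, gfit$right[keep], NA_integer_),
    leaf_id = match(keep, leaf_nodes)
  )

  eff <- purrr::map_dfr(leaf_nodes, function(v) {
    rows <- gfit$rows_of[[v]]
    leaf_effect(dat$y[rows][!dat$act[rows]], dat$y[rows][dat$act[rows]])
  })
  asg <- optimal_assignment(eff, control)
  flag <- "ok"
  if (is.null(asg)) {
    classes <- rep("P3", length(leaf_nodes))
    criterion <- root_criterion(control)
    if (length(leaf_nodes) == 1L) flag <- "no qualitative interaction detected"
  } else {
    classes <- asg$assignment
    criterion <- asg$criterion
  }

  leaves <- dplyr::bind_cols(
    tibble(
      leaf_id = seq_along(leaf_nodes),
      node_id = leaf_nodes,
      class = classes,
      rule = vapply(
        leaf_nodes, function(v) leaf_rule(gfit, v), character(1)
      )
    ),
    eff
  )

  structure(
    list(
      nodes = nodes, leaves = leaves,
      outcome = outcome, predictors = predictors,
      control = unclass(control), seed = as.integer(seed),
      criterion = criterion, flag = flag,
      trace = gfit$trace, pruning = pruning,
      n = gfit$N, config_hash = config_hash(control)
    ),
    class = "quint_tree"
  )
}

# Human-readable path from root to node, "≤" on left branches.
leaf_rule <- function(gfit, v) {
  parts <- character(0)
  while (!is.na(gfit$parent[v])) {
    p <- gfit$parent[v]
    op <- if (gfit$left[p] == v) "≤" else ">"
    parts <- c(
      sprintf(
        "%s %s %.6g", gfit$vars[gfit$split_var[p]], op, gfit$threshold[p]
      ),
      parts
    )
    v <- p
  }
  if (!length(parts)) "(root)" else paste(parts, collapse = " & ")
}

# Polynomial rolling hash over the deparsed control list; configuration
# fingerprint stored in the tree and its JSON serialization.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.quint_tree <- function(x, ...) {
  cat(
    "<quint_tree> outcome:", x$outcome, " n =", x$n,
    " leaves =", nrow(x$leaves), "\n"
  )
  if (x$flag != "ok") cat("  [", x$flag, "]\n", sep = "")
  cat("  criterion:", format(x$criterion, digits = 4), "\n")
  df <- x$leaves
  for (i in seq_len(nrow(df))) {
    cat(sprintf(
      "  leaf %d [%s] n=%d+%d d=%+.2f  %s\n",
      df$leaf_id[i], df$class[i], df$n_p[i], df$n_t[i], df$d[i], df$rule[i]
    ))
  }
  invisible(x)
}

#' Route participants through a fitted tree
#'
#' @param object A `quint_tree`.
#' @param newdata Data frame containing every split feature of the tree.
#' @param ... Unused.
#' @return A tibble with one row per row of `newdata`: `.leaf` (leaf id) and
#'   `.class` (`"P1"`, `"P2"` or `"P3"`). A value equal to a split threshold
#'   routes to the left branch.
#' @export
predict.quint_tree <- function(object, newdata, ...) {
  used <- unique(object$nodes$split_var[!is.na(object$nodes$split_var)])
  miss <- setdiff(used, names(newdata))
  if (length(miss)) {
    abort(paste0(
      "Split feature(s) missing from `newdata`: ", paste(miss, collapse = ", ")
    ))
  }
  node_of <- route_tree(object, newdata)
  leaf <- object$leaves$leaf_id[match(node_of, object$leaves$node_id)]
  tibble(
    .leaf = leaf,
    .class = object$leaves$class[leaf]
  )
}

route_tree <- function(tree, newdata) {
  nodes <- tree$nodes
  node_of <- rep(nodes$id[1L], nrow(newdata))
  for (i in which(!nodes$is_leaf)) {
    here <- node_of == nodes$id[i]
    if (!any(here)) next
    xv <- newdata[[nodes$split_var[i]]]
    if (anyNA(xv[here])) {
      abort(paste0("Missing value in split feature `", nodes$split_var[i], "`."))
    }
    go_left <- xv <= nodes$threshold[i]
    node_of[here & go_left] <- nodes$left[i]
    node_of[here & !go_left] <- nodes$right[i]
  }
  node_of
}
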