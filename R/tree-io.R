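# JSON serialization of fitted trees. Thresholds and effect summaries are
# stored at full double precision, so write -> read -> write is
# byte-identical and a reloaded tree routes records exactly as the original.

#' Write a fitted tree to JSON
#'
#' The document layout is: `format`/`version` header; fit metadata
#' (`outcome`, `predictors`, `seed`, `control`, `config_hash`, `criterion`,
#' `flag`, `n`); `nodes`, an array of `{id, parent, depth, is_leaf}` records
#' where internal nodes add `{split_var, threshold, rule, left, right}` (the
#' rule text renders the left branch with `"≤"`); `leaves`, an array of
#' `{leaf_id, node_id, class, rule, effect}` with the full
#' [leaf_effect()] summary; plus the growth `trace` and, when pruned, the
#' `pruning` table. Numbers are written at full precision.
#'
#' @param tree A `quint_tree`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_quint_tree <- function(tree, path) {
  nodes <- purrr::pmap(tree$nodes, function(id, parent, depth, is_leaf,
                                            split_var, threshold, left,
                                            right, leaf_id) {
    rec <- list(
      id = id, parent = if (is.na(parent)) NULL else parent,
      depth = depth, is_leaf = is_leaf
    )
    if (!is_leaf) {
      rec$split_var <- split_var
      rec$threshold <- threshold
      rec$rule <- sprintf("%s ≤ %.17g", split_var, threshold)
      rec$left <- left
      rec$right <- right
    } else {
      rec$leaf_id <- leaf_id
    }
    rec
  })
  leaves <- purrr::pmap(tree$leaves, function(leaf_id, node_id, class, rule,
                                              ...) {
    list(
      leaf_id = leaf_id, node_id = node_id, class = class, rule = rule,
      effect = list(...)
    )
  })
  doc <- list(
    format = "quint_tree", version = 1L,
    outcome = tree$outcome, predictors = as.list(tree$predictors),
    seed = tree$seed, control = tree$control,
    config_hash = tree$config_hash,
    criterion = tree$criterion, flag = tree$flag, n = tree$n,
    nodes = nodes, leaves = leaves,
    trace = tree$trace,
    pruning = tree$pruning
  )
  jsonlite::write_json(
    doc, path,
    auto_unbox = TRUE, digits = I(17), null = "null", na = "null",
    pretty = TRUE
  )
  invisible(path)
}

#' Read a fitted tree from JSON
#'
#' Parses and validates a document written by [write_quint_tree()]; the
#' result is structurally identical to the tree that was written (splits,
#' thresholds, leaf classes and effect summaries at full precision). A
#' malformed document raises a parse error naming the offending JSON path.
#'
#' @param path A `.json` file.
#' @return A `quint_tree`.
#' @export
read_quint_tree <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) abort(paste0("Not parseable JSON: ", conditionMessage(e)))
  )
  if (!identical(doc$format, "quint_tree")) {
    abort("$format: expected \"quint_tree\".")
  }
  for (f in c("outcome", "seed", "control", "nodes", "leaves")) {
    if (is.null(doc[[f]])) abort(paste0("$", f, ": missing."))
  }
  nodes <- purrr::imap_dfr(doc$nodes, function(nd, i) {
    for (f in c("id", "depth", "is_leaf")) {
      if (is.null(nd[[f]])) abort(sprintf("$nodes[%d]$%s: missing.", i, f))
    }
    if (!nd$is_leaf) {
      for (f in c("split_var", "threshold", "left", "right")) {
        if (is.null(nd[[f]])) abort(sprintf("$nodes[%d]$%s: missing.", i, f))
      }
    }
    tibble(
      id = as.integer(nd$id),
      parent = as.integer(nd$parent %||% NA),
      depth = as.integer(nd$depth),
      is_leaf = isTRUE(nd$is_leaf),
      split_var = as.character(nd$split_var %||% NA),
      threshold = as.numeric(nd$threshold %||% NA),
      left = as.integer(nd$left %||% NA),
      right = as.integer(nd$right %||% NA),
      leaf_id = as.integer(nd$leaf_id %||% NA)
    )
  })
  leaves <- purrr::imap_dfr(doc$leaves, function(lf, i) {
    for (f in c("leaf_id", "node_id", "class", "effect")) {
      if (is.null(lf[[f]])) abort(sprintf("$leaves[%d]$%s: missing.", i, f))
    }
    if (!lf$class %in% c("P1", "P2", "P3")) {
      abort(sprintf("$leaves[%d]$class: must be P1, P2 or P3.", i))
    }
    eff <- lf$effect
    dplyr::bind_cols(
      tibble(
        leaf_id = as.integer(lf$leaf_id), node_id = as.integer(lf$node_id),
        class = lf$class, rule = as.character(lf$rule %||% NA)
      ),
      tibble(
        n_p = as.integer(eff$n_p), mean_p = as.numeric(eff$mean_p),
        sd_p = as.numeric(eff$sd_p),
        n_t = as.integer(eff$n_t), mean_t = as.numeric(eff$mean_t),
        sd_t = as.numeric(eff$sd_t),
        delta = as.numeric(eff$delta), s_pool = as.numeric(eff$s_pool),
        se = as.numeric(eff$se), d = as.numeric(eff$d),
        ci_lo = as.numeric(eff$ci_lo), ci_hi = as.numeric(eff$ci_hi)
      )
    )
  })
  parse_tbl <- function(x) {
    if (is.null(x)) {
      return(NULL)
    }
    dplyr::bind_rows(lapply(x, function(row) {
      as_tibble(lapply(row, function(v) if (is.null(v)) NA else v))
    }))
  }
  trace <- parse_tbl(doc$trace)
  if (!is.null(trace)) {
    trace <- mutate(trace,
      step = as.integer(step), n_leaves = as.integer(n_leaves),
      node = as.integer(node), split_var = as.character(split_var),
      threshold = as.numeric(threshold), criterion = as.numeric(criterion)
    )
  }
  pruning <- parse_tbl(doc$pruning)
  if (!is.null(pruning)) {
    pruning <- mutate(pruning,
      k = as.integer(k), n_boot = as.integer(n_boot),
      dropped = as.integer(dropped), selected = as.logical(selected)
    )
  }
  structure(
    list(
      nodes = nodes, leaves = leaves,
      outcome = doc$outcome,
      predictors = as.character(unlist(doc$predictors)),
      control = {
        ct <- doc$control
        for (f in c("a1", "a2", "dmin", "c_se")) {
          if (!is.null(ct[[f]])) ct[[f]] <- as.numeric(ct[[f]])
        }
        for (f in c("max_leaves", "min_per_arm", "boot")) {
          if (!is.null(ct[[f]])) ct[[f]] <- as.integer(ct[[f]])
        }
        ct
      },
      seed = as.integer(doc$seed),
      criterion = as.numeric(doc$criterion),
      flag = doc$flag, trace = trace, pruning = pruning,
      n = as.integer(doc$n), config_hash = doc$config_hash
    ),
    class = "quint_tree"
  )
}
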