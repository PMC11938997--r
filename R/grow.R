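# Greedy growth of a qualitative interaction tree.
#
# Internal fit representation ("gfit"): flat parallel vectors over node ids
# (parents precede children), plus per-node membership rows and (n_p, n_t, d)
# summaries on the fitting data, and the growth trace. The exported surface
# wraps this in a `quint_tree` (see tree.R).

leaf_nd <- function(y, act, rows) {
  yy <- y[rows]
  aa <- act[rows]
  n_t <- sum(aa)
  n_p <- length(rows) - n_t
  if (n_p < 2 || n_t < 2) {
    return(c(n = n_p + n_t, n_p = n_p, n_t = n_t, d = NA_real_))
  }
  mp <- mean(yy[!aa])
  mt <- mean(yy[aa])
  vp <- var(yy[!aa])
  vt <- var(yy[aa])
  sp <- sqrt(((n_p - 1) * vp + (n_t - 1) * vt) / (n_p + n_t - 2))
  d <- if (sp > 0) (mt - mp) / sp else 0
  c(n = n_p + n_t, n_p = n_p, n_t = n_t, d = d)
}

# Scan all candidate thresholds (midpoints of consecutive distinct observed
# values) of one predictor within one leaf. Returns NULL when no candidate
# satisfies the min-per-arm rule, else the best threshold by criterion
# (ties -> smallest threshold).
scan_leaf_split <- function(rows, x, y, act, fixed_n, fixed_d, N, control) {
  n <- length(rows)
  mpa <- control$min_per_arm
  if (n < 4 * mpa) {
    return(NULL)
  }
  xs <- x[rows]
  ord <- order(xs)
  xo <- xs[ord]
  yo <- y[rows][ord]
  ao <- act[rows][ord]

  cut <- which(xo[-n] < xo[-1]) # left block = 1..cut
  if (!length(cut)) {
    return(NULL)
  }

  at <- as.numeric(ao)
  cn_t <- cumsum(at)
  cs_t <- cumsum(yo * at)
  cq_t <- cumsum(yo * yo * at)
  cn_p <- seq_len(n) - cn_t
  cs_p <- cumsum(yo) - cs_t
  cq_p <- cumsum(yo * yo) - cq_t

  nl_t <- cn_t[cut]
  nl_p <- cn_p[cut]
  nr_t <- cn_t[n] - nl_t
  nr_p <- cn_p[n] - nl_p
  valid <- nl_t >= mpa & nl_p >= mpa & nr_t >= mpa & nr_p >= mpa
  if (!any(valid)) {
    return(NULL)
  }
  cut <- cut[valid]
  nl_t <- nl_t[valid]
  nl_p <- nl_p[valid]
  nr_t <- nr_t[valid]
  nr_p <- nr_p[valid]

  pool_d <- function(np, nt, sp, st, qp, qt) {
    mp <- sp / np
    mt <- st / nt
    vp <- pmax(qp - np * mp^2, 0) / (np - 1)
    vt <- pmax(qt - nt * mt^2, 0) / (nt - 1)
    s2 <- ((np - 1) * vp + (nt - 1) * vt) / (np + nt - 2)
    ifelse(s2 > 0, (mt - mp) / sqrt(s2), 0)
  }
  dl <- pool_d(
    nl_p, nl_t, cs_p[cut], cs_t[cut], cq_p[cut], cq_t[cut]
  )
  dr <- pool_d(
    nr_p, nr_t, cs_p[n] - cs_p[cut], cs_t[n] - cs_t[cut],
    cq_p[n] - cq_p[cut], cq_t[n] - cq_t[cut]
  )

  crit <- crit_max_scan(
    fixed_n, fixed_d, nl_p + nl_t, dl, nr_p + nr_t, dr, N, control
  )
  if (!any(is.finite(crit))) {
    return(NULL)
  }
  i <- which.max(crit) # first max -> smallest threshold
  list(
    criterion = crit[i],
    threshold = (xo[cut[i]] + xo[cut[i] + 1]) / 2,
    left_rows = rows[ord[seq_len(cut[i])]],
    right_rows = rows[ord[(cut[i] + 1):n]]
  )
}

# Greedy growth. X: numeric matrix (columns in predictor order), y outcome,
# act logical (active arm). Returns a gfit list.
grow_fit <- function(y, act, X, control) {
  N <- length(y)
  parent <- NA_integer_
  depth <- 0L
  split_var <- NA_integer_
  threshold <- NA_real_
  left <- NA_integer_
  right <- NA_integer_
  rows_of <- list(seq_len(N))
  nd <- list(leaf_nd(y, act, seq_len(N)))

  crit_cur <- root_criterion(control)
  trace <- list(list(
    step = 0L, n_leaves = 1L, node = NA_integer_,
    split_var = NA_character_, threshold = NA_real_, criterion = crit_cur
  ))
  leaves_at <- list(1L) # leaf node ids at each size 1..K
  leaves <- 1L
  vars <- colnames(X)

  repeat {
    if (length(leaves) >= control$max_leaves) break
    fixed_all_n <- vapply(nd[leaves], `[[`, numeric(1), "n")
    fixed_all_d <- vapply(nd[leaves], `[[`, numeric(1), "d")
    best <- NULL
    for (li in seq_along(leaves)) {
      l <- leaves[li]
      fx_n <- fixed_all_n[-li]
      fx_d <- fixed_all_d[-li]
      keep <- !is.na(fx_d)
      for (j in seq_along(vars)) {
        sc <- scan_leaf_split(
          rows_of[[l]], X[, j], y, act, fx_n[keep], fx_d[keep], N, control
        )
        if (!is.null(sc) &&
          (is.null(best) || sc$criterion > best$criterion)) {
          best <- c(sc, list(node = l, var = j))
        }
      }
    }
    if (is.null(best) || best$criterion <= crit_cur) break

    id_l <- length(parent) + 1L
    id_r <- length(parent) + 2L
    parent[c(id_l, id_r)] <- best$node
    depth[c(id_l, id_r)] <- depth[best$node] + 1L
    split_var[c(id_l, id_r)] <- NA_integer_
    threshold[c(id_l, id_r)] <- NA_real_
    left[c(id_l, id_r)] <- NA_integer_
    right[c(id_l, id_r)] <- NA_integer_
    split_var[best$node] <- best$var
    threshold[best$node] <- best$threshold
    left[best$node] <- id_l
    right[best$node] <- id_r
    rows_of[[id_l]] <- best$left_rows
    rows_of[[id_r]] <- best$right_rows
    nd[[id_l]] <- leaf_nd(y, act, best$left_rows)
    nd[[id_r]] <- leaf_nd(y, act, best$right_rows)

    leaves <- sort(c(setdiff(leaves, best$node), id_l, id_r))
    crit_cur <- best$criterion
    trace[[length(trace) + 1L]] <- list(
      step = length(trace), n_leaves = length(leaves),
      node = best$node, split_var = vars[best$var],
      threshold = best$threshold, criterion = best$criterion
    )
    leaves_at[[length(leaves_at) + 1L]] <- leaves
  }

  list(
    parent = parent, depth = depth, split_var = split_var,
    threshold = threshold, left = left, right = right,
    rows_of = rows_of, nd = nd,
    trace = dplyr::bind_rows(lapply(trace, as_tibble)),
    leaves_at = leaves_at, vars = vars, N = N
  )
}

# Leaf node ids of the size-k subtree, ordered depth-first left-first.
subtree_leaves <- function(gfit, k) {
  ids <- sort(unique(unlist(gfit$leaves_at[[k]])))
  ordered <- integer(0)
  walk <- function(v) {
    if (v %in% ids) {
      ordered <<- c(ordered, v)
    } else {
      walk(gfit$left[v])
      walk(gfit$right[v])
    }
  }
  walk(1L)
  ordered
}

# Internal node ids of the size-k subtree (strict ancestors of its leaves).
subtree_internal <- function(gfit, k) {
  leaf_ids <- gfit$leaves_at[[k]]
  internal <- integer(0)
  for (l in leaf_ids) {
    a <- gfit$parent[l]
    while (!is.na(a) && !(a %in% internal)) {
      internal <- c(internal, a)
      a <- gfit$parent[a]
    }
  }
  sort(internal)
}

# Route rows of a numeric matrix through the size-k subtree of a gfit.
# Returns the leaf node id for each row; value <= threshold goes left.
route_matrix <- function(gfit, k, X) {
  internal <- subtree_internal(gfit, k)
  node_of <- rep(1L, nrow(X))
  for (v in internal) { # parents precede children in id order
    here <- node_of == v
    if (!any(here)) next
    go_left <- X[, gfit$split_var[v]] <= gfit$threshold[v]
    node_of[here & go_left] <- gfit$left[v]
    node_of[here & !go_left] <- gfit$right[v]
  }
  node_of
}
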