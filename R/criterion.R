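#' Tuning parameters for qualitative interaction tree fitting
#'
#' @param a1,a2 Non-negative weights of the two criterion components:
#'   within-leaf effect size (`a1`) and leaf cardinality (`a2`). Defaults 1, 1.
#' @param dmin Minimum |Cohen's *d*| for a leaf to qualify as a responder (P1)
#'   or iatrogenic (P2) leaf. Default 0.30, a conventional small-to-moderate
#'   effect floor.
#' @param max_leaves Maximum number of leaves grown. Default 8.
#' @param min_per_arm Minimum number of participants per arm in every leaf.
#'   Default 10.
#' @param boot Number of bootstrap samples used by bias-corrected pruning.
#'   Default 200.
#' @param c_se Multiplier of the one-SE pruning rule: the selected size is the
#'   smallest whose bias-corrected criterion is within `c_se` standard errors
#'   of the best. Default 1.
#' @return A list of class `quint_control`.
#' @examples
#' quint_control(max_leaves = 4, boot = 50)
#' @export
quint_control <- function(a1 = 1, a2 = 1, dmin = 0.3, max_leaves = 8,
                          min_per_arm = 10, boot = 200, c_se = 1) {
  if (a1 < 0 || a2 < 0) abort("`a1` and `a2` must be non-negative.")
  if (dmin <= 0) abort("`dmin` must be positive.")
  if (max_leaves < 2) abort("`max_leaves` must be at least 2.")
  if (min_per_arm < 2) abort("`min_per_arm` must be at least 2.")
  if (boot < 1) abort("`boot` must be at least 1.")
  structure(
    list(
      a1 = a1, a2 = a2, dmin = dmin,
      max_leaves = as.integer(max_leaves),
      min_per_arm = as.integer(min_per_arm),
      boot = as.integer(boot), c_se = c_se
    ),
    class = "quint_control"
  )
}

# Reference criterion of the degenerate all-P3 root: the score a minimally
# eligible (|d| = dmin), perfectly balanced qualitative partition would get.
# A split must beat this value for a qualitative interaction to be declared;
# the root enters pruning with this criterion and zero optimism/SE.
root_criterion <- function(control) {
  2 * control$a1 * log1p(control$dmin) + 2 * control$a2 * log(0.5)
}

# --- assignment enumeration ---------------------------------------------

# All class assignments for L leaves as an L-column integer matrix with
# entries 1 (P1), 2 (P2), 3 (P3); cached per L.
the_assign_cache <- new.env(parent = emptyenv())
assignment_matrix <- function(L) {
  key <- as.character(L)
  if (is.null(the_assign_cache[[key]])) {
    m <- as.matrix(expand.grid(rep(list(1:3), L))[, L:1, drop = FALSE])
    dimnames(m) <- NULL
    storage.mode(m) <- "integer"
    the_assign_cache[[key]] <- m
  }
  the_assign_cache[[key]]
}

# Subset masks for k elements (2^k x k logical), cached.
the_subset_cache <- new.env(parent = emptyenv())
subset_matrix <- function(k) {
  key <- as.character(k)
  if (is.null(the_subset_cache[[key]])) {
    m <- if (k == 0) {
      matrix(logical(0), nrow = 1, ncol = 0)
    } else {
      as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
    }
    dimnames(m) <- NULL
    the_subset_cache[[key]] <- m
  }
  the_subset_cache[[key]]
}

effects_nd <- function(effects) {
  n <- effects$n_p + effects$n_t
  list(n = as.numeric(n), d = as.numeric(effects$d))
}

#' Partitioning criterion of a leaf-class assignment
#'
#' The criterion balances the size of the treatment effects inside responder
#' (P1) and iatrogenic (P2) leaves against how many participants those leaves
#' cover:
#' \deqn{C = a_1[\log(1+D_1) + \log(1+D_2)] + a_2[\log(N_1/N) + \log(N_2/N)]}
#' where \eqn{D_1} is the size-weighted mean Cohen's *d* over P1 leaves,
#' \eqn{D_2} the size-weighted mean of \eqn{-d} over P2 leaves, and
#' \eqn{N_1, N_2} the participant counts they cover out of \eqn{N} total.
#'
#' An assignment is *admissible* only if it contains at least one P1 and one
#' P2 leaf (a qualitative interaction), every P1 leaf has `d >= dmin` and
#' every P2 leaf has `d <= -dmin`. Inadmissible assignments score `-Inf`.
#'
#' @param effects A data frame of leaf effect summaries with at least columns
#'   `n_p`, `n_t` and `d` (one row per leaf, in leaf order).
#' @param assignment Character vector over `{"P1","P2","P3"}`, one class per
#'   leaf.
#' @param control A [quint_control()] object.
#' @return A single number; `-Inf` for an inadmissible assignment.
#' @examples
#' eff <- leaf_effect_from_summary(
#'   c(50, 50), c(1, 0), c(1, 1), c(50, 50), c(1.5, -0.5), c(1, 1)
#' )
#' partition_criterion(eff, c("P1", "P2"), quint_control())
#' @export
partition_criterion <- function(effects, assignment, control = quint_control()) {
  stopifnot(length(assignment) == nrow(effects))
  if (!all(assignment %in% c("P1", "P2", "P3"))) {
    abort('`assignment` classes must be "P1", "P2" or "P3".')
  }
  nd <- effects_nd(effects)
  cls <- match(assignment, c("P1", "P2", "P3"))
  criterion_value(nd$n, nd$d, cls, control)
}

# cls: integer vector 1/2/3. Returns -Inf when inadmissible.
criterion_value <- function(n, d, cls, control) {
  p1 <- cls == 1L
  p2 <- cls == 2L
  if (!any(p1) || !any(p2)) {
    return(-Inf)
  }
  if (any(d[p1] < control$dmin) || any(d[p2] > -control$dmin)) {
    return(-Inf)
  }
  N <- sum(n)
  n1 <- sum(n[p1])
  n2 <- sum(n[p2])
  D1 <- sum(n[p1] * d[p1]) / n1
  D2 <- -sum(n[p2] * d[p2]) / n2
  control$a1 * (log1p(D1) + log1p(D2)) +
    control$a2 * (log(n1 / N) + log(n2 / N))
}

# Plug-in criterion of a *fixed* assignment on (possibly different) data:
# no eligibility check; 1 + D floored to keep the log finite out of sample.
# Returns NA when the assignment has no P1 or no P2 leaf or any needed d is NA.
criterion_eval <- function(n, d, cls, control, floor = 0.01) {
  p1 <- cls == 1L
  p2 <- cls == 2L
  if (!any(p1) || !any(p2)) {
    return(NA_real_)
  }
  if (anyNA(d[p1 | p2])) {
    return(NA_real_)
  }
  N <- sum(n)
  n1 <- sum(n[p1])
  n2 <- sum(n[p2])
  D1 <- sum(n[p1] * d[p1]) / n1
  D2 <- -sum(n[p2] * d[p2]) / n2
  # same log1p arithmetic as criterion_value so that in-sample evaluation is
  # bit-identical; the floor only engages out of sample
  safe_log1p <- function(D) if (1 + D > floor) log1p(D) else log(floor)
  control$a1 * (safe_log1p(D1) + safe_log1p(D2)) +
    control$a2 * (log(n1 / N) + log(n2 / N))
}

#' Best admissible leaf-class assignment
#'
#' Exhaustive search over all \eqn{3^L} class assignments of `L` leaves,
#' respecting the `dmin` eligibility rule, for the one maximizing
#' [partition_criterion()]. Ties are broken toward more P3 (nonresponder)
#' leaves, then by lexicographic class order (P1 < P2 < P3) along the leaves.
#'
#' @inheritParams partition_criterion
#' @return `NULL` when no admissible assignment exists; otherwise a list with
#'   `assignment` (character vector) and `criterion` (its value).
#' @examples
#' eff <- leaf_effect_from_summary(
#'   c(50, 50), c(1, 0), c(1, 1), c(50, 50), c(1.8, -0.8), c(1, 1)
#' )
#' optimal_assignment(eff, quint_control())
#' @export
optimal_assignment <- function(effects, control = quint_control()) {
  L <- nrow(effects)
  if (L > control$max_leaves) {
    abort("More leaves than `max_leaves` in `control`.")
  }
  nd <- effects_nd(effects)
  A <- assignment_matrix(L)
  vals <- apply(A, 1L, function(cls) criterion_value(nd$n, nd$d, cls, control))
  best <- max(vals)
  if (!is.finite(best)) {
    return(NULL)
  }
  cand <- which(vals == best)
  if (length(cand) > 1L) {
    n3 <- rowSums(A[cand, , drop = FALSE] == 3L)
    cand <- cand[n3 == max(n3)]
    if (length(cand) > 1L) {
      ord <- do.call(order, as.data.frame(A[cand, , drop = FALSE]))
      cand <- cand[ord[1L]]
    }
  }
  list(
    assignment = c("P1", "P2", "P3")[A[cand[1L], ]],
    criterion = best
  )
}

# --- fast criterion maximum for split scans ------------------------------
#
# Because dmin > 0 makes P1- and P2-eligibility mutually exclusive, the
# maximization over assignments decomposes into two independent "best
# non-empty subset" problems, one per class. Used to score every candidate
# threshold of a (leaf, predictor) scan in one vectorized pass.

# Best over non-empty subsets of {fixed eligibles} + optionally the two
# children, of a1*log1p(sum(nd)/sum(n)) + a2*log(sum(n)/N).
# fx_n, fx_nd: eligible fixed leaves (signed nd, already negated for P2 side).
# cl/cr eligibility and stats vary across thresholds (vectors length Tn).
side_best_scan <- function(fx_n, fx_nd, cl_el, cl_n, cl_nd,
                           cr_el, cr_n, cr_nd, N, a1, a2) {
  Tn <- length(cl_el)
  M <- subset_matrix(length(fx_n))
  sub_n <- as.numeric(M %*% fx_n)
  sub_nd <- as.numeric(M %*% fx_nd)
  best <- rep(-Inf, Tn)
  zeros <- numeric(Tn)
  for (use_l in c(FALSE, TRUE)) {
    for (use_r in c(FALSE, TRUE)) {
      ok <- rep(TRUE, Tn)
      add_n <- zeros
      add_nd <- zeros
      if (use_l) {
        ok <- ok & cl_el
        add_n <- add_n + cl_n
        add_nd <- add_nd + cl_nd
      }
      if (use_r) {
        ok <- ok & cr_el
        add_n <- add_n + cr_n
        add_nd <- add_nd + cr_nd
      }
      if (!any(ok)) next
      for (s in seq_along(sub_n)) {
        tot_n <- sub_n[s] + add_n
        if (sub_n[s] == 0 && !use_l && !use_r) next # empty subset
        # ratio can fall below -1 only at ineligible (masked) positions
        r <- pmax((sub_nd[s] + add_nd) / tot_n, -1)
        v <- a1 * log1p(r) + a2 * log(tot_n / N)
        v[!ok] <- -Inf
        best <- pmax(best, v)
      }
    }
  }
  best
}

# Criterion maximum for the leaf set {fixed leaves} + {left, right child},
# for each candidate threshold. fixed_n/fixed_d: stats of the untouched
# leaves; child stats are vectors across thresholds. Returns numeric(Tn).
crit_max_scan <- function(fixed_n, fixed_d, nl, dl, nr, dr, N, control) {
  dmin <- control$dmin
  e1 <- which(fixed_d >= dmin)
  e2 <- which(fixed_d <= -dmin)
  b1 <- side_best_scan(
    fixed_n[e1], fixed_n[e1] * fixed_d[e1],
    dl >= dmin, nl, nl * dl,
    dr >= dmin, nr, nr * dr,
    N, control$a1, control$a2
  )
  b2 <- side_best_scan(
    fixed_n[e2], -fixed_n[e2] * fixed_d[e2],
    dl <= -dmin, nl, -nl * dl,
    dr <= -dmin, nr, -nr * dr,
    N, control$a1, control$a2
  )
  b1 + b2
}
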