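# Bias-corrected bootstrap pruning of a grown tree.
#
# For each size k in the nested growth sequence, the apparent criterion C_k is
# corrected by the bootstrap optimism o_k = mean over resamples of
# (criterion of a size-k tree regrown on the resample, evaluated on the
# resample) minus (the same fitted tree and class assignment evaluated on the
# original table). The selected size is the smallest k whose corrected
# criterion is within c_se standard errors of the best corrected criterion.
# The root (k = 1) participates with the reference criterion, zero optimism
# and zero SE.

# Best-assignment classes (1/2/3 ints) for a set of leaves of a gfit on its
# own fitting data; NULL when inadmissible.
gfit_assignment <- function(gfit, leaf_ids, control) {
  n <- vapply(gfit$nd[leaf_ids], `[[`, numeric(1), "n")
  d <- vapply(gfit$nd[leaf_ids], `[[`, numeric(1), "d")
  if (anyNA(d)) {
    return(NULL)
  }
  A <- assignment_matrix(length(leaf_ids))
  vals <- apply(A, 1L, function(cls) criterion_value(n, d, cls, control))
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
  list(cls = A[cand[1L], ], criterion = best)
}

# Stratified-by-arm resample of row indices (preserves the 1:1 design).
resample_rows <- function(act, identity = FALSE) {
  if (identity) {
    return(seq_along(act))
  }
  ia <- which(act)
  ip <- which(!act)
  c(
    ip[sample.int(length(ip), length(ip), replace = TRUE)],
    ia[sample.int(length(ia), length(ia), replace = TRUE)]
  )
}

prune_fit <- function(gfit, y, act, X, control,
                      resample = c("stratified", "identity")) {
  resample <- arg_match(resample)
  K <- length(gfit$leaves_at)
  C_app <- gfit$trace$criterion # criterion at sizes 1..K

  if (K == 1L) {
    return(list(
      size = 1L,
      table = tibble(
        k = 1L, criterion = C_app, optimism = 0, se = 0,
        bc_criterion = C_app, n_boot = 0L, dropped = 0L, selected = TRUE
      )
    ))
  }

  B <- control$boot
  diffs <- matrix(NA_real_, nrow = B, ncol = K) # col k: c_boot_k - c_orig_k
  for (b in seq_len(B)) {
    idx <- resample_rows(act, identity = resample == "identity")
    bfit <- grow_fit(y[idx], act[idx], X[idx, , drop = FALSE], control)
    Kb <- length(bfit$leaves_at)
    if (Kb < 2L) next
    for (k in 2:min(Kb, K)) {
      leaf_ids <- bfit$leaves_at[[k]]
      asg <- gfit_assignment(bfit, leaf_ids, control)
      if (is.null(asg)) next
      c_boot <- asg$criterion
      node_of <- route_matrix(bfit, k, X)
      nd <- t(vapply(
        leaf_ids,
        function(v) leaf_nd(y, act, which(node_of == v)),
        numeric(4)
      ))
      c_orig <- criterion_eval(nd[, "n"], nd[, "d"], asg$cls, control)
      if (!is.na(c_orig)) diffs[b, k] <- c_boot - c_orig
    }
  }

  o <- c(0, vapply(2:K, function(k) {
    x <- diffs[, k]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }, numeric(1)))
  se <- c(0, vapply(2:K, function(k) {
    x <- diffs[, k][!is.na(diffs[, k])]
    if (length(x) < 2) 0 else sd(x)
  }, numeric(1)))
  n_boot <- c(0L, vapply(2:K, function(k) sum(!is.na(diffs[, k])), integer(1)))
  bc <- C_app - o

  usable <- which(!is.na(bc))
  i_best <- usable[which.max(bc[usable])]
  cutoff <- bc[i_best] - control$c_se * se[i_best]
  sel <- usable[bc[usable] >= cutoff][1L]

  list(
    size = sel,
    table = tibble(
      k = seq_len(K), criterion = C_app, optimism = o, se = se,
      bc_criterion = bc, n_boot = n_boot,
      dropped = c(0L, rep(B, K - 1L)) - c(0L, n_boot[-1L]),
      selected = seq_len(K) == sel
    )
  )
}
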