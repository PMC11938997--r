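# Shared fixtures and reference implementations; everything is generated in
# code at test time.

# Numeric vector of length n with exactly the requested mean and sample SD.
vec_with_moments <- function(n, m, s) {
  x <- seq_len(n)
  m + s * (x - mean(x)) / sd(x)
}

# Direct continuous-outcome engine data: planted qualitative interaction on
# x1 (d = -d0 for x1 <= 0, +d0 for x1 > 0), unit noise, alternating arms.
make_interaction_data <- function(n = 600, d0 = 0.8, p_extra = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * (1 + p_extra)), n,
    dimnames = list(NULL, paste0("x", seq_len(1 + p_extra)))
  )
  act <- rep(c(FALSE, TRUE), length.out = n)
  d <- ifelse(X[, 1] <= 0, -d0, d0)
  y <- d * act + rnorm(n)
  tibble::tibble(
    arm = ifelse(act, "active", "placebo"),
    y = y
  ) %>% dplyr::bind_cols(tibble::as_tibble(X))
}

# Naive reference implementation of the greedy search: at every step,
# enumerate every (leaf, predictor, threshold) candidate directly with
# leaf_effect() + optimal_assignment(), no incremental statistics, no
# eligibility decomposition. Mirrors the documented growth contract.
naive_quint_grow <- function(data, outcome, predictors, control) {
  y <- data[[outcome]]
  act <- data$arm == "active"
  X <- as.matrix(data[predictors])
  mpa <- control$min_per_arm

  rows_of <- list(seq_len(nrow(data)))
  leaf_ids <- 1L
  crit <- quintree:::root_criterion(control)
  trace <- list()

  leafset_value <- function(rows_list) {
    eff <- lapply(rows_list, function(r) {
      p <- y[r][!act[r]]
      t <- y[r][act[r]]
      if (length(p) < mpa || length(t) < mpa) {
        return(NULL)
      }
      leaf_effect(p, t)
    })
    if (any(vapply(eff, is.null, logical(1)))) {
      return(NULL)
    }
    optimal_assignment(dplyr::bind_rows(eff), control)
  }

  repeat {
    if (length(leaf_ids) >= control$max_leaves) break
    best <- NULL
    for (l in sort(leaf_ids)) {
      others <- setdiff(sort(leaf_ids), l)
      for (j in seq_along(predictors)) {
        xv <- sort(unique(X[rows_of[[l]], j]))
        if (length(xv) < 2) next
        for (thr in (xv[-1] + xv[-length(xv)]) / 2) {
          rl <- rows_of[[l]][X[rows_of[[l]], j] <= thr]
          rr <- setdiff(rows_of[[l]], rl)
          asg <- leafset_value(c(rows_of[others], list(rl), list(rr)))
          if (!is.null(asg) &&
            (is.null(best) || asg$criterion > best$criterion)) {
            best <- list(
              criterion = asg$criterion, node = l, var = predictors[j],
              threshold = thr, rl = rl, rr = rr
            )
          }
        }
      }
    }
    if (is.null(best) || best$criterion <= crit) break
    id_l <- length(rows_of) + 1L
    id_r <- length(rows_of) + 2L
    rows_of[[id_l]] <- best$rl
    rows_of[[id_r]] <- best$rr
    leaf_ids <- c(setdiff(leaf_ids, best$node), id_l, id_r)
    crit <- best$criterion
    trace[[length(trace) + 1L]] <- tibble::tibble(
      node = best$node, split_var = best$var,
      threshold = best$threshold, criterion = best$criterion
    )
  }
  list(
    n_leaves = length(leaf_ids),
    criterion = crit,
    trace = dplyr::bind_rows(trace)
  )
}

# Small generator configs used across tests.
null_sim_config <- function(n = 160, seed = 1, dropout = 0, ...) {
  sim_config(
    n = n,
    subgroups = split_subgroups("motivation", 6, c(0, 0)),
    dropout = dropout,
    item_missing = c(), na_item_rates = c(),
    seed = seed, ...
  )
}

planted_sim_config <- function(n = 600, d0 = 0.8, seed = 1, ...) {
  sim_config(
    n = n,
    subgroups = split_subgroups("motivation", 6, c(-d0, d0)),
    item_missing = c(), na_item_rates = c(),
    seed = seed, ...
  )
}

recovery_predictors <- c("motivation", "confidence", "anxiety", "drinks_per_week")
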