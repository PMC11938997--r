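# Synthetic two-arm trial generator with planted qualitative treatment-by-
# subgroup interactions, used to evaluate every downstream stage against a
# known ground truth.

#' Default baseline covariate battery of the synthetic trial
#'
#' A mixed-type battery emulating the structure of an alcohol pharmacotherapy
#' trial: drinking pattern (drinks/week, drinks per drinking day, baseline
#' heavy drinking days), motivation and confidence for the drinking goal
#' (1-10), anxiety/depression/sleep scores, impulsivity, years of regular
#' drinking, education, sex and smoking status, plus six drinking-consequence
#' items forming one questionnaire scale ("imbibe"), two of which admit
#' "Not Applicable" responses. Marginals are produced by quantile transforms
#' of a Gaussian copula.
#'
#' @return A list of covariate definitions (`name`, `kind`, `qfun`, `levels`).
#' @export
default_covariates <- function() {
  clip_round <- function(lo, hi, qf) {
    force(lo)
    force(hi)
    force(qf)
    function(p) pmin(hi, pmax(lo, round(qf(p))))
  }
  list(
    cov_def("drinks_per_week", "numeric", function(p) {
      pmax(21, stats::qlnorm(p, log(55), 0.35))
    }),
    cov_def("drinks_per_day", "numeric", function(p) {
      pmax(3, stats::qlnorm(p, log(8), 0.35))
    }),
    cov_def(
      "heavy_days_base", "ordinal",
      function(p) pmin(24, pmax(4, round(4 + 20 * stats::qbeta(p, 2.2, 1.8)))),
      levels = 4:24
    ),
    cov_def(
      "motivation", "ordinal", clip_round(1, 10, function(p) qnorm(p, 6.5, 2)),
      levels = 1:10
    ),
    cov_def(
      "confidence", "ordinal", clip_round(1, 10, function(p) qnorm(p, 6, 2.2)),
      levels = 1:10
    ),
    cov_def(
      "anxiety", "ordinal",
      clip_round(0, 63, function(p) stats::qgamma(p, 2, scale = 5)),
      levels = 0:63
    ),
    cov_def(
      "depression", "ordinal",
      clip_round(0, 63, function(p) stats::qgamma(p, 2.2, scale = 5.5)),
      levels = 0:63
    ),
    cov_def(
      "impulsivity", "ordinal", clip_round(8, 32, function(p) qnorm(p, 17, 4)),
      levels = 8:32
    ),
    cov_def(
      "sleep", "ordinal", clip_round(0, 21, function(p) qnorm(p, 7, 3)),
      levels = 0:21
    ),
    cov_def("years_drinking", "numeric", function(p) pmax(1, qnorm(p, 15, 8))),
    cov_def(
      "education", "ordinal", clip_round(8, 20, function(p) qnorm(p, 14, 2.5)),
      levels = 8:20
    ),
    cov_def("female", "binary", function(p) as.numeric(p > 0.66), levels = 0:1),
    cov_def("smoker", "binary", function(p) as.numeric(p > 0.55), levels = 0:1),
    cov_def(
      "imbibe_social", "ordinal",
      clip_round(0, 4, function(p) qnorm(p, 1.8, 1.2)),
      levels = 0:4
    ),
    cov_def(
      "imbibe_health", "ordinal",
      clip_round(0, 4, function(p) qnorm(p, 1.6, 1.2)),
      levels = 0:4
    ),
    cov_def(
      "imbibe_work", "ordinal",
      clip_round(0, 4, function(p) qnorm(p, 1.2, 1.1)),
      levels = 0:4
    ),
    cov_def(
      "imbibe_legal", "ordinal",
      clip_round(0, 4, function(p) qnorm(p, 0.8, 1.0)),
      levels = 0:4
    ),
    cov_def(
      "imbibe_parenting", "ordinal",
      clip_round(0, 4, function(p) qnorm(p, 1.0, 1.1)),
      levels = 0:4
    ),
    cov_def(
      "imbibe_marriage", "ordinal",
      clip_round(0, 4, function(p) qnorm(p, 1.2, 1.1)),
      levels = 0:4
    )
  )
}

cov_def <- function(name, kind, qfun, levels = NULL) {
  list(name = name, kind = kind, qfun = qfun, levels = levels)
}

#' Default copula correlation of the synthetic battery
#'
#' Drinking-pattern variables correlate at 0.55, mood variables (anxiety,
#' depression, sleep) at 0.50, motivation with confidence at 0.35,
#' consequence items at 0.45 among themselves and 0.30 with drinking, and
#' drinking with mood at 0.15; remaining pairs are uncorrelated.
#'
#' @param names Covariate names (defaults to the default battery's).
#' @return A positive-definite correlation matrix.
#' @export
default_correlation <- function(names = vapply(
                                  default_covariates(), `[[`, "", "name"
                                )) {
  p <- length(names)
  R <- diag(p)
  dimnames(R) <- list(names, names)
  set_block <- function(R, a, b, r) {
    a <- intersect(a, names)
    b <- intersect(b, names)
    for (i in a) {
      for (j in b) if (i != j) R[i, j] <- R[j, i] <- r
    }
    R
  }
  drinking <- c("drinks_per_week", "drinks_per_day", "heavy_days_base")
  mood <- c("anxiety", "depression", "sleep")
  imbibe <- paste0("imbibe_", c(
    "social", "health", "work", "legal", "parenting", "marriage"
  ))
  R <- set_block(R, drinking, drinking, 0.55)
  R <- set_block(R, mood, mood, 0.50)
  R <- set_block(R, "motivation", "confidence", 0.35)
  R <- set_block(R, imbibe, imbibe, 0.45)
  R <- set_block(R, imbibe, drinking, 0.30)
  R <- set_block(R, drinking, mood, 0.15)
  R
}

#' Planted subgroup definitions
#'
#' Each subgroup is a conjunction of threshold conditions over the covariates
#' together with a true standardized treatment effect `d` (positive favors
#' the active arm). Subgroups must partition the covariate space.
#'
#' @param var Covariate to split on.
#' @param cut Threshold; the first subgroup is `var <= cut`, the second
#'   `var > cut`.
#' @param d Length-2 numeric: true `d` below and above the cut.
#' @return A list of subgroup definitions usable in [sim_config()].
#' @export
split_subgroups <- function(var = "motivation", cut = 6, d = c(-0.45, 0.45)) {
  list(
    list(
      name = paste0(var, "_low"),
      when = list(list(var = var, op = "<=", value = cut)),
      d = d[1]
    ),
    list(
      name = paste0(var, "_high"),
      when = list(list(var = var, op = ">", value = cut)),
      d = d[2]
    )
  )
}

#' Configuration of the synthetic trial generator
#'
#' Defaults emulate the structure of the motivating trial: 338 participants
#' over 10 sites, 1:1 permuted-block randomization (block size 4) stratified
#' by site, a correlated mixed-type baseline battery, a planted qualitative
#' interaction (default: iatrogenic d = -0.45 below the motivation midpoint,
#' responder d = +0.45 above it), 17.75% maintenance-phase outcome dropout,
#' and item-level predictor missingness including two high-"Not Applicable"
#' consequence items (25% and 10%).
#'
#' Outcomes are generated on the proportion-change scale
#' (`mu_change` + arm effect `d * noise_sd` + Gaussian noise, clipped to the
#' feasible range) and back-converted to daily heavy/non-heavy drinking
#' records so that the outcome-derivation code path is exercised.
#'
#' @param n Number of participants.
#' @param sites Number of clinical sites.
#' @param block_size Permuted-block size (even).
#' @param covariates Covariate battery, as [default_covariates()].
#' @param rho Copula correlation matrix over the battery.
#' @param subgroups Planted subgroup list, as [split_subgroups()].
#' @param mu_change Subgroup-mean proportion change averaged over arms.
#' @param noise_sd Within-arm SD of the proportion-change latent; the planted
#'   arm difference within a subgroup is `d * noise_sd`, applied
#'   symmetrically (`-d * noise_sd / 2` under placebo,
#'   `+d * noise_sd / 2` under active) to keep both arms away from the
#'   feasibility bounds of a proportion.
#' @param dropout Probability of missing the whole maintenance phase
#'   (default 0.1775).
#' @param dropout_mar Logistic slope of dropout on standardized log baseline
#'   drinks/week; 0 (default) gives MCAR dropout.
#' @param day_missing Day-level probability that a maintenance TLFB day is
#'   unobserved for retained participants.
#' @param item_missing Named per-feature "Refuse to Respond" missingness
#'   rates.
#' @param na_item_rates Named "Not Applicable" rates for designated items.
#' @param compliance_missing Probability a weekly compliance entry is missing.
#' @param seed Integer seed; identical seeds give byte-identical trials.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 338,
                       sites = 10,
                       block_size = 4,
                       covariates = default_covariates(),
                       rho = NULL,
                       subgroups = split_subgroups(),
                       mu_change = 0.25,
                       noise_sd = 0.30,
                       dropout = 0.1775,
                       dropout_mar = 0,
                       day_missing = 0.05,
                       item_missing = c(
                         motivation = 0.02, confidence = 0.02,
                         anxiety = 0.03, depression = 0.03,
                         impulsivity = 0.02, sleep = 0.02
                       ),
                       na_item_rates = c(
                         imbibe_parenting = 0.25, imbibe_marriage = 0.10
                       ),
                       compliance_missing = 0.06,
                       seed = 1L) {
  if (block_size %% 2 != 0) abort("`block_size` must be even.")
  if (dropout < 0 || dropout > 1) abort("`dropout` must be in [0, 1].")
  if (any(item_missing < 0 | item_missing > 1) ||
    any(na_item_rates < 0 | na_item_rates > 1)) {
    abort("Missingness rates must be in [0, 1].")
  }
  names_cov <- vapply(covariates, `[[`, "", "name")
  if (anyDuplicated(names_cov)) abort("Duplicate covariate names.")
  if (is.null(rho)) rho <- default_correlation(names_cov)
  if (!isTRUE(all.equal(dim(rho), c(length(names_cov), length(names_cov))))) {
    abort("`rho` dimension must match the covariate battery.")
  }
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) abort("`rho` must be positive definite.")
  bad_keys <- setdiff(
    c(names(item_missing), names(na_item_rates)), names_cov
  )
  if (length(bad_keys)) {
    abort(paste0(
      "Missingness rate(s) for unknown feature(s): ",
      paste(bad_keys, collapse = ", ")
    ))
  }
  for (g in subgroups) {
    for (cond in g$when) {
      if (!cond$var %in% names_cov) {
        abort(paste0("Subgroup condition on unknown covariate: ", cond$var))
      }
      if (!cond$op %in% c("<=", ">")) {
        abort('Subgroup condition `op` must be "<=" or ">".')
      }
    }
  }
  structure(
    list(
      n = as.integer(n), sites = as.integer(sites),
      block_size = as.integer(block_size),
      covariates = covariates, rho = rho, subgroups = subgroups,
      mu_change = mu_change, noise_sd = noise_sd,
      dropout = dropout, dropout_mar = dropout_mar,
      day_missing = day_missing,
      item_missing = item_missing, na_item_rates = na_item_rates,
      compliance_missing = compliance_missing,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Schema matching the default synthetic battery
#'
#' @param covariates Covariate battery (defaults to [default_covariates()]).
#' @return A [feature_schema()] covering the battery, with the six
#'   consequence items mapped to the `imbibe` scale and the parenting and
#'   marriage items flagged as admitting "Not Applicable".
#' @export
default_schema <- function(covariates = default_covariates()) {
  feature_schema(
    features = tibble(
      name = vapply(covariates, `[[`, "", "name"),
      kind = vapply(covariates, `[[`, "", "kind")
    ),
    missing_codes = c("Refuse to Respond", "NA", ""),
    scales = list(imbibe = paste0("imbibe_", c(
      "social", "health", "work", "legal", "parenting", "marriage"
    ))),
    na_items = c("imbibe_parenting", "imbibe_marriage"),
    levels = setNames(
      lapply(covariates, function(cv) cv$levels),
      vapply(covariates, `[[`, "", "name")
    )
  )
}

# 1:1 permuted-block arm assignment within each site, in participant order.
permuted_block_arms <- function(site, block_size) {
  arm <- character(length(site))
  for (s in unique(site)) {
    idx <- which(site == s)
    n_blocks <- ceiling(length(idx) / block_size)
    seq_arms <- unlist(lapply(seq_len(n_blocks), function(b) {
      sample(rep(c("placebo", "active"), block_size / 2))
    }))
    arm[idx] <- seq_arms[seq_along(idx)]
  }
  arm
}

match_subgroup <- function(covs, subgroups) {
  hits <- vapply(subgroups, function(g) {
    ok <- rep(TRUE, nrow(covs))
    for (cond in g$when) {
      x <- covs[[cond$var]]
      ok <- ok & if (cond$op == "<=") x <= cond$value else x > cond$value
    }
    ok
  }, logical(nrow(covs)))
  hits <- matrix(hits, nrow = nrow(covs))
  k <- rowSums(hits)
  if (any(k != 1)) {
    abort(paste0(
      "Subgroup predicates do not partition the covariate space: ",
      sum(k == 0), " record(s) match none, ",
      sum(k > 1), " match several."
    ))
  }
  max.col(hits, ties.method = "first")
}

#' Generate a synthetic randomized trial
#'
#' Draws the correlated baseline battery, assigns arms by site-stratified
#' permuted blocks, plants the configured subgroup treatment effects on the
#' proportion-change-in-heavy-drinking-days scale, realizes them as daily
#' drinking records (baseline days -28..-1; maintenance weeks 2-25, days
#' 8..175), then applies outcome dropout and item-level missingness. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param tlfb `"full"` (default) generates per-day drinking records from
#'   which outcomes can be re-derived with [derive_outcomes()]; `"none"`
#'   skips the daily records and computes the identical outcome values
#'   directly (same rounding arithmetic), which is faster for large
#'   simulations.
#' @return A list with `table` (participant tibble: id, site, arm, sex,
#'   battery, weekly compliance `comp_01..comp_26`, realized outcomes),
#'   `tlfb` (per-day tibble `id, sex, day, drinks, observed`, or `NULL`),
#'   `truth` (per-participant planted subgroup and true `d`), and `config`.
#' @examples
#' trial <- generate_trial(sim_config(n = 60, seed = 3), tlfb = "none")
#' dplyr::count(trial$table, arm)
#' @export
generate_trial <- function(config, tlfb = c("full", "none")) {
  tlfb <- arg_match(tlfb)
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n

  id <- sprintf("P%04d", seq_len(n))
  site <- sample(rep_len(seq_len(config$sites), n))

  # correlated battery through a Gaussian copula
  p <- length(config$covariates)
  Z <- matrix(rnorm(n * p), n, p) %*% chol(config$rho)
  U <- pnorm(Z)
  covs <- as_tibble(setNames(
    lapply(seq_len(p), function(j) config$covariates[[j]]$qfun(U[, j])),
    vapply(config$covariates, `[[`, "", "name")
  ))

  g <- match_subgroup(covs, config$subgroups)
  true_d <- vapply(config$subgroups, `[[`, numeric(1), "d")[g]

  arm <- permuted_block_arms(site, config$block_size)
  sex <- ifelse(covs$female == 1, "F", "M")

  # proportion-change latent, clipped to the feasible range of %HDD
  phdd_base <- covs$heavy_days_base / 28
  pc <- config$mu_change +
    true_d * config$noise_sd * ((arm == "active") - 0.5) +
    rnorm(n, 0, config$noise_sd)
  pc <- pmin(pc, 1)
  pc <- pmax(pc, 1 - 1 / phdd_base)
  heavy_maint <- round(phdd_base * (1 - pc) * 168)
  phdd_maint <- heavy_maint / 168

  # outcome dropout: whole maintenance phase unobserved
  p_drop <- if (config$dropout_mar == 0) {
    rep(config$dropout, n)
  } else {
    z <- as.numeric(scale(log(covs$drinks_per_week)))
    plogis(qlogis(config$dropout) + config$dropout_mar * z)
  }
  dropped <- runif(n) < p_drop

  # weekly compliance (doses of a twice-daily regimen), some weeks missing
  comp <- matrix(
    rbinom(n * 26, 14, 0.95), n, 26,
    dimnames = list(NULL, sprintf("comp_%02d", 1:26))
  )
  comp[matrix(runif(n * 26) < config$compliance_missing, n, 26)] <- NA

  table <- dplyr::bind_cols(
    tibble(
      id = id, site = factor(site), arm = factor(arm, c("placebo", "active")),
      sex = sex
    ),
    covs,
    as_tibble(comp),
    tibble(
      phdd_base = phdd_base,
      phdd_maint = ifelse(dropped, NA_real_, phdd_maint),
      raw_change = ifelse(dropped, NA_real_, (phdd_base - phdd_maint) * 28),
      prop_change = ifelse(
        dropped, NA_real_, (phdd_base - phdd_maint) / phdd_base
      ),
      observed_maintenance_days = ifelse(dropped, 0L, 168L)
    )
  )

  tlfb_tbl <- NULL
  if (tlfb == "full") {
    tlfb_tbl <- build_tlfb(
      id, sex, covs$heavy_days_base, heavy_maint, dropped, config$day_missing
    )
    if (config$day_missing > 0) {
      # %HDD among observed maintenance days only
      out <- derive_outcomes(tlfb_tbl)
      table$phdd_maint <- out$phdd_maint[match(table$id, out$id)]
      table$raw_change <- out$raw_change[match(table$id, out$id)]
      table$prop_change <- out$prop_change[match(table$id, out$id)]
      table$observed_maintenance_days <-
        out$observed_maintenance_days[match(table$id, out$id)]
    }
  }

  # item-level predictor missingness, applied after outcome generation
  rates <- c(config$item_missing, config$na_item_rates)
  if (length(rates)) table <- apply_missingness(table, rates)

  list(
    table = table,
    tlfb = tlfb_tbl,
    truth = tibble(
      id = id,
      subgroup = vapply(config$subgroups, `[[`, "", "name")[g],
      true_d = true_d
    ),
    config = config
  )
}

# Daily drinking records realizing given baseline / maintenance heavy-day
# counts. Heavy days get drinks at or above the sex threshold; other days a
# mix of abstinent and sub-threshold drinking days.
build_tlfb <- function(id, sex, heavy_base, heavy_maint, dropped,
                       day_missing) {
  n <- length(id)
  base_days <- -28:-1
  maint_days <- 8:175
  out <- vector("list", n)
  for (i in seq_len(n)) {
    thr <- if (sex[i] == "F") 4 else 5
    hb <- sample(28, heavy_base[i])
    hm <- sample(168, heavy_maint[i])
    heavy <- c(seq_len(28) %in% hb, seq_len(168) %in% hm)
    nd <- length(heavy)
    drinks <- numeric(nd)
    drinks[heavy] <- thr + round(rexp(sum(heavy), 1 / 3), 1)
    light <- which(!heavy)
    abstinent <- runif(length(light)) < 0.35
    drinks[light[!abstinent]] <-
      round(runif(sum(!abstinent), 0.5, thr - 0.5), 1)
    observed <- c(
      rep(TRUE, 28),
      if (dropped[i]) rep(FALSE, 168) else runif(168) >= day_missing
    )
    drinks[!observed] <- NA_real_
    out[[i]] <- tibble(
      id = id[i], sex = sex[i], day = c(base_days, maint_days),
      drinks = drinks, observed = observed
    )
  }
  dplyr::bind_rows(out)
}

#' Mask table cells at configured rates
#'
#' Independent Bernoulli masking of feature cells (set to `NA`), or of the
#' whole outcome set when a rate is keyed `"outcome"`. The input table is not
#' modified.
#'
#' @param table A participant tibble.
#' @param rates Named numeric vector of rates in `[0, 1]`, keyed by feature
#'   column or `"outcome"`.
#' @param seed Optional integer seed; `NULL` (default) uses the current RNG
#'   state.
#' @return A copy of `table` with cells masked.
#' @examples
#' trial <- generate_trial(sim_config(n = 40, seed = 1), tlfb = "none")
#' masked <- apply_missingness(trial$table, c(motivation = 0.5), seed = 2)
#' mean(is.na(masked$motivation))
#' @export
apply_missingness <- function(table, rates, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (any(rates < 0 | rates > 1)) abort("Rates must be in [0, 1].")
  outcome_cols <- c(
    "phdd_maint", "raw_change", "prop_change"
  )
  bad <- setdiff(names(rates), c(names(table), "outcome"))
  if (length(bad)) {
    abort(paste0(
      "Missingness rate(s) for unknown feature(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  for (key in names(rates)) {
    hit <- runif(nrow(table)) < rates[[key]]
    if (key == "outcome") {
      for (col in intersect(outcome_cols, names(table))) {
        table[[col]][hit] <- NA
      }
      if ("observed_maintenance_days" %in% names(table)) {
        table$observed_maintenance_days[hit] <- 0L
      }
    } else {
      table[[key]][hit] <- NA
    }
  }
  table
}
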