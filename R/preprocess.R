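# Scale scoring, chained-regression predictor imputation, compliance
# zero-filling and the two missing-outcome strategies.

#' Items excluded from scale scoring by trial-wide missingness
#'
#' An item is dropped from its scale when its missing / "Not Applicable"
#' fraction reaches `max_missing` across the trial. A threshold of 1 or more
#' disables the policy entirely.
#'
#' @param table Participant tibble.
#' @param schema A [feature_schema()] with an item-to-scale map.
#' @param max_missing Exclusion threshold (default 0.10).
#' @return Character vector of excluded item names.
#' @export
excluded_items <- function(table, schema, max_missing = 0.10) {
  if (max_missing >= 1) {
    return(character(0))
  }
  items <- unlist(schema$scales, use.names = FALSE)
  frac <- vapply(items, function(it) mean(is.na(table[[it]])), numeric(1))
  items[frac >= max_missing]
}

#' Score questionnaire scales from their items
#'
#' Each scale score is the sum of its retained items (observed plus imputed).
#' Items whose trial-wide missing / "Not Applicable" fraction reaches the
#' exclusion threshold are dropped from scoring for the whole trial and
#' recorded in the `"excluded_items"` attribute of the result. Rows with a
#' missing retained item get a missing score (impute items first).
#'
#' @inheritParams excluded_items
#' @param exclude Items to drop from scoring. `NULL` (default) computes them
#'   from the table with [excluded_items()]; pass the pre-imputation result
#'   when scoring an imputed table.
#' @return `table` with one numeric column appended per scale.
#' @export
score_scales <- function(table, schema, max_missing = 0.10, exclude = NULL) {
  if (!length(schema$scales)) {
    return(table)
  }
  if (is.null(exclude)) {
    exclude <- excluded_items(table, schema, max_missing)
  }
  for (sc in names(schema$scales)) {
    keep <- setdiff(schema$scales[[sc]], exclude)
    if (!length(keep)) {
      abort(paste0("All items of scale `", sc, "` are excluded."))
    }
    table[[sc]] <- Reduce(`+`, lapply(keep, function(it) table[[it]]))
  }
  attr(table, "excluded_items") <- exclude
  table
}

#' Chained-regression imputation of baseline predictors
#'
#' Deterministic round-robin chained regression: missing cells are
#' initialized at column medians, then for a fixed number of sweeps each
#' predictor with missing values is regressed (ordinary least squares) on all
#' other predictors over the rows where it was originally observed, and its
#' missing cells replaced by the fitted values. Ordinal and binary predictors
#' are snapped to the nearest legal value after each update. Observed cells
#' are never altered.
#'
#' @param table Participant tibble.
#' @param predictors Character vector of predictor columns to impute over
#'   (at least 2); every predictor needs at least one observed value.
#' @param schema Optional [feature_schema()] supplying kinds and legal
#'   values; without it all predictors are treated as numeric.
#' @param sweeps Number of round-robin passes (default 10).
#' @param seed Integer seed (the scheme is deterministic; the seed is part of
#'   the provenance contract).
#' @return `table` with missing predictor cells filled; the number of imputed
#'   cells per predictor is recorded in the `"imputed_cells"` attribute.
#' @export
impute_predictors <- function(table, predictors, schema = NULL,
                              sweeps = 10, seed = 1L) {
  if (length(predictors) < 2) abort("Need at least 2 predictors.")
  miss <- setdiff(predictors, names(table))
  if (length(miss)) {
    abort(paste0("Predictor(s) not in table: ", paste(miss, collapse = ", ")))
  }
  set.seed(as.integer(seed))
  X <- as.data.frame(lapply(table[predictors], as.numeric))
  obs <- !is.na(X)
  none <- predictors[colSums(obs) == 0]
  if (length(none)) {
    abort(paste0(
      "Predictor(s) with no observed values: ", paste(none, collapse = ", ")
    ))
  }
  kinds <- if (is.null(schema)) {
    setNames(rep("numeric", length(predictors)), predictors)
  } else {
    setNames(schema_kind(schema, predictors), predictors)
  }

  # median initialization
  for (j in predictors) {
    m <- median(X[[j]][obs[, j]])
    if (kinds[[j]] != "numeric") {
      lv <- schema_levels(schema, j, table[[j]])
      m <- lv[which.min(abs(lv - m))]
    }
    X[[j]][!obs[, j]] <- m
  }

  to_fill <- predictors[colSums(!obs) > 0]
  for (s in seq_len(sweeps)) {
    for (j in to_fill) {
      others <- setdiff(predictors, j)
      fit <- suppressWarnings(
        lm(reformulate(sprintf("`%s`", others), sprintf("`%s`", j)),
          data = X[obs[, j], , drop = FALSE]
        )
      )
      pred <- suppressWarnings(
        predict(fit, newdata = X[!obs[, j], , drop = FALSE])
      )
      if (kinds[[j]] != "numeric") {
        lv <- schema_levels(schema, j, table[[j]])
        pred <- lv[max.col(-abs(outer(pred, lv, `-`)), ties.method = "first")]
      }
      X[[j]][!obs[, j]] <- pred
    }
  }
  for (j in predictors) table[[j]] <- X[[j]]
  attr(table, "imputed_cells") <- colSums(!obs)
  table
}

#' Zero-fill missing weekly compliance
#'
#' Medication was dispensed at weekly study visits, so a missing weekly
#' compliance entry means no dispensation: missing entries are imputed as 0
#' and the total recomputed into `comp_total`.
#'
#' @param table Participant tibble with weekly compliance columns matching
#'   `comp_pattern`.
#' @param comp_pattern Regular expression selecting the weekly columns.
#' @return `table` with zero-filled compliance and a `comp_total` column.
#' @export
handle_compliance <- function(table, comp_pattern = "^comp_\\d+$") {
  cols <- grep(comp_pattern, names(table), value = TRUE)
  if (!length(cols)) {
    abort("No compliance columns match `comp_pattern`.")
  }
  for (col in cols) {
    table[[col]][is.na(table[[col]])] <- 0
  }
  table$comp_total <- Reduce(`+`, table[cols])
  table
}

#' Resolve participants with missing outcomes
#'
#' Two strategies for participants missing the whole maintenance phase:
#' `"exclude"` drops them (count recorded in the `"dropped_records"`
#' attribute); `"impute"` fills each outcome by a single ordinary-least-
#' squares regression on the (already imputed, complete) predictors, the
#' same mechanism as [impute_predictors()].
#'
#' @param table Participant tibble whose outcome columns are `outcomes`.
#' @param strategy `"exclude"` or `"impute"`.
#' @param predictors Predictor columns used by the `"impute"` strategy; must
#'   be complete.
#' @param outcomes Outcome columns to resolve.
#' @param seed Integer seed (deterministic; provenance contract).
#' @return The resolved tibble.
#' @export
resolve_missing_outcomes <- function(table,
                                     strategy = c("exclude", "impute"),
                                     predictors = NULL,
                                     outcomes = c("prop_change", "raw_change"),
                                     seed = 1L) {
  strategy <- arg_match(strategy)
  outcomes <- intersect(outcomes, names(table))
  if (!length(outcomes)) abort("No outcome columns found in `table`.")
  missing_any <- Reduce(`|`, lapply(table[outcomes], is.na))
  if (all(missing_any)) abort("All outcomes are missing.")
  if (strategy == "exclude") {
    out <- table[!missing_any, , drop = FALSE]
    attr(out, "dropped_records") <- sum(missing_any)
    return(out)
  }
  if (is.null(predictors)) {
    abort('`predictors` are required for strategy = "impute".')
  }
  if (anyNA(table[predictors])) {
    abort("Predictors must be complete before outcome imputation.")
  }
  set.seed(as.integer(seed))
  X <- as.data.frame(lapply(table[predictors], as.numeric))
  for (oc in outcomes) {
    y <- table[[oc]]
    hole <- is.na(y)
    if (!any(hole)) next
    dat <- cbind(X, .y = y)
    fit <- suppressWarnings(
      lm(reformulate(sprintf("`%s`", predictors), ".y"), data = dat[!hole, ])
    )
    table[[oc]][hole] <- suppressWarnings(
      predict(fit, newdata = dat[hole, , drop = FALSE])
    )
  }
  attr(table, "imputed_outcomes") <- sum(missing_any)
  table
}

#' One-call preprocessing pipeline
#'
#' Runs the standard preparation sequence on a generated or loaded trial:
#' zero-fill compliance, decide item exclusions on the raw table, impute
#' predictor items and scores by chained regression, score scales, derive or
#' merge outcomes, and resolve missing outcomes by the chosen strategy.
#'
#' @param table Participant tibble.
#' @param schema A [feature_schema()].
#' @param tlfb Optional daily drinking tibble; when given, outcomes are
#'   derived from it with [derive_outcomes()] and replace any outcome columns
#'   in `table`.
#' @param predictors Predictor columns to impute (defaults to every schema
#'   feature present in the table).
#' @param missing_outcomes Strategy passed to [resolve_missing_outcomes()].
#' @param max_missing Item-exclusion threshold (default 0.10).
#' @param sweeps,seed Imputation parameters.
#' @return The prepared tibble, with a `"prep_log"` attribute listing
#'   excluded items, imputed cell counts and dropped/imputed outcome counts.
#' @export
prep_trial <- function(table, schema, tlfb = NULL,
                       predictors = NULL,
                       missing_outcomes = c("exclude", "impute"),
                       max_missing = 0.10, sweeps = 10, seed = 1L) {
  missing_outcomes <- arg_match(missing_outcomes)
  if (!is.null(tlfb)) {
    out <- derive_outcomes(tlfb)
    out$phdd_maint[out$observed_maintenance_days == 0] <- NA
    drop_cols <- intersect(names(out)[-1], names(table))
    table <- table[setdiff(names(table), drop_cols)] %>%
      left_join(out, by = "id")
  }
  if (any(grepl("^comp_\\d+$", names(table)))) {
    table <- handle_compliance(table)
  }
  if (is.null(predictors)) {
    predictors <- intersect(schema$features$name, names(table))
  }
  excl <- excluded_items(table, schema, max_missing)
  table <- impute_predictors(
    table, setdiff(predictors, excl), schema,
    sweeps = sweeps, seed = seed
  )
  table <- score_scales(table, schema, exclude = excl)
  imputed <- attr(table, "imputed_cells")
  scale_names <- names(schema$scales)
  table <- resolve_missing_outcomes(
    table,
    strategy = missing_outcomes,
    predictors = c(setdiff(predictors, unlist(schema$scales)), scale_names),
    seed = seed
  )
  attr(table, "prep_log") <- list(
    excluded_items = excl,
    imputed_cells = imputed,
    dropped_records = attr(table, "dropped_records"),
    imputed_outcomes = attr(table, "imputed_outcomes")
  )
  table
}
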