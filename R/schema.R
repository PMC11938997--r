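#' Describe the baseline feature battery of a trial table
#'
#' A feature schema records, for every baseline column a trial table may
#' carry: its measurement kind (`"numeric"`, `"ordinal"` or `"binary"`),
#' the text codes that encode a missing response (for example
#' `"Refuse to Respond"`), which questionnaire scale each item belongs to,
#' and which items admit a "Not Applicable" response. Loaders use it to type
#' columns and map missing codes onto `NA`; scoring and imputation use the
#' item-to-scale map and the kind (ordinal/binary imputations are snapped to
#' the nearest legal value).
#'
#' @param features A data frame with columns `name` and `kind`
#'   (`"numeric"`, `"ordinal"` or `"binary"`), or a named character vector of
#'   kinds.
#' @param missing_codes Character vector of cell values that encode a missing
#'   response in delimited files.
#' @param scales Named list mapping a scale name to the character vector of
#'   its item features. Every scale must reference at least one item and all
#'   items must appear in `features`.
#' @param na_items Character vector of items that admit a "Not Applicable"
#'   response (candidates for trial-wide exclusion from scale scoring).
#' @param levels Optional named list giving, for ordinal/binary features, the
#'   numeric vector of legal values. When absent the observed values of the
#'   column define the legal set.
#' @return An object of class `feature_schema`.
#' @examples
#' sch <- feature_schema(
#'   c(motivation = "ordinal", drinks_per_week = "numeric"),
#'   scales = list(),
#'   levels = list(motivation = 1:10)
#' )
#' sch
#' @export
feature_schema <- function(features,
                           missing_codes = c("Refuse to Respond", "NA", ""),
                           scales = list(),
                           na_items = character(),
                           levels = list()) {
  if (is.character(features) && !is.null(names(features))) {
    features <- tibble(name = names(features), kind = unname(features))
  }
  features <- as_tibble(features)
  if (!all(c("name", "kind") %in% names(features))) {
    abort("`features` needs columns `name` and `kind`.")
  }
  if (anyDuplicated(features$name)) {
    abort(paste0(
      "Duplicate feature names in schema: ",
      paste(unique(features$name[duplicated(features$name)]), collapse = ", ")
    ))
  }
  bad_kind <- setdiff(unique(features$kind), c("numeric", "ordinal", "binary"))
  if (length(bad_kind)) {
    abort(paste0("Unknown feature kind(s): ", paste(bad_kind, collapse = ", ")))
  }
  if (length(scales)) {
    if (is.null(names(scales)) || any(!nzchar(names(scales)))) {
      abort("Every scale must be named.")
    }
    n_items <- vapply(scales, length, integer(1))
    if (any(n_items < 1L)) {
      abort(paste0(
        "Scale(s) with no items: ",
        paste(names(scales)[n_items < 1L], collapse = ", ")
      ))
    }
    orphan <- setdiff(unlist(scales), features$name)
    if (length(orphan)) {
      abort(paste0(
        "Scale items absent from `features`: ", paste(orphan, collapse = ", ")
      ))
    }
  }
  orphan_na <- setdiff(na_items, features$name)
  if (length(orphan_na)) {
    abort(paste0(
      "`na_items` absent from `features`: ", paste(orphan_na, collapse = ", ")
    ))
  }
  if (length(levels)) {
    orphan_lv <- setdiff(names(levels), features$name)
    if (length(orphan_lv)) {
      abort(paste0(
        "`levels` given for unknown feature(s): ",
        paste(orphan_lv, collapse = ", ")
      ))
    }
  }
  structure(
    list(
      features = features,
      missing_codes = as.character(missing_codes),
      scales = scales,
      na_items = as.character(na_items),
      levels = levels
    ),
    class = "feature_schema"
  )
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> ", nrow(x$features), " features, ",
    length(x$scales), " scales\n",
    sep = ""
  )
  kinds <- table(x$features$kind)
  cat("  kinds: ", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n",
    sep = ""
  )
  if (length(x$scales)) {
    cat("  scales: ", paste(names(x$scales), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

schema_kind <- function(schema, feature) {
  k <- schema$features$kind[match(feature, schema$features$name)]
  if (anyNA(k)) {
    abort(paste0(
      "Feature(s) not in schema: ",
      paste(feature[is.na(k)], collapse = ", ")
    ))
  }
  k
}

# Legal numeric values a (ordinal|binary) feature may take; falls back to the
# observed values of `x` when the schema declares none.
schema_levels <- function(schema, feature, x) {
  lv <- schema$levels[[feature]]
  if (is.null(lv)) lv <- sort(unique(x[!is.na(x)]))
  lv
}

#' Flag heavy drinking days
#'
#' A heavy drinking day (HDD) is a day with at least 4 standard drinks for
#' females and at least 5 standard drinks for males, the standard NIAAA
#' threshold used for trial drinking endpoints.
#'
#' @param drinks Non-negative numeric vector of standard drinks on a day.
#' @param sex Character vector (recycled) of `"M"` / `"F"` codes.
#' @return Logical vector, `TRUE` for heavy days. Monotone non-decreasing in
#'   `drinks` for fixed sex.
#' @examples
#' is_heavy_day(c(4, 4.5, 5), c("F", "M", "M"))
#' @export
is_heavy_day <- function(drinks, sex) {
  if (!is.numeric(drinks) || any(!is.finite(drinks)) || any(drinks < 0)) {
    abort("`drinks` must be finite and non-negative.")
  }
  sex <- as.character(sex)
  bad <- setdiff(unique(sex[!is.na(sex)]), c("M", "F"))
  if (length(bad) || anyNA(sex)) {
    abort(paste0(
      "Unknown sex code(s): ",
      paste(c(bad, if (anyNA(sex)) "NA"), collapse = ", ")
    ))
  }
  if (length(sex) != length(drinks)) sex <- rep_len(sex, length(drinks))
  drinks >= ifelse(sex == "F", 4, 5)
}
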