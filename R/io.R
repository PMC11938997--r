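# Schema-driven delimited I/O for trial tables and daily drinking records.

#' Read a participant-level trial table
#'
#' Reads a delimited text file (comma or tab separated, by extension), types
#' every column against the schema, maps declared missing codes (e.g.
#' `"Refuse to Respond"`) onto `NA`, and normalizes arm labels onto the
#' canonical `"placebo"` / `"active"` pair.
#'
#' @param path CSV or TSV file with an `id` column, an `arm` column, and any
#'   of: `site`, `sex`, schema feature columns, weekly compliance columns
#'   (`comp_01`, ...), outcome columns (`phdd_base`, `phdd_maint`,
#'   `raw_change`, `prop_change`, `observed_maintenance_days`).
#' @param schema A [feature_schema()]; columns that are neither standard nor
#'   schema features raise a load error naming the column.
#' @param arm_synonyms Named character vector mapping arm labels found in the
#'   file to `"placebo"` or `"active"` (case-insensitive; identity labels are
#'   always accepted).
#' @return A typed tibble.
#' @export
read_trial_table <- function(path, schema,
                             arm_synonyms = c(
                               "control" = "placebo", "pbo" = "placebo",
                               "treatment" = "active", "drug" = "active",
                               "med" = "active", "verum" = "active"
                             )) {
  raw <- read_delim_chr(path)
  if (!"id" %in% names(raw)) abort("Trial table needs an `id` column.")
  if (!"arm" %in% names(raw)) abort("Trial table needs an `arm` column.")
  dup <- raw$id[duplicated(raw$id)]
  if (length(dup)) {
    abort(paste0(
      "Duplicate participant id(s): ", paste(unique(dup), collapse = ", "),
      " (rows ", paste(which(raw$id %in% dup), collapse = ", "), ")"
    ))
  }

  std <- c("id", "site", "arm", "sex")
  outcome_cols <- c(
    "phdd_base", "phdd_maint", "raw_change", "prop_change",
    "observed_maintenance_days", "comp_total"
  )
  known <- c(
    std, outcome_cols, schema$features$name, names(schema$scales)
  )
  unknown <- setdiff(
    names(raw)[!grepl("^comp_\\d+$", names(raw))], known
  )
  if (length(unknown)) {
    abort(paste0(
      "Unknown column(s) not covered by the schema: ",
      paste(unknown, collapse = ", ")
    ))
  }

  raw[] <- lapply(raw, function(col) {
    col[col %in% schema$missing_codes] <- NA
    col
  })

  a <- tolower(raw$arm)
  canon <- c(arm_synonyms, placebo = "placebo", active = "active")
  names(canon) <- tolower(names(canon))
  mapped <- unname(canon[a])
  if (any(is.na(mapped) & !is.na(a))) {
    bad <- unique(a[is.na(mapped) & !is.na(a)])
    abort(paste0("Unknown arm label(s): ", paste(bad, collapse = ", ")))
  }
  lv <- unique(mapped[!is.na(mapped)])
  if (length(lv) != 2) {
    abort(paste0(
      "`arm` must have exactly two levels after normalization; found: ",
      paste(lv, collapse = ", ")
    ))
  }
  raw$arm <- factor(mapped, levels = c("placebo", "active"))

  num_cols <- c(
    schema$features$name, names(schema$scales), outcome_cols,
    grep("^comp_\\d+$", names(raw), value = TRUE)
  )
  for (col in intersect(num_cols, names(raw))) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(parsed))
    if (length(bad)) {
      abort(paste0(
        "Unparseable value(s) in column `", col, "`, row(s) ",
        paste(head(bad, 5), collapse = ", ")
      ))
    }
    raw[[col]] <- parsed
  }
  if ("site" %in% names(raw)) raw$site <- factor(raw$site)
  if ("observed_maintenance_days" %in% names(raw)) {
    raw$observed_maintenance_days <-
      as.integer(raw$observed_maintenance_days)
  }
  raw
}

#' Write a trial table to delimited text
#'
#' Missing cells are written as `"NA"` (a declared missing code of the
#' default schema), so a load/save/load cycle is the identity.
#'
#' @param table Participant tibble.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  write_delim_auto(table, path)
}

#' Read / write daily drinking records
#'
#' Timeline-followback style per-day records: `id`, `sex`, `day` (day 0 =
#' randomization; negative days are pre-randomization), `drinks`, `observed`.
#'
#' @param path CSV or TSV file.
#' @return A typed tibble.
#' @export
read_tlfb <- function(path) {
  raw <- read_delim_chr(path)
  need <- c("id", "sex", "day", "drinks", "observed")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(paste0("TLFB file lacks column(s): ", paste(miss, collapse = ", ")))
  }
  raw$day <- as.integer(raw$day)
  raw$drinks <- suppressWarnings(as.numeric(ifelse(
    raw$drinks %in% c("NA", ""), NA, raw$drinks
  )))
  raw$observed <- raw$observed %in% c("TRUE", "true", "1")
  dup <- raw %>%
    dplyr::count(id, day) %>%
    filter(n > 1L)
  if (nrow(dup)) {
    abort(paste0(
      "Duplicate day index for participant(s): ",
      paste(unique(dup$id), collapse = ", ")
    ))
  }
  if (any(!is.na(raw$drinks) & raw$drinks < 0)) {
    abort("`drinks` must be non-negative.")
  }
  raw
}

#' @rdname read_tlfb
#' @param tlfb Daily drinking tibble.
#' @export
write_tlfb <- function(tlfb, path) {
  write_delim_auto(tlfb, path)
}

read_delim_chr <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
}

write_delim_auto <- function(x, path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(x, path, delim = delim, na = "NA", progress = FALSE)
  invisible(path)
}
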