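#' Derive heavy-drinking-day outcomes from daily drinking records
#'
#' From timeline-followback style per-day records, computes per participant:
#' the proportion of heavy drinking days in the 28-day baseline window
#' (`phdd_base`), the proportion of heavy days among *observed* maintenance
#' days (`phdd_maint`; weeks 2-25 by default), the raw change
#' `(phdd_base - phdd_maint) * 28` in days per 28-day period, and the
#' proportion change `(phdd_base - phdd_maint) / phdd_base`. Heavy days are
#' flagged with [is_heavy_day()] (>= 4 drinks for females, >= 5 for males).
#'
#' Unobserved maintenance days are excluded from the denominator — they are
#' never treated as abstinent. A participant with zero observed maintenance
#' days has a missing outcome set. `prop_change` is undefined (NA) when
#' `phdd_base` is 0; the record is retained and `raw_change` still computed.
#'
#' @param tlfb A tibble with columns `id`, `sex` (`"M"`/`"F"`), `day`
#'   (integer, day 0 = randomization, negative = baseline), `drinks`
#'   (non-negative; may be NA when unobserved) and `observed` (logical).
#' @param baseline_window,maintenance_window Integer `c(first, last)` day
#'   ranges; defaults `c(-28, -1)` (28 calendar days before randomization)
#'   and `c(8, 175)` (weeks 2-25). Windows must be disjoint and the baseline
#'   window 28 days long.
#' @return A tibble with one row per participant: `id`, `phdd_base`,
#'   `phdd_maint`, `raw_change`, `prop_change`,
#'   `observed_maintenance_days`.
#' @examples
#' tl <- tibble::tibble(
#'   id = "a", sex = "F", day = c(-28:-1, 8:35),
#'   drinks = c(rep(c(6, 0), 14), rep(0, 28)), observed = TRUE
#' )
#' derive_outcomes(tl)
#' @export
derive_outcomes <- function(tlfb,
                            baseline_window = c(-28, -1),
                            maintenance_window = c(8, 175)) {
  need <- c("id", "sex", "day", "drinks", "observed")
  miss <- setdiff(need, names(tlfb))
  if (length(miss)) {
    abort(paste0("`tlfb` lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (diff(baseline_window) + 1 != 28) {
    abort("The baseline window must span 28 calendar days.")
  }
  if (baseline_window[2] >= maintenance_window[1] &&
    maintenance_window[2] >= baseline_window[1]) {
    abort("Baseline and maintenance windows must be disjoint.")
  }
  dup <- tlfb %>%
    dplyr::count(id, day) %>%
    filter(n > 1L)
  if (nrow(dup)) {
    abort(paste0(
      "Duplicate day index within participant(s): ",
      paste(unique(dup$id), collapse = ", ")
    ))
  }

  obs <- tlfb %>% filter(observed)
  if (any(is.na(obs$drinks))) {
    abort("Observed days must have non-missing `drinks`.")
  }
  obs <- obs %>% mutate(heavy = is_heavy_day(drinks, sex))

  base <- obs %>%
    filter(day >= baseline_window[1], day <= baseline_window[2]) %>%
    group_by(id) %>%
    summarise(phdd_base = mean(heavy), .groups = "drop")
  maint <- obs %>%
    filter(day >= maintenance_window[1], day <= maintenance_window[2]) %>%
    group_by(id) %>%
    summarise(
      phdd_maint = mean(heavy),
      observed_maintenance_days = dplyr::n(),
      .groups = "drop"
    )

  tibble(id = unique(tlfb$id)) %>%
    left_join(base, by = "id") %>%
    left_join(maint, by = "id") %>%
    mutate(
      observed_maintenance_days = dplyr::coalesce(
        observed_maintenance_days, 0L
      ),
      raw_change = (phdd_base - phdd_maint) * 28,
      prop_change = ifelse(
        phdd_base > 0, (phdd_base - phdd_maint) / phdd_base, NA_real_
      )
    ) %>%
    select(
      id, phdd_base, phdd_maint, raw_change, prop_change,
      observed_maintenance_days
    )
}
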