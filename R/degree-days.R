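#' Days in a calendar month
#'
#' @param year Calendar year (used only for the Gregorian leap rule).
#' @param month Month 1-12.
#' @param calendar `"gregorian"` (leap years) or `"fixed_365"` (February
#'   always 28 days; used for period climatologies, which have no specific
#'   year).
#' @return Integer day count, vectorised over `year` and `month`.
#' @examples
#' days_in_month(2000, 2) # 29
#' days_in_month(1900, 2) # 28
#' @export
days_in_month <- function(year, month, calendar = c("gregorian", "fixed_365")) {
  calendar <- match.arg(calendar)
  if (any(is.na(month)) || any(month < 1 | month > 12))
    abort("`month` must be in 1..12.", class = "thermalscape_domain_error")
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- base[month]
  if (calendar == "gregorian") {
    leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
    d <- ifelse(month == 2L & leap, 29L, d)
  }
  as.integer(d)
}

#' Monthly degree days from a monthly mean temperature
#'
#' The monthly-expander reading of the degree-day sum: every day of the
#' month is assigned the month's mean temperature, clamped at the base
#' threshold, and summed, i.e. `n_days * max(0, tas_c - base_c)`. Negative
#' accumulations are truncated to zero (no heat accrued above threshold).
#'
#' @param tas_c Monthly mean air temperature (degC), vectorised.
#' @param base_c Threshold temperature T0 (degC).
#' @param n_days Days in the month (>= 1).
#' @return Degree days (degC day), never negative.
#' @examples
#' monthly_degree_days(10, 0, 30)     # 300
#' monthly_degree_days(-5, 0, 31)     # 0
#' @export
monthly_degree_days <- function(tas_c, base_c, n_days) {
  if (any(n_days < 1))
    abort("`n_days` must be >= 1.", class = "thermalscape_domain_error")
  n_days * pmax(0, tas_c - base_c)
}

#' Annual degree days for one watershed-year
#'
#' Sums the monthly degree-day expansion over a complete year of monthly
#' means. Partial years are an error: a year missing any month cannot be
#' summed honestly and is excluded upstream.
#'
#' @param tas_c Twelve monthly mean temperatures (degC).
#' @param year Calendar year (for leap-day counts; ignored under
#'   `fixed_365`).
#' @param month Months the values belong to; defaults to 1:12 in order.
#' @param base_c Threshold temperature (degC).
#' @param calendar See [days_in_month()].
#' @return Annual degree days (degC day).
#' @examples
#' annual_degree_days(rep(10, 12), year = 2001) # 3650
#' @export
annual_degree_days <- function(tas_c, year, month = 1:12, base_c = 0,
                               calendar = c("gregorian", "fixed_365")) {
  calendar <- match.arg(calendar)
  if (length(tas_c) != 12L || !setequal(month, 1:12) || length(month) != 12L)
    abort("A complete year needs exactly the 12 months 1..12.",
          class = "thermalscape_incomplete_year_error")
  sum(monthly_degree_days(tas_c, base_c, days_in_month(year, month, calendar)))
}

#' Region-specific killing-degree-day thresholds
#'
#' For each region, pools every historical (watershed, year, month) monthly
#' mean temperature and takes an empirical quantile as the region's KDD base
#' threshold. The quantile uses the linear order-statistic interpolation
#' convention with position `h = (n - 1) q + 1` (R type 7), because the
#' threshold is sensitive to the convention and this one is the common
#' default.
#'
#' @param temps Tibble of monthly temperatures (`watershed_id`, `year`,
#'   `month`, `tas_c`).
#' @param watersheds Tibble mapping `watershed_id` to `region`.
#' @param kdd_quantile Quantile in (0, 1); default 0.90.
#' @return Tibble with `region`, `kdd_threshold_c`, `quantile`, `n_values`.
#' @export
kdd_thresholds <- function(temps, watersheds, kdd_quantile = 0.90) {
  if (kdd_quantile <= 0 || kdd_quantile >= 1)
    abort("`kdd_quantile` must be in (0, 1).", class = "thermalscape_domain_error")
  if (nrow(temps) == 0)
    abort("No temperature values to compute thresholds from.",
          class = "thermalscape_domain_error")
  temps %>%
    inner_join(watersheds %>% select("watershed_id", "region"),
               by = "watershed_id") %>%
    group_by(.data$region) %>%
    summarise(
      kdd_threshold_c = {
        if (dplyr::n() < 2)
          abort("A region needs at least 2 monthly values for a threshold.",
                class = "thermalscape_domain_error")
        quantile(.data$tas_c, kdd_quantile, names = FALSE, type = 7)
      },
      quantile = kdd_quantile,
      n_values = dplyr::n(),
      .groups = "drop"
    )
}

#' Annual GDD and KDD per watershed-year
#'
#' Computes growing degree days (base `gdd_base_c`, default 0 degC) and
#' killing degree days (base = the watershed's region threshold) for every
#' complete watershed-year. Incomplete years are dropped with a warning,
#' mirroring the usual exclusion of partially observed first years in
#' climate archives. Zero-GDD and zero-KDD rows are retained: a year with no
#' heat above threshold is an observation, not a gap.
#'
#' @param temps Monthly temperatures (`watershed_id`, `year`, `month`,
#'   `tas_c`).
#' @param watersheds Tibble with `watershed_id`, `region`.
#' @param thresholds Tibble from [kdd_thresholds()]; every region present in
#'   `watersheds` must have a threshold.
#' @param gdd_base_c GDD base temperature (degC), default 0.
#' @param calendar See [days_in_month()].
#' @return Tibble of annual degree days: `watershed_id`, `region`,
#'   `time_key` (year as character), `time_kind = "year"`, `gdd`, `kdd`.
#' @export
compute_degree_days <- function(temps, watersheds, thresholds,
                                gdd_base_c = 0,
                                calendar = c("gregorian", "fixed_365")) {
  calendar <- match.arg(calendar)
  joined <- join_thresholds(temps, watersheds, thresholds)
  complete <- joined %>%
    group_by(.data$watershed_id, .data$year) %>%
    filter(dplyr::n() == 12L) %>%
    ungroup()
  dropped <- anti_join(joined, complete,
                       by = c("watershed_id", "year")) %>%
    distinct(.data$watershed_id, .data$year)
  if (nrow(dropped) > 0)
    warn(sprintf("Dropped %d incomplete watershed-year(s) (fewer than 12 months).",
                 nrow(dropped)))
  complete %>%
    mutate(n_days = days_in_month(.data$year, .data$month, calendar)) %>%
    group_by(.data$watershed_id, .data$region, .data$year) %>%
    summarise(
      gdd = sum(monthly_degree_days(.data$tas_c, gdd_base_c, .data$n_days)),
      kdd = sum(monthly_degree_days(.data$tas_c, .data$kdd_threshold_c[1], .data$n_days)),
      .groups = "drop"
    ) %>%
    mutate(time_key = as.character(.data$year), time_kind = "year") %>%
    select("watershed_id", "region", "time_key", "time_kind", "gdd", "kdd")
}

#' Annual GDD and KDD from period climatologies
#'
#' The projected analogue of [compute_degree_days()]: one annual value per
#' watershed-period, summing the 12 period-month means with non-leap
#' (365-day) month lengths, since a climatology has no specific year. KDD
#' uses the thresholds estimated from historical data only.
#'
#' @param climatology Tibble with `watershed_id`, `period`, `month`,
#'   `tas_c`; 12 months per watershed-period required.
#' @inheritParams compute_degree_days
#' @return Tibble as in [compute_degree_days()] with `time_key` = period
#'   label and `time_kind = "period"`.
#' @export
climatology_degree_days <- function(climatology, watersheds, thresholds,
                                    gdd_base_c = 0) {
  joined <- join_thresholds(climatology, watersheds, thresholds)
  bad <- joined %>%
    count(.data$watershed_id, .data$period) %>%
    filter(.data$n != 12L)
  if (nrow(bad) > 0)
    abort(sprintf("%d watershed-period(s) lack a complete 12-month climatology.",
                  nrow(bad)),
          class = "thermalscape_incomplete_year_error")
  joined %>%
    mutate(n_days = days_in_month(0L, .data$month, "fixed_365")) %>%
    group_by(.data$watershed_id, .data$region, .data$period) %>%
    summarise(
      gdd = sum(monthly_degree_days(.data$tas_c, gdd_base_c, .data$n_days)),
      kdd = sum(monthly_degree_days(.data$tas_c, .data$kdd_threshold_c[1], .data$n_days)),
      .groups = "drop"
    ) %>%
    mutate(time_key = .data$period, time_kind = "period") %>%
    select("watershed_id", "region", "time_key", "time_kind", "gdd", "kdd")
}

join_thresholds <- function(temps, watersheds, thresholds) {
  w <- watersheds %>% select("watershed_id", "region")
  missing_thr <- setdiff(unique(w$region), thresholds$region)
  if (length(missing_thr))
    abort(paste0("No KDD threshold for region(s): ",
                 paste(missing_thr, collapse = ", ")),
          class = "thermalscape_lookup_error")
  temps %>%
    inner_join(w, by = "watershed_id") %>%
    left_join(thresholds %>% select("region", "kdd_threshold_c"), by = "region")
}
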