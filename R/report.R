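#' Percent change between two percentages
#'
#' Relative change of a tier's share versus the historic baseline,
#' `100 * (future - historic) / historic`, computed on unrounded
#' percentages. Undefined (NA) when the historic share is zero.
#'
#' @param historic_pct,future_pct Percentages (vectorised).
#' @return Percent change; `NA` where `historic_pct` is 0.
#' @examples
#' percent_change(40, 20)  # -50
#' percent_change(10, 25)  # +150
#' @export
percent_change <- function(historic_pct, future_pct) {
  ifelse(historic_pct > 0,
         100 * (future_pct - historic_pct) / historic_pct,
         NA_real_)
}

#' Tier membership table across periods
#'
#' Per region and pooled over all regions ("all"): the percentage of
#' watersheds in each tier in each period, plus the percent change of each
#' tier's share versus the historic period. The pooled row is count-weighted
#' (percentages of the pooled watersheds), not a mean of region
#' percentages. Percentages are kept at full precision; round for display.
#'
#' @param assignments Tibble with `watershed_id`, `region`, `time_period`,
#'   `tier` (e.g. [historic_assignments()] plus [predict_membership()]
#'   rows).
#' @param historic_label The `time_period` value of the historic baseline.
#' @return Tibble with `region`, `time_period`, `n`, `pct_cold`,
#'   `pct_transitional`, `pct_hot`, `chg_cold`, `chg_transitional`,
#'   `chg_hot`.
#' @export
membership_table <- function(assignments, historic_label = "historic") {
  if (!historic_label %in% assignments$time_period)
    abort(sprintf("No assignments for historic period '%s'.", historic_label),
          class = "thermalscape_domain_error")
  period_order <- unique(c(historic_label, assignments$time_period))
  pooled <- assignments %>% mutate(region = "all")
  counts <- bind_rows(assignments, pooled) %>%
    mutate(tier = factor(.data$tier, levels = TIER_LEVELS)) %>%
    count(.data$region, .data$time_period, .data$tier, .drop = FALSE) %>%
    group_by(.data$region, .data$time_period) %>%
    mutate(total = sum(.data$n), pct = 100 * .data$n / .data$total) %>%
    ungroup() %>%
    filter(.data$total > 0)
  wide <- counts %>%
    select("region", "time_period", "tier", "pct", "total") %>%
    tidyr::pivot_wider(names_from = "tier", values_from = "pct",
                       names_prefix = "pct_") %>%
    rename(n = "total")
  hist <- wide %>%
    filter(.data$time_period == historic_label) %>%
    select("region", hist_cold = "pct_cold",
           hist_transitional = "pct_transitional", hist_hot = "pct_hot")
  wide %>%
    left_join(hist, by = "region") %>%
    mutate(
      chg_cold = ifelse(.data$time_period == historic_label, NA_real_,
                        percent_change(.data$hist_cold, .data$pct_cold)),
      chg_transitional = ifelse(.data$time_period == historic_label, NA_real_,
                                percent_change(.data$hist_transitional,
                                               .data$pct_transitional)),
      chg_hot = ifelse(.data$time_period == historic_label, NA_real_,
                       percent_change(.data$hist_hot, .data$pct_hot))
    ) %>%
    select("region", "time_period", "n", "pct_cold", "pct_transitional",
           "pct_hot", "chg_cold", "chg_transitional", "chg_hot") %>%
    mutate(
      region = factor(.data$region, levels = c(setdiff(sort(unique(.data$region)), "all"), "all")),
      time_period = factor(.data$time_period, levels = period_order)
    ) %>%
    arrange(.data$region, .data$time_period) %>%
    mutate(region = as.character(.data$region),
           time_period = as.character(.data$time_period))
}

#' Killing-degree-day change between two epochs
#'
#' Per-region mean annual KDD in a historical table and a projected table
#' (typically the end-of-century period), the percent increase per region,
#' and the cross-region minimum / maximum / mean of those increases.
#' Regions with zero historical mean KDD have no defined percent change;
#' they are excluded from the cross-region summary and listed.
#'
#' @param dd_historic Annual degree-day table (historical rows).
#' @param dd_future Degree-day rows of one projection period (e.g. the
#'   last period of [climatology_degree_days()] output).
#' @return List of class `kdd_change_summary` with `by_region`, `overall`
#'   and `excluded_regions`.
#' @export
kdd_change_summary <- function(dd_historic, dd_future) {
  shared <- intersect(unique(dd_historic$watershed_id),
                      unique(dd_future$watershed_id))
  if (length(shared) == 0)
    abort("The two epochs share no watersheds.",
          class = "thermalscape_domain_error")
  by_region <- inner_join(
    dd_historic %>% filter(.data$watershed_id %in% shared) %>%
      group_by(.data$region) %>%
      summarise(mean_kdd_historic = mean(.data$kdd), .groups = "drop"),
    dd_future %>% filter(.data$watershed_id %in% shared) %>%
      group_by(.data$region) %>%
      summarise(mean_kdd_future = mean(.data$kdd), .groups = "drop"),
    by = "region"
  ) %>%
    mutate(pct_change = ifelse(.data$mean_kdd_historic > 0,
                               100 * (.data$mean_kdd_future - .data$mean_kdd_historic) /
                                 .data$mean_kdd_historic,
                               NA_real_))
  defined <- by_region %>% filter(!is.na(.data$pct_change))
  excluded <- setdiff(by_region$region, defined$region)
  overall <- tibble(
    min_pct_change = if (nrow(defined)) min(defined$pct_change) else NA_real_,
    max_pct_change = if (nrow(defined)) max(defined$pct_change) else NA_real_,
    mean_pct_change = if (nrow(defined)) mean(defined$pct_change) else NA_real_
  )
  structure(list(by_region = by_region, overall = overall,
                 excluded_regions = excluded),
            class = "kdd_change_summary")
}

#' @export
print.kdd_change_summary <- function(x, ...) {
  cat("<kdd_change_summary>\n")
  print(x$by_region)
  cat(sprintf("Across regions: %.1f%% to %.1f%% (mean %.1f%%)\n",
              x$overall$min_pct_change, x$overall$max_pct_change,
              x$overall$mean_pct_change))
  if (length(x$excluded_regions))
    cat("Excluded (zero historical KDD):",
        paste(x$excluded_regions, collapse = ", "), "\n")
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. Defaults describe the demo
#' landscape: 2 regions x 50 watersheds over 1980-2019 with three
#' projection periods.
#'
#' @param landscape A [landscape_config()].
#' @param climate A [climate_params()].
#' @param gdd_base_c GDD base temperature (degC).
#' @param kdd_quantile KDD threshold quantile.
#' @param calendar Calendar for historical years.
#' @param transform Velocity response transform.
#' @param velocity_mode `"total"` or `"deviation"` slopes.
#' @param restarts k-means restarts.
#' @param historic_label Label used for the historic epoch in outputs.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(landscape = landscape_config(),
                            climate = climate_params(),
                            gdd_base_c = 0,
                            kdd_quantile = 0.90,
                            calendar = "gregorian",
                            transform = "ln_gdd_plus1",
                            velocity_mode = "total",
                            restarts = 25L,
                            historic_label = "historic") {
  structure(
    list(landscape = landscape, climate = climate, gdd_base_c = gdd_base_c,
         kdd_quantile = kdd_quantile, calendar = calendar,
         transform = transform, velocity_mode = velocity_mode,
         restarts = as.integer(restarts), historic_label = historic_label),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Any subset of the [pipeline_config()] fields may be given; `landscape:`
#' and `climate:` are nested maps passed to [landscape_config()] and
#' [climate_params()]. `period_offsets_c` entries become the projection
#' periods.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  land <- do.call(landscape_config, raw$landscape %||% list())
  clim_args <- raw$climate %||% list()
  if (!is.null(clim_args$period_offsets_c))
    clim_args$period_offsets_c <- unlist(clim_args$period_offsets_c)
  clim <- do.call(climate_params, clim_args)
  top <- raw[setdiff(names(raw), c("landscape", "climate"))]
  do.call(pipeline_config, c(list(landscape = land, climate = clim), top))
}

pipeline_stage <- function(name, quiet, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          class = "thermalscape_pipeline_error", parent = e)
  })
  if (!quiet)
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full vulnerability pipeline
#'
#' simulate -> degree days -> velocity -> classify -> project -> report.
#' Writes every stage's CSV plus a `manifest.json` (config echo, seed,
#' package version, per-file row counts and MD5 checksums) into `out_dir`.
#' Outputs are byte-identical under a fixed `(config, seed)`; nothing is
#' left behind if a stage fails.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, created if needed; `NULL` to skip
#'   writing.
#' @param seed Master seed; stage seeds are derived from it.
#' @param quiet Suppress stage timing messages.
#' @return A `pipeline_result` list with every intermediate and final table.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         seed = 1L, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(seed)

  config$landscape$seed <- seed
  watersheds <- pipeline_stage("simulate", quiet, {
    generate_landscape(config$landscape)
  })
  truth <- true_slopes(watersheds, config$climate)
  temps <- pipeline_stage("monthly-series", quiet,
    generate_monthly_series(watersheds, config$climate, seed = seed + 1L))
  climatology <- generate_projection_climatology(watersheds, config$climate)

  thresholds <- pipeline_stage("degree-days", quiet, {
    kdd_thresholds(temps, watersheds, config$kdd_quantile)
  })
  dd_hist <- compute_degree_days(temps, watersheds, thresholds,
                                 gdd_base_c = config$gdd_base_c,
                                 calendar = config$calendar)
  dd_proj <- climatology_degree_days(climatology, watersheds, thresholds,
                                     gdd_base_c = config$gdd_base_c)

  fits <- pipeline_stage("velocity", quiet,
    fit_velocity_models(dd_hist, watersheds, transform = config$transform))
  velocities <- extract_velocities(fits, watersheds, mode = config$velocity_mode)
  model_fits <- glance(fits)
  velocity_tests <- pipeline_stage("velocity-tests", quiet, {
    per_region <- velocities %>%
      group_by(.data$region) %>%
      dplyr::group_modify(~ velocity_elevation_correlation(.x)) %>%
      ungroup()
    list(anova = compare_ranges_anova(velocities), pearson = per_region)
  })

  tier_models <- pipeline_stage("classify", quiet,
    fit_tier_models(dd_hist, watersheds, restarts = config$restarts,
                    seed = seed + 2L))
  assignments <- pipeline_stage("project", quiet, {
    bind_rows(
      historic_assignments(tier_models, period_label = config$historic_label),
      predict_membership(tier_models, dd_proj)
    )
  })

  report <- pipeline_stage("report", quiet, {
    periods <- unique(dd_proj$time_key)
    end_period <- periods[length(periods)]
    list(
      membership = membership_table(assignments,
                                    historic_label = config$historic_label),
      kdd_change = kdd_change_summary(dd_hist,
                                      dd_proj %>% filter(.data$time_key == end_period)),
      end_period = end_period
    )
  })

  result <- structure(
    list(config = config, seed = seed, watersheds = watersheds, truth = truth,
         temps = temps, climatology = climatology, thresholds = thresholds,
         dd_hist = dd_hist, dd_proj = dd_proj, fits = fits,
         velocities = velocities, model_fits = model_fits,
         velocity_tests = velocity_tests, tier_models = tier_models,
         assignments = assignments, membership = report$membership,
         kdd_change = report$kdd_change, end_period = report$end_period),
    class = "pipeline_result"
  )

  if (!is.null(out_dir))
    result$manifest <- pipeline_stage("write", quiet,
                                      write_pipeline_bundle(result, out_dir))
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d watersheds, %d regions, %d historical years, %d periods\n",
              nrow(x$watersheds), n_distinct(x$watersheds$region),
              n_distinct(x$dd_hist$time_key), n_distinct(x$dd_proj$time_key)))
  cat("Pooled membership:\n")
  print(x$membership %>% filter(.data$region == "all"))
  invisible(x)
}
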