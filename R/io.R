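#' Read pipeline CSV schemas
#'
#' Typed readers for the CSV schemas the pipeline writes (and that
#' schema-compatible extracts of real archives can be supplied through):
#' `watersheds.csv` (watershed_id, region, elevation_m),
#' `temps_monthly.csv` (watershed_id, year, month, tas_c),
#' `climatology.csv` (watershed_id, period, month, tas_c),
#' `degree_days.csv` (watershed_id, region, time_key, time_kind, gdd, kdd).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @name read_schemas
NULL

#' @rdname read_schemas
#' @export
read_watersheds <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    watershed_id = "c", region = "c", elevation_m = "d"))
}

#' @rdname read_schemas
#' @export
read_monthly_temps <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    watershed_id = "c", year = "i", month = "i", tas_c = "d"))
}

#' @rdname read_schemas
#' @export
read_climatology <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    watershed_id = "c", period = "c", month = "i", tas_c = "d"))
}

#' @rdname read_schemas
#' @export
read_degree_days <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    watershed_id = "c", region = "c", time_key = "c", time_kind = "c",
    gdd = "d", kdd = "d"))
}

# Flatten a pipeline_result into named tables for writing.
pipeline_tables <- function(result) {
  list(
    watersheds = result$watersheds,
    truth = result$truth,
    temps_monthly = result$temps,
    climatology = result$climatology,
    kdd_thresholds = result$thresholds,
    degree_days = bind_rows(result$dd_hist, result$dd_proj),
    velocities = result$velocities,
    model_fits = result$model_fits,
    velocity_tests = result$velocity_tests$pearson %>%
      mutate(anova_F = result$velocity_tests$anova$anova_F,
             anova_p = result$velocity_tests$anova$anova_p),
    tier_models = glance(result$tier_models),
    assignments = result$assignments %>% mutate(tier = as.character(.data$tier)),
    membership_table = result$membership,
    kdd_change = result$kdd_change$by_region %>%
      mutate(overall_min = result$kdd_change$overall$min_pct_change,
             overall_max = result$kdd_change$overall$max_pct_change,
             overall_mean = result$kdd_change$overall$mean_pct_change)
  )
}

# Write all bundle CSVs plus manifest.json; remove partial output on failure.
write_pipeline_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- pipeline_tables(result)
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    abort(paste0("Writing bundle failed: ", conditionMessage(e)),
          class = "thermalscape_pipeline_error", parent = e)
  }
  manifest_files <- tryCatch({
    rows <- purrr::imap(tables, function(tab, name) {
      path <- file.path(out_dir, paste0(name, ".csv"))
      readr::write_csv(tab, path)
      written <<- c(written, path)
      list(filename = basename(path), rows = nrow(tab),
           md5 = unname(tools::md5sum(path)))
    })
    rows
  }, error = on_fail)
  manifest <- list(
    package = "thermalscape",
    version = as.character(utils::packageVersion("thermalscape")),
    seed = result$seed,
    config = config_echo(result$config),
    files = manifest_files
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  c(written, manifest_path)
}

# Plain-list echo of the configuration for the manifest.
config_echo <- function(config) {
  list(
    landscape = unclass(config$landscape),
    climate = c(unclass(config$climate)[setdiff(names(config$climate),
                                                "period_offsets_c")],
                list(period_offsets_c = as.list(config$climate$period_offsets_c))),
    gdd_base_c = config$gdd_base_c,
    kdd_quantile = config$kdd_quantile,
    calendar = config$calendar,
    transform = config$transform,
    velocity_mode = config$velocity_mode,
    restarts = config$restarts,
    historic_label = config$historic_label,
    k = 3L
  )
}
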