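#' Configure a synthetic mountain landscape
#'
#' Defines the sampling frame for a synthetic landscape: a set of regions
#' (stand-ins for mountain ranges) each holding a fixed number of watershed
#' points with elevations drawn uniformly from a common range. Optional
#' per-region elevation offsets shift whole regions up or down the gradient.
#'
#' @param n_regions Number of regions (mountain ranges). At least 1.
#' @param watersheds_per_region Watershed points per region. At least 2,
#'   because the downstream random-slope model needs two or more grouping
#'   units.
#' @param elevation_range_m Length-2 numeric, minimum and maximum elevation
#'   in metres; min must be strictly below max.
#' @param region_elevation_offsets Optional numeric vector, one value per
#'   region, added to that region's sampled elevations (metres). Defaults to
#'   no offset.
#' @param seed Integer seed; identical configurations yield byte-identical
#'   landscapes.
#'
#' @return A `landscape_config` object (a validated list).
#' @seealso [generate_landscape()]
#' @export
landscape_config <- function(n_regions = 2,
                             watersheds_per_region = 50,
                             elevation_range_m = c(500, 3500),
                             region_elevation_offsets = NULL,
                             seed = 1L) {
  if (length(n_regions) != 1L || is.na(n_regions) || n_regions < 1)
    abort("`n_regions` must be a single count >= 1.", class = "thermalscape_config_error")
  if (length(watersheds_per_region) != 1L || is.na(watersheds_per_region) ||
      watersheds_per_region < 2)
    abort("`watersheds_per_region` must be >= 2 (random-slope models need at least two groups).",
          class = "thermalscape_config_error")
  if (length(elevation_range_m) != 2L || any(is.na(elevation_range_m)) ||
      elevation_range_m[1] >= elevation_range_m[2])
    abort("`elevation_range_m` must be c(min, max) with min < max.",
          class = "thermalscape_config_error")
  if (!is.null(region_elevation_offsets) &&
      length(region_elevation_offsets) != n_regions)
    abort("`region_elevation_offsets` must have one value per region.",
          class = "thermalscape_config_error")
  structure(
    list(
      n_regions = as.integer(n_regions),
      watersheds_per_region = as.integer(watersheds_per_region),
      elevation_range_m = as.numeric(elevation_range_m),
      region_elevation_offsets = region_elevation_offsets,
      seed = as.integer(seed)
    ),
    class = "landscape_config"
  )
}

#' Configure the synthetic climate generator
#'
#' Parameters of the structural model behind every synthetic temperature:
#' monthly mean air temperature at watershed `w`, year `y`, month `m` is
#'
#' \deqn{T = T_0 - \Gamma\, e_w + A \cos\!\big(2\pi (m - m_{peak})/12\big)
#'       + s_w (y - y_1) + \varepsilon,}
#'
#' with elevation `e_w` in km, per-watershed warming trend
#' `s_w = trend_base + coupling * e_w`, and iid Gaussian noise. A negative
#' elevation coupling makes low-elevation watersheds warm fastest, the sign
#' structure the velocity analysis is designed to detect. Defaults describe
#' a warm-temperate mountain landscape: 14 degC at sea level, a 5 degC/km
#' surface lapse rate, an 8 degC seasonal half-amplitude peaking in July,
#' warming of 0.035 degC/yr at sea level declining by 0.009 degC/yr per km
#' (positive at every elevation, fastest in the lowlands),
#' 0.5 degC monthly noise over 1980-2019, and stepwise period offsets
#' emulating a business-as-usual projection.
#'
#' @param baseline_temp_c Mean annual temperature at 0 m elevation (degC).
#' @param lapse_rate_c_per_km Decline of temperature with elevation
#'   (degC per km).
#' @param seasonal_amplitude_c Half-amplitude of the seasonal cosine (degC).
#' @param peak_month Month (1-12) at which the seasonal cycle peaks.
#' @param trend_base_c_per_yr Linear warming trend at 0 m (degC per year).
#' @param trend_elevation_coupling Change of the warming trend with
#'   elevation (degC per year per km); negative means faster warming at low
#'   elevation.
#' @param noise_sd_c Standard deviation of monthly noise (degC), >= 0.
#' @param year_range Length-2 integer, first and last historical year
#'   (inclusive).
#' @param period_offsets_c Named numeric vector mapping projection-period
#'   labels to warming offsets (degC) added to the noise-free climatology.
#'
#' @return A `climate_params` object (a validated list).
#' @seealso [generate_monthly_series()], [generate_projection_climatology()]
#' @export
climate_params <- function(baseline_temp_c = 14,
                           lapse_rate_c_per_km = 5,
                           seasonal_amplitude_c = 8,
                           peak_month = 7L,
                           trend_base_c_per_yr = 0.035,
                           trend_elevation_coupling = -0.009,
                           noise_sd_c = 0.5,
                           year_range = c(1980L, 2019L),
                           period_offsets_c = c("2011-2040" = 1.0,
                                                "2041-2070" = 2.2,
                                                "2071-2100" = 3.5)) {
  if (noise_sd_c < 0)
    abort("`noise_sd_c` must be >= 0.", class = "thermalscape_config_error")
  if (length(year_range) != 2L || year_range[1] > year_range[2])
    abort("`year_range` must be c(first, last) with first <= last.",
          class = "thermalscape_config_error")
  if (!(peak_month %in% 1:12))
    abort("`peak_month` must be in 1..12.", class = "thermalscape_config_error")
  if (length(period_offsets_c) > 0 &&
      (is.null(names(period_offsets_c)) || any(!nzchar(names(period_offsets_c)))))
    abort("`period_offsets_c` must be a named vector of period labels.",
          class = "thermalscape_config_error")
  structure(
    list(
      baseline_temp_c = baseline_temp_c,
      lapse_rate_c_per_km = lapse_rate_c_per_km,
      seasonal_amplitude_c = seasonal_amplitude_c,
      peak_month = as.integer(peak_month),
      trend_base_c_per_yr = trend_base_c_per_yr,
      trend_elevation_coupling = trend_elevation_coupling,
      noise_sd_c = noise_sd_c,
      year_range = as.integer(year_range),
      period_offsets_c = period_offsets_c
    ),
    class = "climate_params"
  )
}

#' Generate a synthetic watershed landscape
#'
#' Draws `n_regions * watersheds_per_region` watershed points with uniform
#' elevations, labelled `r1..rK` by region. Deterministic given the
#' configuration (including its seed).
#'
#' @param cfg A [landscape_config()].
#' @return A tibble with columns `watershed_id`, `region`, `elevation_m`.
#' @examples
#' generate_landscape(landscape_config(n_regions = 2, watersheds_per_region = 3))
#' @export
generate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "landscape_config"))
  withr::with_seed(cfg$seed, {
    regions <- paste0("r", seq_len(cfg$n_regions))
    purrr::map_dfr(seq_len(cfg$n_regions), function(k) {
      off <- if (is.null(cfg$region_elevation_offsets)) 0 else cfg$region_elevation_offsets[k]
      tibble(
        watershed_id = sprintf("w%s_%03d", regions[k], seq_len(cfg$watersheds_per_region)),
        region = regions[k],
        elevation_m = runif(cfg$watersheds_per_region,
                            cfg$elevation_range_m[1],
                            cfg$elevation_range_m[2]) + off
      )
    })
  })
}

#' True per-watershed warming slopes of a synthetic landscape
#'
#' The generator's hidden truth: each watershed's linear warming trend is
#' `trend_base + coupling * elevation_km`, exactly. Used by parameter
#' recovery tests against estimated velocities.
#'
#' @param watersheds Tibble from [generate_landscape()].
#' @param params A [climate_params()].
#' @return Tibble with `watershed_id`, `true_slope_c_per_yr`, `elevation_m`.
#' @export
true_slopes <- function(watersheds, params) {
  stopifnot(inherits(params, "climate_params"))
  watersheds %>%
    mutate(true_slope_c_per_yr = params$trend_base_c_per_yr +
             params$trend_elevation_coupling * .data$elevation_m / 1000) %>%
    select("watershed_id", "true_slope_c_per_yr", "elevation_m")
}

# Noise-free structural monthly mean temperature; year_offset counts from the
# first historical year.
structural_temp <- function(elevation_m, month, year_offset, params) {
  slope <- params$trend_base_c_per_yr +
    params$trend_elevation_coupling * elevation_m / 1000
  params$baseline_temp_c -
    params$lapse_rate_c_per_km * elevation_m / 1000 +
    params$seasonal_amplitude_c * cos(2 * pi * (month - params$peak_month) / 12) +
    slope * year_offset
}

#' Generate synthetic monthly temperature series
#'
#' One row per watershed x year x month over the historical window, built
#' from the structural model of [climate_params()] plus Gaussian noise.
#'
#' @param watersheds Tibble from [generate_landscape()]; must be nonempty.
#' @param params A [climate_params()].
#' @param seed Integer seed for the noise draws.
#' @return Tibble with `watershed_id`, `year`, `month`, `tas_c`.
#' @export
generate_monthly_series <- function(watersheds, params, seed = 1L) {
  stopifnot(inherits(params, "climate_params"))
  if (nrow(watersheds) == 0)
    abort("`watersheds` is empty.", class = "thermalscape_config_error")
  years <- seq(params$year_range[1], params$year_range[2])
  grid <- tidyr::expand_grid(
    watersheds %>% select("watershed_id", "elevation_m"),
    year = years,
    month = 1:12
  )
  withr::with_seed(seed, {
    grid %>%
      mutate(
        tas_c = structural_temp(.data$elevation_m, .data$month,
                                .data$year - params$year_range[1], params) +
          rnorm(dplyr::n(), 0, params$noise_sd_c)
      ) %>%
      select("watershed_id", "year", "month", "tas_c")
  })
}

#' Generate projection-period climatologies
#'
#' Emulates projected climate data that exist only as period-month averages:
#' for each watershed, period and month the value is the noise-free
#' structural mean evaluated at the midpoint of the historical window plus
#' the period's warming offset. Climatologies are noise-free by design,
#' mirroring the mismatch between projected and historical variance
#' structure.
#'
#' @param watersheds Tibble from [generate_landscape()].
#' @param params A [climate_params()]; `period_offsets_c` must cover every
#'   requested period.
#' @param periods Character vector of period labels; defaults to all periods
#'   configured in `params`.
#' @return Tibble with `watershed_id`, `period`, `month`, `tas_c`; exactly
#'   12 rows per watershed-period.
#' @export
generate_projection_climatology <- function(watersheds, params,
                                            periods = names(params$period_offsets_c)) {
  stopifnot(inherits(params, "climate_params"))
  unknown <- setdiff(periods, names(params$period_offsets_c))
  if (length(unknown))
    abort(paste0("No period offset configured for: ",
                 paste(unknown, collapse = ", ")),
          class = "thermalscape_config_error")
  mid_offset <- mean(params$year_range) - params$year_range[1]
  tidyr::expand_grid(
    watersheds %>% select("watershed_id", "elevation_m"),
    period = periods,
    month = 1:12
  ) %>%
    mutate(
      tas_c = structural_temp(.data$elevation_m, .data$month, mid_offset, params) +
        unname(params$period_offsets_c[.data$period])
    ) %>%
    select("watershed_id", "period", "month", "tas_c")
}
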