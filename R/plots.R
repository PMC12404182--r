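#' Plot transformed GDD trends per region
#'
#' Thin per-watershed trajectories of the transformed response with the
#' region's fixed (overall) trend overlaid, one panel per region.
#'
#' @param fits A `velocity_fit` or `velocity_fit_list`.
#' @return A ggplot object.
#' @export
plot_gdd_trends <- function(fits) {
  if (inherits(fits, "velocity_fit")) fits <- structure(list(fits),
                                                        class = "velocity_fit_list")
  pts <- purrr::map_dfr(fits, function(f)
    f$data %>% mutate(region = f$region))
  fixed <- purrr::map_dfr(fits, function(f)
    tibble(region = f$region, intercept = f$fixed_intercept -
             f$fixed_slope * f$year_mean, slope = f$fixed_slope))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$year, y = .data$y)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$watershed_id),
                       colour = "steelblue", linewidth = 0.2, alpha = 0.5) +
    ggplot2::geom_abline(data = fixed,
                         ggplot2::aes(intercept = .data$intercept,
                                      slope = .data$slope),
                         colour = "black", linewidth = 0.8) +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = "Year", y = "Transformed response")
}

#' Plot velocity of change against elevation
#'
#' Scatter of per-watershed velocities over elevation, one panel per
#' region, with the Pearson correlation annotated.
#'
#' @param velocities Tibble with `velocity`, `elevation_m`, `region`.
#' @return A ggplot object.
#' @export
plot_velocity_elevation <- function(velocities) {
  ann <- velocities %>%
    group_by(.data$region) %>%
    dplyr::group_modify(~ velocity_elevation_correlation(.x)) %>%
    ungroup() %>%
    mutate(label = sprintf("R = %.2f", .data$pearson_r))
  ggplot2::ggplot(velocities,
                  ggplot2::aes(x = .data$elevation_m, y = .data$velocity)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.6) +
    ggplot2::geom_text(data = ann, ggplot2::aes(label = .data$label),
                       x = Inf, y = Inf, hjust = 1.1, vjust = 1.5,
                       inherit.aes = FALSE) +
    ggplot2::facet_wrap(~region, scales = "free") +
    ggplot2::labs(x = "Elevation (m)", y = "Velocity of change")
}

#' Plot tier membership across periods
#'
#' Stacked shares of the cold / transitional / hot tiers per period, one
#' panel per region (including the pooled "all" rows).
#'
#' @param membership Tibble from [membership_table()].
#' @return A ggplot object.
#' @export
plot_membership <- function(membership) {
  long <- membership %>%
    select("region", "time_period", "pct_cold", "pct_transitional",
           "pct_hot") %>%
    tidyr::pivot_longer(dplyr::starts_with("pct_"), names_to = "tier",
                        values_to = "pct", names_prefix = "pct_") %>%
    mutate(tier = factor(.data$tier, levels = rev(TIER_LEVELS)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_period, y = .data$pct,
                                     fill = .data$tier)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(hot = "#c0392b",
                                          transitional = "#e6b35a",
                                          cold = "#3b6fb6")) +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = "Period", y = "Share of watersheds (%)", fill = "Tier")
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.velocity_fit <- function(object, ...) plot_gdd_trends(object)

#' @export
autoplot.velocity_fit_list <- function(object, ...) plot_gdd_trends(object)

#' @export
autoplot.tier_model <- function(object, ...) {
  ggplot2::ggplot(object$tiers,
                  ggplot2::aes(x = .data$ln_mean_gdd, fill = .data$tier)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = object$centers, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(cold = "#3b6fb6",
                                          transitional = "#e6b35a",
                                          hot = "#c0392b")) +
    ggplot2::labs(x = "ln(mean GDD + 1)", y = "Watersheds", fill = "Tier",
                  title = paste("Region", object$region))
}
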