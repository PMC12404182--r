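#' Response transforms for velocity models
#'
#' Annual degree days enter the trend model as `ln(x + 1)` (or `log10(x + 1)`),
#' keeping zero-accumulation years defined; annual mean temperature as
#' `ln(x + 10)`, rendering sub-zero means positive before the logarithm.
#' The log base rescales every slope by a constant and leaves correlations
#' and ANOVA statistics invariant.
#'
#' @param x Numeric values on the response's natural scale.
#' @param transform One of `"ln_gdd_plus1"`, `"log10_gdd_plus1"`,
#'   `"ln_temp_plus10"`.
#' @return Transformed (or back-transformed) values.
#' @examples
#' transform_response(exp(1) - 1, "ln_gdd_plus1") # 1
#' @export
transform_response <- function(x, transform = c("ln_gdd_plus1",
                                                "log10_gdd_plus1",
                                                "ln_temp_plus10")) {
  transform <- match.arg(transform)
  switch(transform,
    ln_gdd_plus1 = {
      if (any(x < 0, na.rm = TRUE))
        abort("ln(x + 1) requires x >= 0.", class = "thermalscape_domain_error")
      log(x + 1)
    },
    log10_gdd_plus1 = {
      if (any(x < 0, na.rm = TRUE))
        abort("log10(x + 1) requires x >= 0.", class = "thermalscape_domain_error")
      log10(x + 1)
    },
    ln_temp_plus10 = {
      if (any(x <= -10, na.rm = TRUE))
        abort("ln(x + 10) requires x > -10.", class = "thermalscape_domain_error")
      log(x + 10)
    }
  )
}

#' @rdname transform_response
#' @param y Transformed values.
#' @export
inverse_transform <- function(y, transform = c("ln_gdd_plus1",
                                               "log10_gdd_plus1",
                                               "ln_temp_plus10")) {
  transform <- match.arg(transform)
  switch(transform,
    ln_gdd_plus1 = exp(y) - 1,
    log10_gdd_plus1 = 10^y - 1,
    ln_temp_plus10 = exp(y) - 10
  )
}

#' Annual mean temperature per watershed-year
#'
#' Unweighted mean of the 12 monthly means; the response option for the
#' parallel temperature-based velocity model.
#'
#' @param temps Monthly temperatures (`watershed_id`, `year`, `month`,
#'   `tas_c`).
#' @return Tibble with `watershed_id`, `year`, `tmean_c` (complete years
#'   only).
#' @export
annual_mean_temp <- function(temps) {
  temps %>%
    group_by(.data$watershed_id, .data$year) %>%
    filter(dplyr::n() == 12L) %>%
    summarise(tmean_c = mean(.data$tas_c), .groups = "drop")
}

#' Fit a random-slope velocity model for one region
#'
#' Fits, by REML, a linear mixed model with transformed annual heat
#' accumulation (or mean temperature) as response, year as fixed effect,
#' and watershed as a random effect on both intercept and slope with an
#' unstructured 2x2 covariance:
#' \deqn{y_{it} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i})\,t + \varepsilon_{it}.}
#' Each watershed's total slope \eqn{\beta_1 + b_{1i}} is its velocity of
#' change. Year is centred at its mean internally; slopes are per calendar
#' year regardless. Boundary (singular) fits are flagged, not rejected:
#' degenerate data legitimately drive variance components to zero.
#'
#' @param data Tibble with `watershed_id`, a year column (`year`, or
#'   `time_key` with `time_kind == "year"`), and the response column.
#' @param response Name of the response column on its natural scale
#'   (default `"gdd"`).
#' @param transform See [transform_response()]; default `ln_gdd_plus1`.
#' @param region Optional region label carried into outputs; taken from a
#'   `region` column when present.
#' @return A `velocity_fit` object; see [tidy()] and [glance()] methods,
#'   [extract_velocities()], [pseudo_r2()].
#' @export
fit_velocity_model <- function(data, response = "gdd",
                               transform = "ln_gdd_plus1",
                               region = NULL) {
  if (!response %in% names(data))
    abort(sprintf("Response column `%s` not found.", response),
          class = "thermalscape_model_error")
  if (!"year" %in% names(data)) {
    if (all(c("time_key", "time_kind") %in% names(data))) {
      data <- data %>% filter(.data$time_kind == "year") %>%
        mutate(year = as.numeric(.data$time_key))
    } else {
      abort("`data` needs a `year` column (or `time_key`/`time_kind`).",
            class = "thermalscape_model_error")
    }
  }
  if (is.null(region) && "region" %in% names(data)) {
    region <- unique(data$region)
    if (length(region) != 1L)
      abort("`data` spans several regions; fit one model per region (see fit_velocity_models()).",
            class = "thermalscape_model_error")
  }
  d <- data %>%
    select("watershed_id", "year", all_of(response)) %>%
    tidyr::drop_na()
  if (n_distinct(d$watershed_id) < 2)
    abort("Random-slope model needs >= 2 watersheds.",
          class = "thermalscape_model_error")
  years_per <- d %>% count(.data$watershed_id)
  if (any(years_per$n < 3))
    abort("Every watershed needs >= 3 years of data.",
          class = "thermalscape_model_error")

  year_mean <- mean(d$year)
  d <- d %>% mutate(
    y = transform_response(.data[[response]], transform),
    year_c = .data$year - year_mean
  )

  warned <- character()
  model <- withCallingHandlers(
    lme4::lmer(y ~ year_c + (1 + year_c | watershed_id), data = d,
               REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           check.nobs.vs.nRE = "ignore")),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  singular <- lme4::isSingular(model, tol = 1e-5)
  converged <- length(model@optinfo$conv$lme4) == 0 &&
    !any(grepl("failed to converge", warned))

  vc <- lme4::VarCorr(model)
  S <- vc$watershed_id
  re <- lme4::ranef(model)$watershed_id
  fe <- lme4::fixef(model)
  velocities <- tibble(
    watershed_id = rownames(re),
    deviation = re[, "year_c"],
    velocity = unname(fe[["year_c"]]) + re[, "year_c"]
  )

  structure(
    list(
      region = region %||% NA_character_,
      response = response,
      transform = transform,
      model = model,
      year_mean = year_mean,
      fixed_intercept = unname(fe[["(Intercept)"]]),
      fixed_slope = unname(fe[["year_c"]]),
      var_b0 = unname(S["(Intercept)", "(Intercept)"]),
      var_b1 = unname(S["year_c", "year_c"]),
      cov_b0b1 = unname(S["(Intercept)", "year_c"]),
      sigma2 = stats::sigma(model)^2,
      reml_criterion = as.numeric(stats::deviance(model, REML = TRUE)),
      converged = converged,
      singular = singular,
      n_watersheds = n_distinct(d$watershed_id),
      n_obs = nrow(d),
      velocities = velocities,
      data = d
    ),
    class = "velocity_fit"
  )
}

#' Fit one velocity model per region
#'
#' @param dd Annual degree-day table ([compute_degree_days()]), or any table
#'   accepted by [fit_velocity_model()] with a `region` column (joined from
#'   `watersheds` when absent).
#' @param watersheds Optional tibble with `watershed_id`, `region` used to
#'   assign regions when `dd` lacks them.
#' @inheritParams fit_velocity_model
#' @return A named list of `velocity_fit` objects (class
#'   `velocity_fit_list`), one per region.
#' @export
fit_velocity_models <- function(dd, watersheds = NULL, response = "gdd",
                                transform = "ln_gdd_plus1") {
  if (!"region" %in% names(dd)) {
    if (is.null(watersheds))
      abort("Provide `watersheds` to assign regions.",
            class = "thermalscape_model_error")
    dd <- dd %>% inner_join(watersheds %>% select("watershed_id", "region"),
                            by = "watershed_id")
  }
  regions <- sort(unique(dd$region))
  fits <- purrr::map(regions, function(r)
    fit_velocity_model(dd %>% filter(.data$region == r),
                       response = response, transform = transform, region = r))
  structure(setNames(fits, regions), class = "velocity_fit_list")
}

#' Per-watershed velocities of change
#'
#' Total slope (fixed slope + BLUP deviation) per watershed by default; the
#' mean-zero BLUP deviations alone via `mode = "deviation"`.
#'
#' @param fit A `velocity_fit` or `velocity_fit_list`.
#' @param watersheds Optional tibble with `watershed_id`, `elevation_m`
#'   (and `region`) to join onto the result.
#' @param mode `"total"` or `"deviation"`.
#' @return Tibble with `watershed_id`, `region`, `velocity` and, when
#'   available, `elevation_m`.
#' @export
extract_velocities <- function(fit, watersheds = NULL,
                               mode = c("total", "deviation")) {
  mode <- match.arg(mode)
  if (inherits(fit, "velocity_fit_list")) {
    return(purrr::map_dfr(fit, extract_velocities, watersheds = watersheds,
                          mode = mode))
  }
  stopifnot(inherits(fit, "velocity_fit"))
  out <- fit$velocities %>%
    mutate(region = fit$region,
           velocity = if (mode == "total") .data$velocity else .data$deviation) %>%
    select("watershed_id", "region", "velocity")
  if (!is.null(watersheds))
    out <- out %>% left_join(watersheds %>%
                               select(any_of(c("watershed_id", "elevation_m"))),
                             by = "watershed_id")
  out
}

#' Marginal and conditional pseudo-R2 of a velocity fit
#'
#' Variance explained by the fixed trend alone (marginal) and by fixed plus
#' random effects (conditional), each relative to the total of fixed,
#' random and residual variance. The random-effect contribution uses the
#' design-adjusted (mean-covariate) formulation
#' `var_b0 + 2 cov_b0b1 mean(t) + var_b1 mean(t^2)` over the observed
#' (centred) year covariate, the standard extension of the fixed/random
#' variance decomposition to random-slope models.
#'
#' @param fit A `velocity_fit`.
#' @return Tibble with `r2_marginal`, `r2_conditional`.
#' @export
pseudo_r2 <- function(fit) {
  stopifnot(inherits(fit, "velocity_fit"))
  x <- fit$data$year_c
  var_fixed <- var(fit$fixed_intercept + fit$fixed_slope * x)
  var_random <- fit$var_b0 + 2 * fit$cov_b0b1 * mean(x) +
    fit$var_b1 * mean(x^2)
  total <- var_fixed + var_random + fit$sigma2
  if (!is.finite(total) || total <= 0)
    abort("Total variance is zero; pseudo-R2 undefined.",
          class = "thermalscape_domain_error")
  tibble(r2_marginal = var_fixed / total,
         r2_conditional = (var_fixed + var_random) / total)
}

#' Pearson correlation of velocity with elevation
#'
#' @param velocities Tibble with `velocity` and `elevation_m` (e.g. from
#'   [extract_velocities()] with `watersheds`).
#' @return Tibble with `pearson_r`, `p_value`, `n`.
#' @export
velocity_elevation_correlation <- function(velocities) {
  v <- velocities %>% select("velocity", "elevation_m") %>% tidyr::drop_na()
  if (nrow(v) < 3)
    abort("Need >= 3 watersheds for a correlation.",
          class = "thermalscape_domain_error")
  if (sd(v$velocity) == 0 || sd(v$elevation_m) == 0)
    abort("Zero variance in velocity or elevation; correlation undefined.",
          class = "thermalscape_domain_error")
  ct <- cor.test(v$velocity, v$elevation_m, method = "pearson")
  tibble(pearson_r = unname(ct$estimate), p_value = ct$p.value, n = nrow(v))
}

#' One-way ANOVA of velocities across regions
#'
#' Tests whether mean velocity of change differs among regions
#' (fixed-effects one-way ANOVA).
#'
#' @param velocities Tibble with `velocity` and `region`.
#' @return Tibble with `anova_F`, `anova_p`, `df_between`, `df_within`.
#' @export
compare_ranges_anova <- function(velocities) {
  v <- velocities %>% select("velocity", "region") %>% tidyr::drop_na()
  sizes <- v %>% count(.data$region)
  if (nrow(sizes) < 2 || any(sizes$n < 2))
    abort("ANOVA needs >= 2 regions with >= 2 velocities each.",
          class = "thermalscape_domain_error")
  tab <- summary(aov(velocity ~ factor(region), data = v))[[1]]
  tibble(
    anova_F = tab[["F value"]][1],
    anova_p = tab[["Pr(>F)"]][1],
    df_between = tab[["Df"]][1],
    df_within = tab[["Df"]][2]
  )
}

#' @export
tidy.velocity_fit <- function(x, ...) {
  x$velocities %>%
    mutate(region = x$region, .before = 1)
}

#' @export
glance.velocity_fit <- function(x, ...) {
  r2 <- pseudo_r2(x)
  tibble(
    region = x$region,
    fixed_intercept = x$fixed_intercept,
    fixed_slope = x$fixed_slope,
    var_b0 = x$var_b0,
    var_b1 = x$var_b1,
    cov_b0b1 = x$cov_b0b1,
    sigma2 = x$sigma2,
    r2_marginal = r2$r2_marginal,
    r2_conditional = r2$r2_conditional,
    converged = x$converged,
    singular = x$singular,
    n_watersheds = x$n_watersheds,
    n_obs = x$n_obs
  )
}

#' @export
tidy.velocity_fit_list <- function(x, ...) purrr::map_dfr(x, tidy.velocity_fit)

#' @export
glance.velocity_fit_list <- function(x, ...) purrr::map_dfr(x, glance.velocity_fit)

#' @export
print.velocity_fit <- function(x, ...) {
  cat(sprintf("<velocity_fit> region %s: %d watersheds, %d obs\n",
              x$region, x$n_watersheds, x$n_obs))
  cat(sprintf("  response %s [%s]; fixed slope %.5g per yr; singular: %s\n",
              x$response, x$transform, x$fixed_slope, x$singular))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
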