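#' Mean historical GDD per watershed
#'
#' The clustering feature: each watershed's arithmetic mean annual GDD over
#' the historical window, ln(x + 1) transformed.
#'
#' @param dd Annual degree-day table ([compute_degree_days()]); only
#'   `time_kind == "year"` rows are used when the column is present.
#' @return Tibble with `watershed_id` (and `region` when present),
#'   `mean_gdd`, `ln_mean_gdd`.
#' @export
mean_historical_gdd <- function(dd) {
  if ("time_kind" %in% names(dd))
    dd <- dd %>% filter(.data$time_kind == "year")
  if (nrow(dd) == 0)
    abort("No historical (yearly) degree-day rows.",
          class = "thermalscape_domain_error")
  keys <- intersect(c("watershed_id", "region"), names(dd))
  dd %>%
    group_by(across(all_of(keys))) %>%
    summarise(mean_gdd = mean(.data$gdd), .groups = "drop") %>%
    mutate(ln_mean_gdd = log(.data$mean_gdd + 1))
}

# Deterministic starts from contiguous partitions of the sorted values:
# optimal 1-D clusters are contiguous, so block means over a coarse grid of
# split-point pairs seed Lloyd inside most basins, including heavily skewed
# ones (e.g. a singleton extreme cluster) that nearest-centre random starts
# rarely reach.
grid_partition_starts <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  fr <- (1:5) / 6
  out <- list()
  for (a in seq_along(fr)) {
    for (b in seq_along(fr)) {
      if (b <= a) next
      i <- min(max(floor(n * fr[a]), 1L), n - 2L)
      j <- min(max(floor(n * fr[b]), i + 1L), n - 1L)
      out[[length(out) + 1L]] <- c(mean(xs[1:i]), mean(xs[(i + 1):j]),
                                   mean(xs[(j + 1):n]))
    }
  }
  unique(out)
}

# k-means++ draw of k centres from x (assumes current RNG state).
kmpp_start <- function(x, k) {
  cs <- sample(x, 1)
  while (length(cs) < k) {
    d2 <- vapply(x, function(v) min((v - cs)^2), numeric(1))
    cs <- c(cs, if (all(d2 == 0)) sample(x, 1) else sample(x, 1, prob = d2))
  }
  cs
}

# Exact 1-D k-means by dynamic programming over contiguous partitions of
# the sorted values (optimal 1-D clusters are contiguous). O(k n^2) with
# prefix sums; guarantees the global within-SS optimum.
exact_kmeans_1d <- function(x, k = 3L) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs * xs)
  # within-SS of the sorted block j..i, vectorised over j
  block_cost <- function(j, i) {
    s <- cs[i] - c(0, cs)[j]
    s2 <- cs2[i] - c(0, cs2)[j]
    pmax(s2 - s * s / (i - j + 1), 0)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(NA_integer_, k, n)
  D[1, ] <- block_cost(1L, 1:n)
  for (kk in 2:k) {
    for (i in kk:n) {
      j <- kk:i
      tot <- D[kk - 1, j - 1] + block_cost(j, i)
      best <- which.min(tot)
      D[kk, i] <- tot[best]
      B[kk, i] <- j[best]
    }
  }
  # backtrack split points
  bounds <- integer(k + 1)
  bounds[k + 1] <- n
  i <- n
  for (kk in k:2) {
    j <- B[kk, i]
    bounds[kk] <- j - 1L
    i <- j - 1L
  }
  bounds[1] <- 0L
  cluster_sorted <- rep(seq_len(k), diff(bounds))
  cluster <- integer(n)
  cluster[ord] <- cluster_sorted
  centers <- vapply(seq_len(k), function(c) mean(xs[cluster_sorted == c]),
                    numeric(1))
  list(cluster = cluster, centers = centers, tot_withinss = D[k, n],
       totss = sum((x - mean(x))^2))
}

# Best-of-restarts Lloyd's algorithm: deterministic quantile and
# contiguous-grid starts plus k-means++ draws, best by within-SS.
lloyd_kmeans_1d <- function(x, k = 3L, restarts = 25L, seed = 1L) {
  fit <- withr::with_seed(seed, {
    det <- c(
      list(
        quantile(x, c(1, 3, 5) / 6, names = FALSE, type = 7),
        quantile(x, c(0.1, 0.5, 0.9), names = FALSE, type = 7),
        c(min(x), median(x), max(x))
      ),
      grid_partition_starts(x)
    )
    starts <- Filter(function(s) length(unique(s)) == k, det)
    starts <- starts[seq_len(min(length(starts), restarts))]
    while (length(starts) < restarts) {
      cen <- kmpp_start(x, k)
      if (length(unique(cen)) == k) starts <- c(starts, list(cen))
    }
    best <- NULL
    for (cen in starts) {
      km <- suppressWarnings(
        kmeans(x, centers = matrix(sort(cen)), algorithm = "Lloyd",
               iter.max = 100L))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  list(cluster = fit$cluster, centers = as.numeric(fit$centers),
       tot_withinss = fit$tot.withinss, totss = fit$totss)
}

#' Three-tier 1-D k-means on transformed mean GDD
#'
#' One-dimensional k-means a priori constrained to three clusters. The
#' default method solves the problem exactly by dynamic programming over
#' contiguous partitions of the sorted values (optimal 1-D clusters are
#' contiguous), so the reported partition attains the global within-cluster
#' sum of squares optimum and is fully deterministic. A classical
#' best-of-`restarts` Lloyd's algorithm is available as `method = "lloyd"`;
#' it reaches the same optimum on almost all inputs but, like any
#' nearest-centre iteration, can lodge in a local optimum on skewed data.
#' Clusters are labelled cold / transitional / hot by ascending centre,
#' making the labels invariant to method and initialisation. Centre ties
#' (possible only on degenerate data) are broken by first data index and
#' flagged.
#'
#' @param x Numeric values (ln-transformed mean GDD) for one region; at
#'   least 3 distinct values required.
#' @param restarts Number of Lloyd initialisations (`method = "lloyd"`).
#' @param seed Integer seed for Lloyd restarts; the exact method is
#'   deterministic and ignores it.
#' @param method `"exact"` (dynamic programming, default) or `"lloyd"`.
#' @return List with `tier` (factor cold/transitional/hot along `x`),
#'   `centers` (named, ascending), `tot_withinss`, `totss`, `tie`.
#' @export
kmeans_tiers <- function(x, restarts = 25L, seed = 1L,
                         method = c("exact", "lloyd")) {
  method <- match.arg(method)
  k <- 3L
  if (length(unique(x)) < k)
    abort("k-means with k = 3 needs at least 3 distinct values.",
          class = "thermalscape_model_error")
  fit <- switch(method,
    exact = exact_kmeans_1d(x, k),
    lloyd = lloyd_kmeans_1d(x, k, restarts = restarts, seed = seed)
  )
  ord <- order(fit$centers, vapply(seq_len(k), function(j)
    min(which(fit$cluster == j)), numeric(1)))
  tie <- any(diff(sort(fit$centers)) == 0)
  relabel <- match(seq_len(k), ord)
  list(
    tier = factor(TIER_LEVELS[relabel[fit$cluster]], levels = TIER_LEVELS),
    centers = setNames(as.numeric(fit$centers[ord]), TIER_LEVELS),
    tot_withinss = fit$tot_withinss,
    totss = fit$totss,
    tie = tie
  )
}

#' Linear discriminant on one standardised feature
#'
#' Standardises the ln-transformed historical GDD with its own mean and
#' standard deviation, then fits a linear discriminant (class means, pooled
#' within-class variance, empirical priors) to the tier labels. The scaler
#' is stored so that projected values are mapped onto the training feature
#' scale rather than re-standardised per period.
#'
#' @param values Numeric ln-transformed mean GDD (training, historical).
#' @param labels Factor of tier labels, levels within
#'   `c("cold", "transitional", "hot")`.
#' @return List with `lda` (a `MASS::lda` fit), `scaler_mean`, `scaler_sd`,
#'   `classes`.
#' @export
fit_discriminant <- function(values, labels) {
  labels <- factor(labels, levels = intersect(TIER_LEVELS, unique(as.character(labels))))
  sizes <- table(labels)
  if (length(sizes) < 2)
    abort("Discriminant needs >= 2 tiers present.",
          class = "thermalscape_model_error")
  small <- names(sizes)[sizes < 2]
  if (length(small))
    abort(paste0("Tier(s) with fewer than 2 members: ",
                 paste(small, collapse = ", ")),
          class = "thermalscape_model_error")
  m <- mean(values)
  s <- sd(values)
  if (!is.finite(s) || s <= 0)
    abort("Zero variance in training values; cannot standardise.",
          class = "thermalscape_model_error")
  z <- (values - m) / s
  fit <- MASS::lda(x = data.frame(z = z), grouping = labels)
  list(lda = fit, scaler_mean = m, scaler_sd = s, classes = levels(labels))
}

# Posterior tier probabilities for raw GDD values under a discriminant.
discriminant_posterior <- function(disc, gdd) {
  if (any(gdd < 0, na.rm = TRUE))
    abort("Projected GDD must be >= 0.", class = "thermalscape_domain_error")
  if (is.null(disc$scaler_mean) || is.null(disc$scaler_sd))
    abort("Discriminant lacks a stored scaler.",
          class = "thermalscape_model_error")
  z <- (log(gdd + 1) - disc$scaler_mean) / disc$scaler_sd
  post_present <- predict(disc$lda, newdata = data.frame(z = z))$posterior
  post <- matrix(0, nrow = length(z), ncol = 3,
                 dimnames = list(NULL, TIER_LEVELS))
  post[, colnames(post_present)] <- post_present
  post
}

#' Fit the vulnerability tier model for one region
#'
#' Chains the classification stages for a single region: k-means tiers on
#' ln-transformed mean historical GDD, then the predictive linear
#' discriminant on the standardised feature, with resubstitution accuracy.
#'
#' @param mean_gdd Tibble from [mean_historical_gdd()] for one region.
#' @param restarts,seed Passed to [kmeans_tiers()].
#' @param region Optional region label (taken from the data when present).
#' @return A `tier_model` object.
#' @export
fit_tier_model <- function(mean_gdd, restarts = 25L, seed = 1L, region = NULL) {
  if (is.null(region) && "region" %in% names(mean_gdd)) {
    region <- unique(mean_gdd$region)
    if (length(region) != 1L)
      abort("`mean_gdd` spans several regions; see fit_tier_models().",
            class = "thermalscape_model_error")
  }
  mg <- mean_gdd
  km <- kmeans_tiers(mg$ln_mean_gdd, restarts = restarts, seed = seed)
  disc <- fit_discriminant(mg$ln_mean_gdd, km$tier)
  obj <- structure(
    list(
      region = region %||% NA_character_,
      centers = km$centers,
      tie = km$tie,
      tot_withinss = km$tot_withinss,
      totss = km$totss,
      scaler_mean = disc$scaler_mean,
      scaler_sd = disc$scaler_sd,
      lda = disc$lda,
      classes = disc$classes,
      tiers = tibble(watershed_id = mg$watershed_id,
                     mean_gdd = mg$mean_gdd,
                     ln_mean_gdd = mg$ln_mean_gdd,
                     tier = km$tier),
      accuracy = NA_real_
    ),
    class = "tier_model"
  )
  obj$accuracy <- resubstitution_accuracy(obj)
  obj
}

#' Fit tier models for every region
#'
#' @param dd Annual degree-day table (historical rows are selected).
#' @param watersheds Optional `watershed_id`/`region` map if `dd` lacks
#'   regions.
#' @inheritParams fit_tier_model
#' @return Named list of `tier_model`s (class `tier_model_list`).
#' @export
fit_tier_models <- function(dd, watersheds = NULL, restarts = 25L, seed = 1L) {
  if (!"region" %in% names(dd)) {
    if (is.null(watersheds))
      abort("Provide `watersheds` to assign regions.",
            class = "thermalscape_model_error")
    dd <- dd %>% inner_join(watersheds %>% select("watershed_id", "region"),
                            by = "watershed_id")
  }
  mg <- mean_historical_gdd(dd)
  regions <- sort(unique(mg$region))
  fits <- purrr::map(regions, function(r)
    fit_tier_model(mg %>% filter(.data$region == r), restarts = restarts,
                   seed = seed, region = r))
  structure(setNames(fits, regions), class = "tier_model_list")
}

#' Resubstitution accuracy of a tier model
#'
#' Fraction of training watersheds whose discriminant prediction equals
#' their k-means tier.
#'
#' @param model A `tier_model`.
#' @param values,labels Optional alternative evaluation set (ln-transformed
#'   values and tier labels); defaults to the training data.
#' @return A fraction in \[0, 1\].
#' @export
resubstitution_accuracy <- function(model, values = NULL, labels = NULL) {
  stopifnot(inherits(model, "tier_model"))
  if (is.null(values)) {
    values <- model$tiers$ln_mean_gdd
    labels <- model$tiers$tier
  }
  post <- discriminant_posterior(model, exp(values) - 1)
  pred <- TIER_LEVELS[max.col(post, ties.method = "first")]
  mean(pred == as.character(labels))
}

#' Predict tier membership for projected GDD
#'
#' Transforms projected annual GDD with ln(x + 1), standardises it with the
#' model's stored historical scaler, and scores it with the linear
#' discriminant: posterior probabilities are normalised class likelihood
#' times prior; the assigned tier is the posterior argmax.
#'
#' @param model A `tier_model` or `tier_model_list`.
#' @param projected Tibble with `watershed_id`, a period column
#'   (`time_key` or `period`), `gdd` and, for a `tier_model_list`, `region`.
#' @return Tibble with `watershed_id`, `region`, `time_period`, `tier`,
#'   `p_cold`, `p_transitional`, `p_hot`.
#' @export
predict_membership <- function(model, projected) {
  if (inherits(model, "tier_model_list")) {
    if (!"region" %in% names(projected))
      abort("`projected` needs a `region` column for a tier_model_list.",
            class = "thermalscape_model_error")
    return(purrr::map_dfr(model, function(m)
      predict_membership(m, projected %>% filter(.data$region == m$region))))
  }
  stopifnot(inherits(model, "tier_model"))
  period_col <- intersect(c("time_key", "period", "time_period"), names(projected))[1]
  if (is.na(period_col))
    abort("`projected` needs a period column (`time_key` or `period`).",
          class = "thermalscape_model_error")
  post <- discriminant_posterior(model, projected$gdd)
  tibble(
    watershed_id = projected$watershed_id,
    region = model$region,
    time_period = projected[[period_col]],
    tier = factor(TIER_LEVELS[max.col(post, ties.method = "first")],
                  levels = TIER_LEVELS),
    p_cold = post[, "cold"],
    p_transitional = post[, "transitional"],
    p_hot = post[, "hot"]
  )
}

#' Historic tier assignments in the same shape as predictions
#'
#' The historic membership of each watershed is its k-means cluster, a
#' deterministic assignment, reported with a one-hot posterior.
#'
#' @param model A `tier_model` or `tier_model_list`.
#' @param period_label Label for the historic period rows.
#' @return Tibble shaped like [predict_membership()] output.
#' @export
historic_assignments <- function(model, period_label = "historic") {
  if (inherits(model, "tier_model_list"))
    return(purrr::map_dfr(model, historic_assignments,
                          period_label = period_label))
  stopifnot(inherits(model, "tier_model"))
  model$tiers %>%
    mutate(
      region = model$region,
      time_period = period_label,
      tier = .data$tier,
      p_cold = as.numeric(.data$tier == "cold"),
      p_transitional = as.numeric(.data$tier == "transitional"),
      p_hot = as.numeric(.data$tier == "hot")
    ) %>%
    select("watershed_id", "region", "time_period", "tier",
           "p_cold", "p_transitional", "p_hot")
}

#' @export
tidy.tier_model <- function(x, ...) {
  x$tiers %>% mutate(region = x$region, .before = 1)
}

#' @export
glance.tier_model <- function(x, ...) {
  tibble(
    region = x$region,
    center_cold = x$centers[["cold"]],
    center_transitional = x$centers[["transitional"]],
    center_hot = x$centers[["hot"]],
    scaler_mean = x$scaler_mean,
    scaler_sd = x$scaler_sd,
    accuracy = x$accuracy,
    tie = x$tie,
    n = nrow(x$tiers)
  )
}

#' @export
tidy.tier_model_list <- function(x, ...) purrr::map_dfr(x, tidy.tier_model)

#' @export
glance.tier_model_list <- function(x, ...) purrr::map_dfr(x, glance.tier_model)

#' @export
print.tier_model <- function(x, ...) {
  cat(sprintf("<tier_model> region %s: centers (ln GDD+1) %.3f / %.3f / %.3f, accuracy %.3f\n",
              x$region, x$centers[1], x$centers[2], x$centers[3], x$accuracy))
  invisible(x)
}
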