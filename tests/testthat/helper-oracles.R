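# Independent oracles used across the suite. Each is a deliberately naive
# reimplementation of the quantity it checks and must stay independent of
# the package's own code paths.

# Degree days by brute-force daily expansion: replicate each month's mean
# over its days, clamp at the base, sum.
daily_expansion_dd <- function(tas_c, year, base_c = 0,
                               calendar = "gregorian") {
  total <- 0
  for (m in 1:12) {
    nd <- thermalscape::days_in_month(year, m, calendar)
    total <- total + sum(pmax(0, rep(tas_c[m], nd) - base_c))
  }
  total
}

# Exhaustive search over all contiguous 3-partitions of sorted 1-D data:
# the global k-means optimum (optimal 1-D clusters are contiguous).
exhaustive_kmeans3_ss <- function(x) {
  x <- sort(x)
  n <- length(x)
  ssq <- function(v) sum((v - mean(v))^2)
  best <- Inf
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      s <- ssq(x[1:i]) + ssq(x[(i + 1):j]) + ssq(x[(j + 1):n])
      if (s < best) best <- s
    }
  }
  best
}

# Direct numerical REML for the random-intercept/random-slope model
# y = (b0 + u0g) + (b1 + u1g) t + e, by maximizing the profiled REML
# objective over the scaled covariance of (u0, u1). sigma^2 and the fixed
# effects are profiled out analytically; the remaining 3-parameter surface
# is optimized with a general-purpose optimizer from moment-based starts.
reml_oracle <- function(d) {
  # d: data.frame with columns y, t (centered), g (group)
  groups <- split(d, d$g)
  n <- nrow(d)
  p <- 2L
  neg2reml <- function(par) {
    psi0 <- exp(par[1]); psi1 <- exp(par[2]); rho <- tanh(par[3])
    Psi <- matrix(c(psi0, rho * sqrt(psi0 * psi1),
                    rho * sqrt(psi0 * psi1), psi1), 2)
    XtWX <- matrix(0, 2, 2); XtWy <- numeric(2)
    logdetW <- 0
    pieces <- lapply(groups, function(gd) {
      Z <- cbind(1, gd$t)
      W <- diag(nrow(gd)) + Z %*% Psi %*% t(Z)
      ch <- tryCatch(chol(W), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      Winv <- chol2inv(ch)
      list(Z = Z, y = gd$y, Winv = Winv,
           logdet = 2 * sum(log(diag(ch))))
    })
    if (any(vapply(pieces, is.null, logical(1)))) return(1e10)
    for (pc in pieces) {
      XtWX <- XtWX + t(pc$Z) %*% pc$Winv %*% pc$Z
      XtWy <- XtWy + t(pc$Z) %*% pc$Winv %*% pc$y
      logdetW <- logdetW + pc$logdet
    }
    beta <- solve(XtWX, XtWy)
    rss <- 0
    for (pc in pieces) {
      r <- pc$y - pc$Z %*% beta
      rss <- rss + t(r) %*% pc$Winv %*% r
    }
    sigma2 <- as.numeric(rss) / (n - p)
    logdetW + determinant(XtWX, logarithm = TRUE)$modulus +
      (n - p) * log(sigma2)
  }
  # moment-based start: per-group OLS intercepts/slopes
  per <- lapply(groups, function(gd) coef(lm(y ~ t, data = gd)))
  B <- do.call(rbind, per)
  resid2 <- mean(unlist(lapply(groups, function(gd)
    resid(lm(y ~ t, data = gd))^2)))
  s0 <- max(var(B[, 1]) / resid2, 1e-4)
  s1 <- max(var(B[, 2]) / resid2, 1e-6)
  start <- c(log(s0), log(s1), atanh(max(min(cor(B[, 1], B[, 2]), 0.95), -0.95)))
  opt <- optim(start, neg2reml, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  opt <- optim(opt$par, neg2reml, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  opt <- optim(opt$par, neg2reml, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-15))
  # recover parameter estimates at the optimum
  psi0 <- exp(opt$par[1]); psi1 <- exp(opt$par[2]); rho <- tanh(opt$par[3])
  Psi <- matrix(c(psi0, rho * sqrt(psi0 * psi1),
                  rho * sqrt(psi0 * psi1), psi1), 2)
  XtWX <- matrix(0, 2, 2); XtWy <- numeric(2); rss <- 0
  for (gd in groups) {
    Z <- cbind(1, gd$t)
    W <- diag(nrow(gd)) + Z %*% Psi %*% t(Z)
    Winv <- chol2inv(chol(W))
    XtWX <- XtWX + t(Z) %*% Winv %*% Z
    XtWy <- XtWy + t(Z) %*% Winv %*% gd$y
  }
  beta <- solve(XtWX, XtWy)
  for (gd in groups) {
    Z <- cbind(1, gd$t)
    W <- diag(nrow(gd)) + Z %*% Psi %*% t(Z)
    r <- gd$y - Z %*% beta
    rss <- rss + t(r) %*% chol2inv(chol(W)) %*% r
  }
  sigma2 <- as.numeric(rss) / (n - p)
  list(beta = as.numeric(beta), sigma2 = sigma2,
       var_b0 = psi0 * sigma2, var_b1 = psi1 * sigma2,
       cov_b0b1 = rho * sqrt(psi0 * psi1) * sigma2,
       objective = neg2reml(opt$par))
}

# Balanced synthetic panel with known mixed-model parameters.
make_panel <- function(n_groups = 20, n_years = 40, beta0 = 5, beta1 = 0.02,
                       sd0 = 0.1, sd1 = 0.01, rho = 0.3, sigma = 0.05,
                       seed = 1) {
  withr::with_seed(seed, {
    t <- seq_len(n_years) - mean(seq_len(n_years))
    u <- MASS::mvrnorm(n_groups, c(0, 0),
                       matrix(c(sd0^2, rho * sd0 * sd1,
                                rho * sd0 * sd1, sd1^2), 2))
    do.call(rbind, lapply(seq_len(n_groups), function(g) {
      data.frame(
        g = sprintf("g%02d", g), t = t,
        y = (beta0 + u[g, 1]) + (beta1 + u[g, 2]) * t +
          rnorm(n_years, 0, sigma)
      )
    }))
  })
}

# Monthly temperature tibble for hand-built fixtures.
make_temps <- function(tas_by_month, years, watershed_id = "w1") {
  tidyr::expand_grid(watershed_id = watershed_id, year = years,
                     month = 1:12) |>
    dplyr::mutate(tas_c = tas_by_month[month])
}

one_region <- function(ids, elev = 1000) {
  tibble::tibble(watershed_id = ids, region = "r1",
                 elevation_m = rep_len(elev, length(ids)))
}
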