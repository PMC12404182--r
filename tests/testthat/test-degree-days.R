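test_that("day counts follow the Gregorian and fixed-365 calendars", {
  expect_equal(days_in_month(2000, 2), 29)
  expect_equal(days_in_month(1900, 2), 28)
  expect_equal(days_in_month(2004, 2), 29)
  expect_equal(days_in_month(2015, 4, "fixed_365"), 30)
  expect_equal(days_in_month(2000, 2, "fixed_365"), 28)
  expect_equal(sum(days_in_month(2015, 1:12, "fixed_365")), 365)
  expect_error(days_in_month(2000, 13), class = "thermalscape_domain_error")
})

test_that("monthly degree days expand the monthly mean and truncate at zero", {
  expect_equal(monthly_degree_days(10, 0, 30), 300)
  expect_equal(monthly_degree_days(-5, 0, 31), 0)
  # 0.8 degC above the Sierra Nevada-style 14.2 degC killing threshold
  expect_equal(monthly_degree_days(15, 14.2, 31), 31 * 0.8)
  expect_error(monthly_degree_days(10, 0, 0), class = "thermalscape_domain_error")
})

test_that("annual degree days sum complete years and reject partial ones", {
  expect_equal(annual_degree_days(rep(10, 12), 2001), 3650)
  expect_equal(annual_degree_days(rep(10, 12), 2000), 3660)
  alt <- rep(c(-10, 10), 6) # warm months: Feb Apr Jun Aug Oct Dec
  expect_equal(annual_degree_days(alt, 2001),
               10 * (28 + 30 + 30 + 31 + 31 + 31))
  expect_error(annual_degree_days(rep(10, 11), 2001, month = 1:11),
               class = "thermalscape_incomplete_year_error")
})

test_that("KDD thresholds use interpolated order statistics per region", {
  w <- one_region(sprintf("w%02d", 1:10))
  temps <- tibble::tibble(watershed_id = w$watershed_id, year = 2000,
                          month = 1, tas_c = 1:10)
  thr <- kdd_thresholds(temps, w, 0.9)
  expect_equal(thr$kdd_threshold_c, 9.1)
  expect_equal(thr$n_values, 10)

  same <- temps |> dplyr::mutate(tas_c = 7)
  expect_equal(kdd_thresholds(same, w, 0.9)$kdd_threshold_c, 7)

  two <- temps[1:2, ] |> dplyr::mutate(tas_c = c(0, 100))
  expect_equal(kdd_thresholds(two, w, 0.9)$kdd_threshold_c, 90)

  expect_error(kdd_thresholds(temps[0, ], w), class = "thermalscape_domain_error")
})

test_that("degree-day tables retain zero rows and share formulas at equal bases", {
  w <- one_region("w1")
  cold <- make_temps(rep(-1, 12), 2000:2002)
  thr <- tibble::tibble(region = "r1", kdd_threshold_c = 15)
  dd <- compute_degree_days(cold, w, thr)
  expect_equal(nrow(dd), 3)
  expect_true(all(dd$gdd == 0 & dd$kdd == 0))

  warm <- make_temps(c(2, 4, 8, 12, 16, 20, 22, 21, 15, 10, 5, 1), 2000:2002)
  thr0 <- tibble::tibble(region = "r1", kdd_threshold_c = 0)
  dd0 <- compute_degree_days(warm, w, thr0, gdd_base_c = 0)
  expect_equal(dd0$gdd, dd0$kdd)
})

test_that("one row per complete watershed-year; incomplete years warn and drop", {
  w <- one_region(c("w1", "w2"))
  temps <- dplyr::bind_rows(make_temps(rep(10, 12), 2000:2002, "w1"),
                            make_temps(rep(12, 12), 2000:2002, "w2"))
  thr <- tibble::tibble(region = "r1", kdd_threshold_c = 11)
  dd <- compute_degree_days(temps, w, thr)
  expect_equal(nrow(dd), 6)

  broken <- temps |> dplyr::filter(!(watershed_id == "w1" & year == 2000 & month == 6))
  expect_warning(dd2 <- compute_degree_days(broken, w, thr), "incomplete")
  expect_equal(nrow(dd2), 5)
  expect_false(any(dd2$watershed_id == "w1" & dd2$time_key == "2000"))

  expect_error(compute_degree_days(temps, w,
                                   tibble::tibble(region = "r9",
                                                  kdd_threshold_c = 1)),
               class = "thermalscape_lookup_error")
})

test_that("climatology degree days use 365-day years and the same truncation", {
  w <- one_region("w1")
  clim <- tidyr::expand_grid(watershed_id = "w1", period = c("P1", "P2"),
                             month = 1:12) |>
    dplyr::mutate(tas_c = ifelse(period == "P1", 10, 11))
  thr <- tibble::tibble(region = "r1", kdd_threshold_c = 20)
  dd <- climatology_degree_days(clim, w, thr)
  expect_equal(dd$gdd[dd$time_key == "P1"], 3650)
  expect_equal(dd$gdd[dd$time_key == "P2"] - dd$gdd[dd$time_key == "P1"], 365)
  expect_true(all(dd$kdd == 0)) # every month below the killing threshold
  expect_error(climatology_degree_days(clim[-1, ], w, thr),
               class = "thermalscape_incomplete_year_error")
})

test_that("annual sums match the brute-force daily expansion oracle", {
  withr::with_seed(101, {
    for (i in 1:25) {
      tas <- runif(12, -15, 25)
      yr <- sample(1980:2019, 1)
      base <- runif(1, 0, 15)
      expect_equal(annual_degree_days(tas, yr, base_c = base),
                   daily_expansion_dd(tas, yr, base_c = base),
                   tolerance = 1e-12)
    }
  })
})

test_that("degree days are monotone in temperature and threshold, and GDD >= KDD", {
  withr::with_seed(55, {
    w <- one_region("w1")
    for (i in 1:10) {
      tas <- runif(12, -10, 25)
      temps <- make_temps(tas, 2001)
      thrv <- runif(1, 5, 20)
      thr <- tibble::tibble(region = "r1", kdd_threshold_c = thrv)
      dd <- compute_degree_days(temps, w, thr)
      expect_gte(dd$gdd, dd$kdd) # kdd threshold above gdd base

      m <- sample(12, 1)
      bump <- temps |>
        dplyr::mutate(tas_c = tas_c + ifelse(month == m, runif(1, 0, 5), 0))
      dd2 <- compute_degree_days(bump, w, thr)
      expect_gte(dd2$gdd, dd$gdd)
      expect_gte(dd2$kdd, dd$kdd)

      thr_hi <- tibble::tibble(region = "r1", kdd_threshold_c = thrv + 2)
      expect_lte(compute_degree_days(temps, w, thr_hi)$kdd, dd$kdd)
    }
  })
})

test_that("shifting an above-base year by delta adds delta x days-in-year", {
  tas <- runif(12, 5, 20)
  delta <- 1.7
  base <- annual_degree_days(tas, 2001)
  expect_equal(annual_degree_days(tas + delta, 2001), base + delta * 365,
               tolerance = 1e-9)
  expect_equal(annual_degree_days(tas + delta, 2000),
               annual_degree_days(tas, 2000) + delta * 366, tolerance = 1e-9)
})
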