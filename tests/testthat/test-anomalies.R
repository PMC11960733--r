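constant_monthly <- function(value = 7.9, years = 2005:2014,
                             months = 1:12, ...) {
  grid <- expand.grid(year = years, month = months)
  grid$value <- value
  make_monthly(grid, ...)
}

test_that("climatology of a constant series is that constant, with a
           minimum-years threshold", {
  clim <- compute_climatology(constant_monthly())
  expect_equal(nrow(clim), 12)
  expect_true(all(clim$clim == 7.9))
  expect_true(all(clim$n_years == 10))

  # one month observed in a single year falls below min_years = 3
  m <- constant_monthly(years = 2005:2010, months = 1:11)
  extra <- constant_monthly(years = 2008, months = 12)
  clim3 <- compute_climatology(dplyr::bind_rows(m, extra), min_years = 3)
  expect_false(12L %in% clim3$month)
})

test_that("anomalies are value minus climatology and average to zero per
           month", {
  m <- constant_monthly()
  m$value <- m$value + rnorm(nrow(m))
  a <- deseasonalize(m)
  expect_equal(a$anomaly, a$value - a$clim)
  by_month <- dplyr::summarise(
    dplyr::group_by(a, month), mu = mean(anomaly), .groups = "drop"
  )
  expect_true(all(abs(by_month$mu) < 1e-9))

  # a series equal to its climatology has exactly zero anomalies
  z <- deseasonalize(constant_monthly())
  expect_true(all(z$anomaly == 0))
})

test_that("de-seasonalizing its own output leaves a zero climatology", {
  m <- constant_monthly()
  m$value <- m$value + rnorm(nrow(m))
  a <- deseasonalize(m)
  a2 <- dplyr::mutate(dplyr::select(a, -"clim", -"anomaly", -"value"),
                      value = a$anomaly)
  clim2 <- compute_climatology(a2)
  expect_true(all(abs(clim2$clim) < 1e-9))
})

test_that("bay-wide averaging is unweighted over reporting stations", {
  a <- dplyr::bind_rows(
    tibble::tibble(station_id = "AA", layer = "surface",
                   parameter = "ph_nbs", year = 2010, month = 6,
                   anomaly = 1),
    tibble::tibble(station_id = "BB", layer = "surface",
                   parameter = "ph_nbs", year = 2010, month = 6,
                   anomaly = -1),
    tibble::tibble(station_id = "AA", layer = "surface",
                   parameter = "ph_nbs", year = 2010, month = 7,
                   anomaly = 0.4)
  )
  bw <- baywide_average(a)
  expect_equal(bw$anomaly[bw$month == 6], 0)
  expect_equal(bw$n_stations[bw$month == 6], 2L)
  # a station silent in July does not enter the denominator
  expect_equal(bw$anomaly[bw$month == 7], 0.4)
  expect_equal(bw$n_stations[bw$month == 7], 1L)
  # the river station is excluded by default
  pd <- dplyr::mutate(a[1, ], station_id = "PD", anomaly = 99)
  expect_equal(baywide_average(dplyr::bind_rows(a, pd))$anomaly[1], 0)
})

test_that("an exact line is recovered with its slope, and adding a constant
           does not change it", {
  grid <- expand.grid(year = 2005:2014, month = 1:12)
  t <- grid$year + (grid$month - 0.5) / 12
  a <- tibble::tibble(layer = "surface", parameter = "do_umolkg",
                      year = grid$year, month = grid$month,
                      anomaly = 0.5 * (t - 2010))
  ft <- fit_trend(a)
  expect_equal(ft$slope, 0.5, tolerance = 1e-12)
  expect_lt(ft$p_value, 1e-10)
  ft2 <- fit_trend(dplyr::mutate(a, anomaly = anomaly + 3.7))
  expect_equal(ft2$slope, ft$slope, tolerance = 1e-12)

  expect_equal(nrow(fit_trend(a[1:10, ])), 0)  # below min_months
})

test_that("white noise rarely yields a significant trend", {
  set.seed(99)
  hits <- 0
  for (i in 1:100) {
    grid <- expand.grid(year = 2005:2019, month = 1:12)
    a <- tibble::tibble(layer = "surface", parameter = "x",
                        year = grid$year, month = grid$month,
                        anomaly = rnorm(nrow(grid)))
    hits <- hits + (fit_trend(a)$p_value < 0.05)
  }
  expect_gte(100 - hits, 90)
})

test_that("Durbin-Watson screening flags autocorrelated series", {
  set.seed(7)
  # month varies fastest so the AR draws follow the time ordering
  grid <- expand.grid(month = 1:12, year = 2005:2019)
  ar <- as.numeric(stats::filter(rnorm(nrow(grid)), 0.8,
                                 method = "recursive"))
  a <- tibble::tibble(layer = "surface", parameter = "x",
                      year = grid$year, month = grid$month, anomaly = ar)
  expect_lt(fit_trend(a)$dw_p, 0.05)
  white <- dplyr::mutate(a, anomaly = rnorm(nrow(a)))
  expect_gt(fit_trend(white)$dw_p, 0.001)
})

test_that("tidy and glance expose the fitted models", {
  net <- small_network()
  bw <- baywide_average(deseasonalize(monthly_means(net$daily)))
  ft <- fit_trend(bw)
  td <- tidy(ft)
  expect_true(all(c("layer", "parameter", "slope", "conf_low",
                    "conf_high") %in% names(td)))
  gl <- glance(ft)
  expect_true(all(c("r_squared", "dw_p", "n_months") %in% names(gl)))
  expect_equal(nrow(td), nrow(gl))
})

test_that("anomaly regression recovers identity and honours layer modes", {
  grid <- expand.grid(year = 2005:2012, month = 1:12,
                      layer = c("surface", "bottom"))
  set.seed(4)
  x <- rnorm(nrow(grid))
  a <- dplyr::bind_rows(
    tibble::tibble(layer = grid$layer, parameter = "temperature",
                   year = grid$year, month = grid$month, anomaly = x),
    tibble::tibble(layer = grid$layer, parameter = "do_umolkg",
                   year = grid$year, month = grid$month, anomaly = x)
  )
  # exact collinearity makes summary.lm warn about a perfect fit
  fit <- suppressWarnings(regress_anomalies(a, "do_umolkg", "temperature",
                                            layer_mode = "pooled"))
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)

  fit_mean <- suppressWarnings(
    regress_anomalies(a, "do_umolkg", "temperature",
                      layer_mode = "mean-of-layers")
  )
  expect_equal(fit_mean$slope, 1, tolerance = 1e-12)
  expect_equal(fit_mean$n, nrow(grid) / 2)

  expect_error(
    regress_anomalies(a[a$year == 2005, ], "do_umolkg", "temperature"),
    "matched months"
  )
})

test_that("a known anomaly coupling is recovered from noisy series", {
  set.seed(12)
  grid <- expand.grid(year = 2005:2019, month = 1:12)
  do_anom <- rnorm(nrow(grid), 0, 10)
  ph_anom <- 0.00156 * do_anom + rnorm(nrow(grid), 0, 0.005)
  a <- dplyr::bind_rows(
    tibble::tibble(layer = "surface", parameter = "do_umolkg",
                   year = grid$year, month = grid$month, anomaly = do_anom),
    tibble::tibble(layer = "surface", parameter = "ph_nbs",
                   year = grid$year, month = grid$month, anomaly = ph_anom)
  )
  fit <- regress_anomalies(a, "ph_nbs", "do_umolkg",
                           layer_mode = "surface")
  expect_true(fit$conf_low < 0.00156 & 0.00156 < fit$conf_high)
  expect_equal(fit$slope, 0.00156, tolerance = 0.05)
})
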