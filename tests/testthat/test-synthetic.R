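test_that("identical seeds give bit-identical networks", {
  cfg <- nb_profile(years = 2005:2006)
  a <- generate_network(cfg, seed = 21)
  b <- generate_network(cfg, seed = 21)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$outliers, b$truth$outliers)
  c <- generate_network(cfg, seed = 22)
  expect_false(identical(a$records, c$records))
})

test_that("the generated network has the configured station structure", {
  net <- small_network()
  rec <- net$records
  expect_setequal(unique(rec$station_id),
                  c("GD", "TW", "BR", "NP", "CP", "MV", "QP", "PP", "SR",
                    "PD"))
  expect_setequal(unique(rec$layer), c("surface", "bottom"))
  # bottom layers carry no chlorophyll
  expect_true(all(is.na(rec$chl[rec$layer == "bottom"])))
  expect_true(all(!is.na(rec$chl[rec$layer == "surface"])))
  # seasonal stations sample May-October only; GD and TW run year-round
  mo <- as.integer(format(as.Date(rec$timestamp), "%m"))
  expect_true(all(mo[rec$station_id == "BR"] %in% 5:10))
  expect_setequal(unique(mo[rec$station_id == "GD"]), 1:12)
  # the river station is much fresher than the bay stations
  expect_lt(mean(rec$salinity[rec$station_id == "PD"]),
            mean(rec$salinity[rec$station_id != "PD"]) - 5)
})

test_that("a noise-free, trend-free network is an exact fixed point of the
           pipeline", {
  net <- generate_network(
    nb_profile(years = 2005:2007, noise = FALSE, outliers = FALSE,
               trends = FALSE),
    seed = 1
  )
  res <- remove_outliers_cascade(daily_means(net$records))
  expect_equal(res$report$n_days_removed, 0)
  ft <- fit_trend(baywide_average(deseasonalize(monthly_means(res$daily))))
  expect_true(all(abs(ft$slope) < 1e-10))
})

test_that("generated carbonate variables close thermodynamically", {
  net <- generate_network(nb_profile(years = 2005:2006, outliers = FALSE),
                          seed = 8)
  set.seed(1)
  d <- net$daily[sample.int(nrow(net$daily), 50), ]
  back <- carb_solve(d$temperature, d$salinity, ta = d$ta, dic = d$dic)
  expect_equal(back$ph_nbs, d$ph_nbs, tolerance = 1e-9)
})

test_that("with biology and noise off, generated pH lies on the mixing
           curve at the reference temperature", {
  net <- generate_network(
    nb_profile(years = 2005:2006, noise = FALSE, outliers = FALSE,
               bio_coupling = FALSE, trends = FALSE),
    seed = 1
  )
  curve <- build_mixing_curve(salinity_grid = seq(0, 33, by = 0.25))
  set.seed(2)
  obs <- dplyr::slice_sample(
    dplyr::select(net$daily, "temperature", "salinity", "ph_nbs"),
    n = 200
  )
  dev <- mixing_deviation(adjust_ph_to_temperature(obs), curve)
  expect_lt(max(abs(dev$delta_ph)), 5e-4)
})

test_that("outlier injection is reproducible, fence-beating and bounded", {
  net <- generate_network(nb_profile(years = 2005:2006, outliers = FALSE),
                          seed = 3)
  none <- inject_outliers(net$daily, rate = 0, seed = 1)
  expect_identical(none$daily, net$daily)
  expect_equal(nrow(none$outliers), 0)

  a <- inject_outliers(net$daily, rate = 0.02, magnitude = 2, seed = 10)
  b <- inject_outliers(net$daily, rate = 0.02, magnitude = 2, seed = 10)
  expect_identical(a$outliers, b$outliers)

  # rate 0.02 per parameter over the series: binomial count near expectation
  n_days <- nrow(net$daily)
  expect_gt(nrow(a$outliers), 0.02 * 4 * n_days * 0.7)
  expect_lt(nrow(a$outliers), 0.02 * 4 * n_days * 1.3)

  # every injected value lies outside the clean series' own fences
  clean_fences <- dplyr::group_by(
    tidyr::pivot_longer(net$daily, dplyr::all_of(
      c("temperature", "salinity", "do_umolkg", "ph_nbs")
    ), names_to = "parameter", values_to = "value"),
    station_id, layer, parameter
  )
  clean_fences <- dplyr::summarise(
    clean_fences, iqr_fences(value[is.finite(value)]), .groups = "drop"
  )
  chk <- dplyr::inner_join(a$outliers, clean_fences,
                           by = c("station_id", "layer", "parameter"))
  expect_true(all(chk$injected < chk$lower | chk$injected > chk$upper))
})

test_that("the truth ledger records realized skeleton trends near the
           configured targets", {
  prep <- nb_prepared()
  tr <- prep$truth$trends
  get <- function(ly, p) tr$slope[tr$layer == ly & tr$parameter == p]
  # oxygen targets are met exactly by calibration (up to the small
  # de-seasonalization attenuation of a finite record)
  expect_equal(get("surface", "do_umolkg"), -0.69, tolerance = 0.01)
  expect_equal(get("bottom", "do_umolkg"), 0.43, tolerance = 0.01)
  expect_equal(get("bottom", "ph_nbs"), 0.0021, tolerance = 0.02)
  expect_equal(get("surface", "chl"), -0.26, tolerance = 0.02)
  expect_equal(get("surface", "temperature"), 0.020, tolerance = 0.01)
  expect_equal(get("bottom", "temperature"), 0.041, tolerance = 0.01)
})
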