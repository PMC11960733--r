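test_that("daily means average readings and honor min_samples", {
  rec <- make_records(n_days = 1, per_day = 96, salinity = 5)
  d <- daily_means(rec)
  expect_equal(nrow(d), 1)
  expect_equal(d$salinity, 5)
  expect_equal(d$n_salinity, 96L)

  rec <- make_records(n_days = 1, per_day = 3, ph_nbs = c(7.9, 8.0, 8.1))
  expect_equal(daily_means(rec)$ph_nbs, 8.0)

  d <- daily_means(make_records(n_days = 1, per_day = 3), min_samples = 4)
  expect_true(is.na(d$salinity))
})

test_that("oxygen is converted per reading before daily averaging", {
  rec <- make_records(n_days = 1, per_day = 2,
                      temperature = c(10, 24), salinity = c(28, 31))
  d <- daily_means(rec)
  expect_equal(d$do_umolkg,
               mean(do_mgL_to_umolkg(8, c(10, 24), c(28, 31))))
})

test_that("IQR fences use interpolated order statistics", {
  f <- iqr_fences(c(2, 4, 4, 5, 5, 5, 6, 6, 20))
  expect_equal(f$q1, 4)
  expect_equal(f$q3, 6)
  expect_equal(f$iqr, 2)
  expect_equal(f$lower, 1)
  expect_equal(f$upper, 9)
  expect_true(20 > f$upper)

  same <- iqr_fences(rep(7.5, 10))
  expect_equal(same$iqr, 0)
  expect_equal(same$lower, 7.5)
  expect_equal(same$upper, 7.5)

  sym <- iqr_fences(1:9)
  expect_equal(c(sym$q1, sym$q3), unname(quantile(1:9, c(0.25, 0.75))))
  expect_true(all(1:9 >= sym$lower & 1:9 <= sym$upper))

  expect_error(iqr_fences(c(1, 2, 3)), "at least 4")
})

test_that("a flagged parameter removes the whole day and the cascade
           reaches a fixed point", {
  sal <- c(rep(c(29.5, 30, 30.5, 29.8, 30.2), 8), 5)
  daily <- make_daily(sal, parameter = "salinity")
  res <- remove_outliers_cascade(daily)
  expect_equal(nrow(res$daily), length(sal) - 1)
  # the extreme day is gone entirely (whole row removed)
  expect_false(max(daily$date) %in% res$daily$date)
  expect_equal(res$report$removed$parameter, "salinity")
  # fixed point: re-running the cascade removes nothing
  again <- remove_outliers_cascade(res$daily)
  expect_equal(nrow(again$daily), nrow(res$daily))
  expect_equal(again$report$n_days_removed, 0)
})

test_that("clean data pass through untouched", {
  daily <- make_daily(rep(c(29.5, 30, 30.5, 29.8), 10))
  res <- remove_outliers_cascade(daily)
  expect_equal(res$daily, daily)
  expect_equal(res$report$n_iterations, 0L)
  expect_equal(res$report$removed_fraction, 0)
})

test_that("masked extremes require multiple passes and the result is clean", {
  # construct a masked outlier with the flagger itself: x2 sits inside the
  # fences while the gross outlier x1 is present, but outside them once
  # x1 has been removed, so the cascade needs a second pass to catch it
  set.seed(81)
  base <- rnorm(40, 10, 1)
  x1 <- 100
  x2 <- NA
  for (cand in seq(12, 18, by = 0.05)) {
    f_with <- iqr_fences(c(base, x1, cand))
    f_without <- iqr_fences(c(base, cand))
    if (cand <= f_with$upper && cand > f_without$upper) {
      x2 <- cand
      break
    }
  }
  expect_false(is.na(x2))
  daily <- make_daily(c(base, x1, x2), parameter = "do_umolkg")
  res <- remove_outliers_cascade(daily)
  expect_gte(res$report$n_iterations, 2)
  expect_true(all(c(x1, x2) %in% res$report$removed$value))
  # verify the fixed point independently with the flagger itself
  f <- iqr_fences(res$daily$do_umolkg)
  expect_true(all(res$daily$do_umolkg >= f$lower &
                    res$daily$do_umolkg <= f$upper))
})

test_that("chlorophyll is never filtered and never causes removal", {
  daily <- make_daily(rep(c(29.5, 30, 30.5, 29.8), 10))
  daily$chl <- c(rep(4, nrow(daily) - 1), 5000)
  res <- remove_outliers_cascade(daily)
  expect_equal(nrow(res$daily), nrow(daily))
  expect_true(5000 %in% res$daily$chl)
})

test_that("days missing a screened parameter are retained", {
  daily <- make_daily(rep(c(29.5, 30, 30.5, 29.8), 10))
  daily$ph_nbs[3] <- NA
  res <- remove_outliers_cascade(daily)
  expect_true(as.Date("2011-06-03") %in% res$daily$date)
})

test_that("removal is monotone under added contamination", {
  set.seed(31)
  base_vals <- rnorm(60, 30, 0.5)
  base_vals[10] <- 36
  base <- make_daily(base_vals, parameter = "salinity")
  res_base <- remove_outliers_cascade(base)
  for (extra in c(45, 20, 36)) {
    vals <- c(base_vals, extra)
    more <- make_daily(vals, parameter = "salinity")
    res_more <- remove_outliers_cascade(more)
    removed_orig <- dplyr::filter(res_more$report$removed,
                                  date <= max(base$date))
    expect_gte(nrow(dplyr::distinct(removed_orig, date)),
               res_base$report$n_days_removed)
  }
})

test_that("injected outliers are recalled at 95% or better", {
  net <- generate_network(nb_profile(years = 2005:2007, outliers = FALSE),
                          seed = 13)
  inj <- inject_outliers(net$daily, rate = 0.03, magnitude = 2, seed = 14)
  res <- remove_outliers_cascade(inj$daily)
  injected <- dplyr::distinct(inj$outliers, station_id, layer, date)
  removed <- dplyr::distinct(res$report$removed, station_id, layer, date)
  hit <- dplyr::inner_join(injected, removed,
                           by = c("station_id", "layer", "date"))
  expect_gte(nrow(hit) / nrow(injected), 0.95)
})

test_that("monthly means aggregate clean days and drop empty months", {
  daily <- make_daily(rep(7.9, 30), parameter = "ph_nbs",
                      start = "2011-06-01")
  m <- monthly_means(daily)
  expect_equal(m$value[m$parameter == "ph_nbs"], 7.9)
  expect_equal(m$n_days[m$parameter == "ph_nbs"], 30L)

  two <- make_daily(c(rep(10, 15), rep(20, 15)), parameter = "salinity",
                    start = "2011-06-01")
  m2 <- monthly_means(two)
  expect_equal(m2$value[m2$parameter == "salinity"], 15)

  # a month fully removed by QA/QC is absent, not NA
  gap <- make_daily(rep(c(29.5, 30, 30.5, 29.8), 20), start = "2011-06-01")
  gap <- gap[format(gap$date, "%m") != "07", ]
  m3 <- monthly_means(gap)
  expect_false(7L %in% m3$month)
})

test_that("QA/QC reports serialize to JSON", {
  daily <- make_daily(c(rep(c(29.5, 30, 30.5, 29.8), 10), 5))
  res <- remove_outliers_cascade(daily)
  path <- tempfile(fileext = ".json")
  write_qaqc_report(res$report, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$n_days_removed, 1L)
  expect_equal(length(back$removed), 1L)
  expect_equal(back$removed[[1]]$parameter, "salinity")
})
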