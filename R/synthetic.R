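#' Narragansett-Bay-like synthetic network profile
#'
#' Configuration for [generate_network()] emulating a ten-station,
#' two-layer estuarine monitoring network over 15 years: two stations
#' (`GD`, `TW`) sample year-round and the rest May through October; `PD`
#' is the brackish river station that bay-wide averages exclude. Each
#' parameter is generated as station mean + annual and semiannual
#' harmonics + linear trend + AR(1) monthly noise carried to daily
#' resolution + daily measurement noise, with a shared decade-scale
#' salinity excursion (wet/dry periods). Oxygen is built from solubility
#' at the generated temperature and salinity plus a biological term
#' coupled to the chlorophyll anomaly; pH is derived by speciating
#' TA(salinity) and DIC(salinity) plus biological DIC perturbations, so
#' the generated carbonate variables are thermodynamically consistent by
#' construction.
#'
#' The default injected trends are the bay's reported decadal rates:
#' surface DO -0.69 and bottom DO +0.43 umol/kg/yr, surface chlorophyll
#' -0.26 ug/L/yr, bottom pH +0.0021 /yr, surface warming 0.020 and bottom
#' warming 0.041 degC/yr. The generator uses a 365-day calendar (no leap
#' days) so that a noise-free configuration reproduces its seasonal
#' climatology exactly.
#'
#' @param years Calendar years spanned (>= 2).
#' @param cadence Readings per day (1 = daily; 96 = 15-minute).
#' @param noise Include AR(1) + daily noise?
#' @param outliers Inject episodic outlier days (rate 1% per parameter,
#'   placed beyond the IQR fences)?
#' @param bio_coupling Include biological DO and DIC terms (and the
#'   calibrated biological trends)? With this off and `noise` off, pH
#'   falls exactly on the conservative mixing curve.
#' @param trends Include all linear trends and the salinity excursion?
#' @param seed Default master seed used by [generate_network()].
#' @return A list of class `synthetic_config`.
#' @export
nb_profile <- function(years = 2005:2019, cadence = 1, noise = TRUE,
                       outliers = TRUE, bio_coupling = TRUE, trends = TRUE,
                       seed = 1) {
  stopifnot(length(years) >= 2, cadence >= 1)
  tr <- function(x) if (trends) x else 0
  bio <- function(x) if (bio_coupling) x else x * 0
  stations <- tibble::tibble(
    station_id = c("GD", "TW", "BR", "NP", "CP", "MV", "QP", "PP", "SR",
                   "PD"),
    year_round = c(TRUE, TRUE, rep(FALSE, 8)),
    s_mean = c(29, 30, 26, 28, 25, 27, 24, 28.5, 29.5, 16),
    t_offset = c(0, -0.2, 0.3, 0.1, 0.4, -0.1, 0.5, 0, -0.3, 0.6)
  )
  cfg <- list(
    stations = stations, years = years, cadence = cadence, seed = seed,
    noise_on = noise, outliers_on = outliers, bio_on = bio_coupling,
    temperature = list(
      surface = list(mean = 11.5, amp1 = 10.5, peak1 = 217, amp2 = 0.6,
                     peak2 = 30, trend = tr(0.020), phi = 0,
                     sd_month = 0.9, sd_day = 0.3),
      bottom = list(mean = 11.0, amp1 = 9.5, peak1 = 225, amp2 = 0.5,
                    peak2 = 30, trend = tr(0.041), phi = 0,
                    sd_month = 0.9, sd_day = 0.3)
    ),
    salinity = list(
      surface = list(mean = 0, amp1 = 1.2, peak1 = 245, amp2 = 0.4,
                     peak2 = 60, trend = 0, phi = 0, sd_month = 1.2,
                     sd_day = 0.4),
      bottom = list(mean = 1.5, amp1 = 0.7, peak1 = 245, amp2 = 0.3,
                    peak2 = 60, trend = 0, phi = 0, sd_month = 0.8,
                    sd_day = 0.3)
    ),
    chl = list(
      surface = list(mean = 8, amp1 = 2.5, peak1 = 200, amp2 = 1.5,
                     peak2 = 40, trend = tr(-0.26), phi = 0,
                     sd_month = 1.5, sd_day = 0.8)
    ),
    # piecewise-linear bay-wide salinity excursion (wet/dry periods),
    # surface amplitude; bottom is damped by excursion_bottom_scale
    excursion = list(year = c(2005, 2011, 2014, 2016, 2019),
                     value = tr(1) * c(0, 0, 2, 2, -1),
                     bottom_scale = 0.6),
    do = list(
      target_trend = c(surface = tr(-0.69), bottom = tr(0.43)),
      bio0 = bio(c(surface = 8, bottom = -25)),
      chl_coupling = bio(c(surface = 2.0, bottom = -1.2)),
      phi = 0, sd_month = 9, sd_day = 4
    ),
    dic = list(
      target_ph_trend_bottom = tr(0.0021),
      bio0 = bio(c(surface = -10, bottom = 30)),
      chl_coupling = bio(c(surface = -3.5, bottom = 2.5)),
      phi = 0, sd_month = 15, sd_day = 6
    ),
    outlier = list(rate = if (outliers) 0.01 else 0, magnitude = 2),
    endmembers = nb_endmembers(), constants = "lueker"
  )
  structure(cfg, class = "synthetic_config")
}

# annual + semiannual harmonics on the 365-day synthetic calendar
.harmonics <- function(doy, p) {
  p$amp1 * cospi(2 * (doy - p$peak1) / 365) +
    p$amp2 * cospi(4 * (doy - p$peak2) / 365)
}

# station x layer x date grid on a no-leap calendar, with season mask
.network_grid <- function(cfg) {
  d0 <- as.Date(paste0(min(cfg$years), "-01-01"))
  d1 <- as.Date(paste0(max(cfg$years), "-12-31"))
  dates <- seq.Date(d0, d1, by = "day")
  dates <- dates[format(dates, "%m-%d") != "02-29"]
  year <- as.integer(format(dates, "%Y"))
  doy <- stats::ave(rep(1, length(dates)), year, FUN = cumsum)
  dec_year <- year + (doy - 0.5) / 365
  cal <- tibble::tibble(date = dates, year = year, doy = doy,
                        dec_year = dec_year,
                        t = dec_year - mean(range(dec_year)))
  grid <- tidyr::expand_grid(
    cfg$stations,
    layer = c("surface", "bottom"),
    cal
  )
  dplyr::arrange(
    dplyr::filter(grid, .data$year_round |
                    (.data$doy >= 121 & .data$doy <= 304)),
    .data$station_id, .data$layer, .data$date
  )
}

# deterministic (noise-free) component of every field
.det_fields <- function(grid, cfg) {
  ex <- approx(cfg$excursion$year, cfg$excursion$value,
               xout = grid$dec_year, rule = 2)$y
  ex <- ex * ifelse(grid$layer == "bottom", cfg$excursion$bottom_scale, 1)
  g <- grid
  g$T_det <- NA_real_
  g$S_det <- NA_real_
  for (ly in c("surface", "bottom")) {
    i <- g$layer == ly
    pt <- cfg$temperature[[ly]]
    ps <- cfg$salinity[[ly]]
    g$T_det[i] <- pt$mean + g$t_offset[i] + .harmonics(g$doy[i], pt) +
      pt$trend * g$t[i]
    g$S_det[i] <- g$s_mean[i] + ps$mean + .harmonics(g$doy[i], ps) +
      ps$trend * g$t[i] + ex[i]
  }
  pc <- cfg$chl$surface
  surf <- g$layer == "surface"
  g$chl_base <- NA_real_
  g$chl_det <- NA_real_
  g$chl_base[surf] <- pc$mean + .harmonics(g$doy[surf], pc)
  g$chl_det[surf] <- pmax(g$chl_base[surf] + pc$trend * g$t[surf], 0.05)
  g
}

# biological DO and DIC offsets for given chlorophyll deviations
.bio_terms <- function(g, cfg, chl_dev, do_free, dic_resp) {
  surf <- g$layer == "surface"
  # bottom respiration responds to the overlying surface chlorophyll
  dev_tbl <- tibble::tibble(station_id = g$station_id[surf],
                            date = g$date[surf], dev = chl_dev[surf])
  bottom_dev <- dplyr::left_join(
    tibble::tibble(station_id = g$station_id[!surf], date = g$date[!surf]),
    dev_tbl, by = c("station_id", "date")
  )$dev
  dev_row <- numeric(nrow(g))
  dev_row[surf] <- chl_dev[surf]
  dev_row[!surf] <- dplyr::coalesce(bottom_dev, 0)
  ly <- ifelse(surf, "surface", "bottom")
  list(
    do = cfg$do$bio0[ly] + cfg$do$chl_coupling[ly] * dev_row +
      do_free[ly] * g$t,
    dic = cfg$dic$bio0[ly] + cfg$dic$chl_coupling[ly] * dev_row +
      ifelse(surf, 0, dic_resp * g$t)
  )
}

# bay-wide anomaly slopes of a daily table, as the pipeline computes them
.skeleton_slopes <- function(daily) {
  m <- monthly_means(daily)
  bw <- baywide_average(deseasonalize(m), exclude = "PD")
  ft <- fit_trend(bw, min_months = 24)
  dplyr::select(tibble::as_tibble(ft), "layer", "parameter", "slope")
}

.slope_of <- function(slopes, ly, param) {
  s <- slopes$slope[slopes$layer == ly & slopes$parameter == param]
  if (length(s) == 0) 0 else s
}

#' Prepare a synthetic network: skeleton, calibration and truth ledger
#'
#' Builds the deterministic (noise-free) skeleton of the configured
#' network, calibrates the free biological trend terms so that the
#' skeleton's pipeline-recovered trends hit the configured targets (the
#' oxygen targets exactly; the bottom-pH target via the local dpH/dDIC
#' sensitivity), and records the realized skeleton trends as the truth
#' ledger. The prepared object can be passed to [generate_network()]
#' repeatedly to draw independent noise replicates around the same truth.
#'
#' @param config A [nb_profile()] configuration.
#' @return A list of class `prepared_network` with elements `grid` (the
#'   skeleton), `truth` (ledger: realized trends, targets, calibrated
#'   coefficients) and `config`.
#' @export
prepare_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  g <- .det_fields(.network_grid(cfg), cfg)
  chl_dev0 <- ifelse(is.na(g$chl_det), NA_real_, g$chl_det - g$chl_base)

  zero <- c(surface = 0, bottom = 0)
  bio0 <- .bio_terms(g, cfg, chl_dev0, do_free = zero, dic_resp = 0)
  ta0 <- ta_from_salinity(g$S_det, cfg$endmembers)
  dic0 <- dic_from_salinity(g$S_det, cfg$endmembers) + bio0$dic
  skel <- function(do_bio, dic) tibble::tibble(
    station_id = g$station_id, layer = g$layer, date = g$date,
    temperature = g$T_det, salinity = g$S_det,
    do_umolkg = o2_solubility(g$T_det, g$S_det) + do_bio,
    ph_nbs = carb_solve(g$T_det, g$S_det, ta = ta0, dic = dic,
                        constants = cfg$constants)$ph_nbs,
    chl = g$chl_det
  )

  do_free <- zero
  dic_resp <- 0
  if (cfg$bio_on) {
    s0 <- .skeleton_slopes(skel(bio0$do, dic0))
    do_free <- c(
      surface = cfg$do$target_trend[["surface"]] -
        .slope_of(s0, "surface", "do_umolkg"),
      bottom = cfg$do$target_trend[["bottom"]] -
        .slope_of(s0, "bottom", "do_umolkg")
    )
    # local pH sensitivity to DIC at the mean bottom state
    bot <- g$layer == "bottom"
    st <- c(t = mean(g$T_det[bot]), s = mean(g$S_det[bot]),
            ta = mean(ta0[bot]), dic = mean(dic0[bot]))
    dph <- (carb_solve(st["t"], st["s"], ta = st["ta"],
                       dic = st["dic"] + 5)$ph_total -
            carb_solve(st["t"], st["s"], ta = st["ta"],
                       dic = st["dic"] - 5)$ph_total) / 10
    dic_resp <- (cfg$dic$target_ph_trend_bottom -
                   .slope_of(s0, "bottom", "ph_nbs")) / dph
  }
  bio1 <- .bio_terms(g, cfg, chl_dev0, do_free, dic_resp)
  dic1 <- dic_from_salinity(g$S_det, cfg$endmembers) + bio1$dic
  truth_trends <- .skeleton_slopes(skel(bio1$do, dic1))

  g$do_bio_det <- bio1$do
  g$dic_bio_det <- bio1$dic
  structure(
    list(
      grid = g,
      truth = list(
        trends = truth_trends,
        targets = tibble::tibble(
          layer = c("surface", "bottom", "surface", "bottom", "surface",
                    "bottom"),
          parameter = c("do_umolkg", "do_umolkg", "chl", "ph_nbs",
                        "temperature", "temperature"),
          target = c(cfg$do$target_trend[["surface"]],
                     cfg$do$target_trend[["bottom"]],
                     cfg$chl$surface$trend,
                     cfg$dic$target_ph_trend_bottom,
                     cfg$temperature$surface$trend,
                     cfg$temperature$bottom$trend)
        ),
        calibration = list(do_free_trend = do_free,
                           dic_resp_trend = dic_resp)
      ),
      config = cfg
    ),
    class = "prepared_network"
  )
}

# AR(1) monthly-scale noise carried to daily resolution as month-constant
# blocks, plus independent daily measurement noise; drawn group by group
# in a fixed order for seed reproducibility. Blocks (rather than linear
# interpolation between monthly knots) keep the lag-1 correlation of the
# resulting monthly means equal to the AR coefficient itself; smoothing
# across knots would add ~0.3 of spurious month-to-month correlation,
# contradicting the mostly-clean Durbin-Watson screening that monitoring
# networks of this kind exhibit.
.field_noise <- function(g, p, enabled) {
  if (!enabled || (p$sd_month == 0 && p$sd_day == 0)) {
    return(numeric(nrow(g)))
  }
  y0 <- min(g$year)
  n_months <- (max(g$year) - y0 + 1) * 12
  month_of <- as.integer(format(g$date, "%m"))
  month_idx <- (g$year - y0) * 12 + month_of
  gid <- paste(g$station_id, g$layer)
  idx <- split(seq_len(nrow(g)), factor(gid, levels = unique(gid)))
  out <- numeric(nrow(g))
  for (i in idx) {
    x <- as.numeric(stats::filter(rnorm(n_months, 0, p$sd_month), p$phi,
                                  method = "recursive"))
    out[i] <- x[month_idx[i]] + rnorm(length(i), 0, p$sd_day)
  }
  out
}

#' Generate a synthetic monitoring-network realization
#'
#' Draws one noise realization of the configured network around its
#' deterministic skeleton, injects outlier days, and emits raw sensor
#' records (DO in mg/L, pH on the NBS scale, chlorophyll at surface
#' stations only) in the layout [read_sensor_csv()] reads. Identical seeds
#' give bit-identical output.
#'
#' @param config A [nb_profile()] configuration, or a
#'   [prepare_network()] result when generating many replicates.
#' @param seed Integer seed; defaults to the profile's master seed.
#' @return A list of class `synthetic_network`: `records` (raw readings),
#'   `daily` (the daily truth-level values the records average back to),
#'   `truth` (the ledger, including the injected outlier days), and
#'   `config`.
#' @examples
#' \donttest{
#' net <- generate_network(nb_profile(years = 2005:2008), seed = 7)
#' head(net$records)
#' }
#' @export
generate_network <- function(config, seed = NULL) {
  prep <- if (inherits(config, "prepared_network")) config
          else prepare_network(config)
  cfg <- prep$config
  seed <- seed %||% cfg$seed
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  g <- prep$grid
  surf <- g$layer == "surface"
  temperature <- g$T_det + .layered_noise(g, cfg$temperature, cfg$noise_on)
  salinity <- pmax(g$S_det + .layered_noise(g, cfg$salinity, cfg$noise_on),
                   0.2)
  chl <- rep(NA_real_, nrow(g))
  chl[surf] <- pmax(
    g$chl_det[surf] +
      .field_noise(g[surf, ], cfg$chl$surface, cfg$noise_on),
    0.05
  )
  chl_dev <- chl - g$chl_base

  # biological terms respond to the *noisy* chlorophyll deviation, with
  # the calibrated free trend components from the prepared skeleton
  bio <- .bio_terms(g, cfg, chl_dev,
                    do_free = prep$truth$calibration$do_free_trend,
                    dic_resp = prep$truth$calibration$dic_resp_trend)

  do_umolkg <- pmax(
    o2_solubility(temperature, salinity) + bio$do +
      .field_noise(g, cfg$do, cfg$noise_on),
    1
  )
  dic <- dic_from_salinity(salinity, cfg$endmembers) + bio$dic +
    .field_noise(g, cfg$dic, cfg$noise_on)
  ta <- ta_from_salinity(salinity, cfg$endmembers)
  ph_nbs <- carb_solve(temperature, salinity, ta = ta, dic = dic,
                       constants = cfg$constants)$ph_nbs

  daily <- tibble::tibble(
    station_id = g$station_id, layer = g$layer, date = g$date,
    temperature = temperature, salinity = salinity,
    do_umolkg = do_umolkg, ph_nbs = ph_nbs, chl = chl,
    ta = ta, dic = dic
  )
  outliers <- NULL
  if (cfg$outlier$rate > 0) {
    inj <- inject_outliers(daily, rate = cfg$outlier$rate,
                           magnitude = cfg$outlier$magnitude)
    daily <- inj$daily
    outliers <- inj$outliers
  }

  truth <- prep$truth
  truth$outliers <- outliers
  truth$seed <- seed
  structure(
    list(records = .expand_records(daily, cfg), daily = daily,
         truth = truth, config = cfg),
    class = "synthetic_network"
  )
}

# noise for a parameter with per-layer settings
.layered_noise <- function(g, p, enabled) {
  out <- numeric(nrow(g))
  for (ly in c("surface", "bottom")) {
    i <- g$layer == ly
    out[i] <- .field_noise(g[i, ], p[[ly]], enabled)
  }
  out
}

# expand daily values to `cadence` readings per day and convert DO units
.expand_records <- function(daily, cfg) {
  cad <- cfg$cadence
  n <- nrow(daily)
  idx <- rep(seq_len(n), each = cad)
  frac <- rep((seq_len(cad) - 0.5) / cad, times = n)
  rec <- daily[idx, ]
  rec$timestamp <- as.POSIXct(rec$date, tz = "UTC") + frac * 86400
  if (cad > 1 && cfg$noise_on) {
    rec$temperature <- rec$temperature + rnorm(nrow(rec), 0, 0.05)
    rec$salinity <- pmax(rec$salinity + rnorm(nrow(rec), 0, 0.05), 0.1)
    rec$do_umolkg <- pmax(rec$do_umolkg + rnorm(nrow(rec), 0, 2), 0.5)
    rec$ph_nbs <- rec$ph_nbs + rnorm(nrow(rec), 0, 0.01)
    surf <- rec$layer == "surface"
    rec$chl[surf] <- pmax(rec$chl[surf] + rnorm(sum(surf), 0, 0.3), 0.01)
  }
  rec$do_mgL <- do_umolkg_to_mgL(rec$do_umolkg, rec$temperature,
                                 rec$salinity)
  dplyr::select(
    dplyr::arrange(rec, .data$station_id, .data$layer, .data$timestamp),
    "station_id", "timestamp", "layer", "temperature", "salinity",
    "do_mgL", "ph_nbs", "chl"
  )
}

#' Inject outlier days into a daily series
#'
#' Replaces randomly selected days (per station, layer and parameter,
#' independently at rate `rate`) with values placed `magnitude` IQR beyond
#' the series' own Tukey fences, on a randomly chosen side, so every
#' injected value is flaggable by construction. The injected day list is
#' returned for recall scoring of the QA/QC cascade.
#'
#' @param daily A daily tibble as from [daily_means()].
#' @param parameters Parameters eligible for injection.
#' @param rate Injection probability per day and parameter, in [0, 0.1].
#' @param magnitude How many IQRs beyond the fence to place the value.
#' @param seed Optional seed (uses the current RNG stream when `NULL`).
#' @return A list with `daily` (modified) and `outliers` (tibble of
#'   `station_id`, `layer`, `date`, `parameter`, `original`, `injected`).
#' @export
inject_outliers <- function(daily, parameters = QC_PARAMETERS, rate = 0.01,
                            magnitude = 2, seed = NULL) {
  stopifnot(rate >= 0, rate <= 0.1, magnitude > 0)
  if (!is.null(seed)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
  }
  if (rate == 0) {
    return(list(daily = daily, outliers = tibble::tibble(
      station_id = character(), layer = character(),
      date = as.Date(character()), parameter = character(),
      original = numeric(), injected = numeric()
    )))
  }
  out <- daily
  ledger <- list()
  gid <- paste(daily$station_id, daily$layer)
  groups <- split(seq_len(nrow(daily)), factor(gid, levels = unique(gid)))
  for (p in parameters) {
    for (i in groups) {
      v <- out[[p]][i]
      ok <- is.finite(v)
      if (sum(ok) < 4) next
      f <- iqr_fences(v[ok])
      sel <- ok & (stats::runif(length(v)) < rate)
      if (!any(sel)) next
      side <- stats::runif(sum(sel)) < 0.5
      inj <- ifelse(side, f$upper + magnitude * f$iqr,
                    f$lower - magnitude * f$iqr)
      ledger[[length(ledger) + 1]] <- tibble::tibble(
        station_id = out$station_id[i][sel], layer = out$layer[i][sel],
        date = out$date[i][sel], parameter = p,
        original = v[sel], injected = inj
      )
      out[[p]][i[sel]] <- inj
    }
  }
  ledger <- if (length(ledger)) dplyr::bind_rows(ledger) else
    tibble::tibble(station_id = character(), layer = character(),
                   date = as.Date(character()), parameter = character(),
                   original = numeric(), injected = numeric())
  list(daily = out, outliers = ledger)
}
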