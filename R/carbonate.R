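#' Equilibrium constants for the seawater carbonate system
#'
#' Evaluates the dissociation and solubility constants needed to speciate
#' the inorganic carbon system at in-situ temperature and salinity, surface
#' pressure. The default (and currently only) registered set matches the
#' customary defaults of the community CO2 calculators: carbonic acid
#' constants of Lueker et al. (2000) on the total hydrogen-ion scale,
#' bisulfate of Dickson (1990a), fluoride of Perez & Fraga (1987), borate
#' total from Uppstrom (1974), water from Millero (1995), and CO2 solubility
#' from Weiss (1974). The set label travels with every solver output so the
#' constants choice is always recorded.
#'
#' @param temperature Temperature, degrees C.
#' @param salinity Practical salinity (PSU).
#' @param set Name of the constants set; `"lueker"` is the registered
#'   default.
#' @return A list of vectors: `K0` (mol/kg/atm), `K1`, `K2`, `KB`, `KW`,
#'   `KS`, `KF` (mol/kg, total scale except `KS` on the free scale), and
#'   the total borate `BT`, sulfate `ST` and fluoride `FT` (mol/kg), plus
#'   the set `label`.
#' @export
carb_constants <- function(temperature, salinity, set = "lueker") {
  set <- match.arg(set)
  tk <- temperature + 273.15
  lnt <- log(tk)
  s <- salinity
  sqs <- sqrt(s)

  pk1 <- 3633.86 / tk - 61.2172 + 9.6777 * lnt - 0.011555 * s +
    0.0001152 * s^2
  pk2 <- 471.78 / tk + 25.929 - 3.16967 * lnt - 0.01781 * s +
    0.0001122 * s^2
  lnkb <- (-8966.90 - 2890.53 * sqs - 77.942 * s + 1.728 * s^1.5 -
             0.0996 * s^2) / tk +
    (148.0248 + 137.1942 * sqs + 1.62142 * s) +
    (-24.4344 - 25.085 * sqs - 0.2474 * s) * lnt + 0.053105 * sqs * tk
  lnkw <- 148.9802 - 13847.26 / tk - 23.6521 * lnt +
    (-5.977 + 118.67 / tk + 1.0495 * lnt) * sqs - 0.01615 * s
  # Dickson (1990a) bisulfate, free scale, molal ionic strength
  is <- 19.924 * s / (1000 - 1.005 * s)
  lnks <- -4276.1 / tk + 141.328 - 23.093 * lnt +
    (-13856 / tk + 324.57 - 47.986 * lnt) * sqrt(is) +
    (35474 / tk - 771.54 + 114.723 * lnt) * is -
    2698 / tk * is^1.5 + 1776 / tk * is^2 + log(1 - 0.001005 * s)
  lnkf <- 874 / tk - 9.68 + 0.111 * sqs
  lnk0 <- -60.2409 + 93.4517 * (100 / tk) + 23.3585 * log(tk / 100) +
    s * (0.023517 - 0.023656 * (tk / 100) + 0.0047036 * (tk / 100)^2)

  list(
    K0 = exp(lnk0), K1 = 10^-pk1, K2 = 10^-pk2,
    KB = exp(lnkb), KW = exp(lnkw), KS = exp(lnks), KF = exp(lnkf),
    BT = 0.0004157 * s / 35, ST = 0.02824 * s / 35, FT = 0.00007 * s / 35,
    label = "lueker"
  )
}

# total alkalinity (mol/kg) implied by [H+] on the total scale and DIC
# (mol/kg): carbonate + borate + water, minus free proton, bisulfate and HF
.ta_from_h <- function(h, dic, k) {
  denom <- h^2 + k$K1 * h + k$K1 * k$K2
  hco3 <- dic * k$K1 * h / denom
  co3 <- dic * k$K1 * k$K2 / denom
  hfree <- h / (1 + k$ST / k$KS)
  hso4 <- k$ST / (1 + k$KS / hfree)
  hf <- k$FT / (1 + k$KF / h)
  hco3 + 2 * co3 + k$BT * k$KB / (k$KB + h) + k$KW / h - hfree - hso4 - hf
}

# vectorised bisection for total-scale pH given a residual function f(ph)
# that is increasing in pH; returns pH where f = 0
.bisect_ph <- function(f, n, lower = 3, upper = 12, iter = 70) {
  lo <- rep(lower, n)
  hi <- rep(upper, n)
  flo <- f(lo)
  fhi <- f(hi)
  bad <- !is.finite(flo) | !is.finite(fhi) | flo * fhi > 0
  if (any(bad, na.rm = TRUE)) {
    stop("carbonate solver: no root bracketed in pH [", lower, ", ", upper,
         "] for ", sum(bad, na.rm = TRUE), " input state(s); ",
         "check that TA, DIC and pCO2 are physically consistent")
  }
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    up <- f(mid) > 0
    hi <- ifelse(up, mid, hi)
    lo <- ifelse(up, lo, mid)
  }
  (lo + hi) / 2
}

# fugacity factor converting fCO2 to pCO2 (Weiss 1974 virial coefficients)
.fugacity_factor <- function(temperature) {
  tk <- temperature + 273.15
  b <- -1636.75 + 12.0408 * tk - 0.0327957 * tk^2 + 3.16528e-5 * tk^3
  delta <- 57.7 - 0.118 * tk
  exp((b + 2 * delta) * 1 / (82.05736 * tk))
}

#' Solve the seawater carbonate system
#'
#' Given any two of total alkalinity (`ta`), dissolved inorganic carbon
#' (`dic`), `ph` and `pco2`, plus temperature and salinity, returns the
#' thermodynamically consistent full state at surface pressure. The
#' alkalinity balance includes the carbonate, borate and water
#' contributions minus the free proton, bisulfate and hydrogen-fluoride
#' terms; nutrient bases (phosphate, silicate) are taken as zero, matching
#' monitoring networks that do not measure them. Internally the system is
#' solved on the total hydrogen-ion scale by bracketed bisection on pH over
#' [3, 12]; sensor-style NBS pH is accepted and reported through a constant
#' scale offset (see [ph_scale_offset()]).
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param temperature Temperature, degrees C.
#' @param salinity Practical salinity (PSU).
#' @param ta Total alkalinity, umol/kg.
#' @param dic Dissolved inorganic carbon, umol/kg.
#' @param ph pH, on the scale named by `ph_scale`.
#' @param pco2 CO2 partial pressure, uatm.
#' @param ph_scale Scale of the supplied `ph`: `"total"` (default) or
#'   `"nbs"`.
#' @param constants Constants set label, see [carb_constants()].
#' @return A tibble with columns `temperature`, `salinity`, `ta`, `dic`,
#'   `ph_total`, `ph_nbs`, `pco2`, `fco2`, `co2`, `hco3`, `co3` (umol/kg
#'   where applicable, uatm for the gas terms) and `constants`.
#' @examples
#' carb_solve(17, 30, ta = 2037, dic = 1915)
#' @export
carb_solve <- function(temperature, salinity, ta = NULL, dic = NULL,
                       ph = NULL, pco2 = NULL,
                       ph_scale = c("total", "nbs"),
                       constants = "lueker") {
  ph_scale <- match.arg(ph_scale)
  given <- !vapply(list(ta = ta, dic = dic, ph = ph, pco2 = pco2),
                   is.null, logical(1))
  if (sum(given) != 2) {
    stop("carb_solve() needs exactly two of `ta`, `dic`, `ph`, `pco2`; got ",
         sum(given))
  }
  if (!is.null(ph) && ph_scale == "nbs") {
    ph <- ph_scale_offset(ph, from = "nbs", to = "total")
  }

  n <- max(lengths(list(temperature, salinity, ta, dic, ph, pco2)))
  temperature <- rep_len(temperature, n)
  salinity <- rep_len(salinity, n)
  k <- carb_constants(temperature, salinity, set = constants)

  ta_m <- if (!is.null(ta)) rep_len(ta, n) * 1e-6
  dic_m <- if (!is.null(dic)) rep_len(dic, n) * 1e-6
  ph <- if (!is.null(ph)) rep_len(ph, n)
  co2_m <- if (!is.null(pco2)) {
    rep_len(pco2, n) * 1e-6 * .fugacity_factor(temperature) * k$K0
  }

  pair <- paste(names(given)[given], collapse = "+")
  if (pair == "ta+dic") {
    ph <- .bisect_ph(function(p) .ta_from_h(10^-p, dic_m, k) - ta_m, n)
  } else if (pair == "ta+ph") {
    h <- 10^-ph
    hfree <- h / (1 + k$ST / k$KS)
    nc <- k$BT * k$KB / (k$KB + h) + k$KW / h - hfree -
      k$ST / (1 + k$KS / hfree) - k$FT / (1 + k$KF / h)
    alpha <- (k$K1 * h + 2 * k$K1 * k$K2) / (h^2 + k$K1 * h + k$K1 * k$K2)
    dic_m <- (ta_m - nc) / alpha
  } else if (pair == "dic+ph") {
    ta_m <- .ta_from_h(10^-ph, dic_m, k)
  } else if (pair == "ph+pco2") {
    h <- 10^-ph
    dic_m <- co2_m * (1 + k$K1 / h + k$K1 * k$K2 / h^2)
    ta_m <- .ta_from_h(h, dic_m, k)
  } else if (pair == "ta+pco2") {
    ph <- .bisect_ph(function(p) {
      h <- 10^-p
      .ta_from_h(h, co2_m * (1 + k$K1 / h + k$K1 * k$K2 / h^2), k) - ta_m
    }, n)
    h <- 10^-ph
    dic_m <- co2_m * (1 + k$K1 / h + k$K1 * k$K2 / h^2)
  } else if (pair == "dic+pco2") {
    # CO2* decreases as pH rises, so negate to keep the residual increasing
    ph <- .bisect_ph(function(p) {
      h <- 10^-p
      co2_m - dic_m * h^2 / (h^2 + k$K1 * h + k$K1 * k$K2)
    }, n)
    ta_m <- .ta_from_h(10^-ph, dic_m, k)
  }

  h <- 10^-ph
  if (is.null(ta_m)) ta_m <- .ta_from_h(h, dic_m, k)
  resid <- .ta_from_h(h, dic_m, k) - ta_m
  if (max(abs(resid)) > 1e-10) {
    stop("carbonate solver did not converge: max |TA residual| = ",
         format(max(abs(resid)), digits = 3), " mol/kg")
  }
  denom <- h^2 + k$K1 * h + k$K1 * k$K2
  co2_m <- dic_m * h^2 / denom
  hco3_m <- dic_m * k$K1 * h / denom
  co3_m <- dic_m * k$K1 * k$K2 / denom
  fco2 <- co2_m / k$K0 * 1e6
  out_pco2 <- fco2 / .fugacity_factor(temperature)

  tibble::tibble(
    temperature = temperature, salinity = salinity,
    ta = ta_m * 1e6, dic = dic_m * 1e6,
    ph_total = ph,
    ph_nbs = ph_scale_offset(ph, from = "total", to = "nbs"),
    pco2 = out_pco2, fco2 = fco2,
    co2 = co2_m * 1e6, hco3 = hco3_m * 1e6, co3 = co3_m * 1e6,
    constants = k$label
  )
}

#' Convert pH between the NBS and total hydrogen-ion scales
#'
#' Estuarine sensor networks report pH on the NBS scale while carbonate
#' solvers work on the total scale. Lacking the activity-coefficient data
#' needed for an exact conversion, the package adopts the constant offset
#' convention `pH_NBS = pH_total + 0.13` that is customary for this
#' monitoring data set.
#'
#' @param ph pH value(s).
#' @param from,to Scales, each one of `"nbs"` or `"total"`.
#' @param offset The constant NBS minus total offset; default `0.13`.
#' @return pH on the `to` scale.
#' @examples
#' ph_scale_offset(7.87, from = "total", to = "nbs")
#' @export
ph_scale_offset <- function(ph, from, to, offset = 0.13) {
  from <- match.arg(from, c("nbs", "total"))
  to <- match.arg(to, c("nbs", "total"))
  if (from == to) return(ph)
  if (from == "total") ph + offset else ph - offset
}

#' Temperature sensitivities of pH and pCO2 at fixed TA and DIC
#'
#' Warming a water parcel without changing its total alkalinity or
#' dissolved inorganic carbon shifts the carbonate equilibria: pH falls and
#' pCO2 rises. These helpers evaluate the discrete sensitivity over a
#' `dt`-degree step (default 1 degree C), which is the form used in
#' driver-attribution budgets.
#'
#' @inheritParams carb_solve
#' @param dt Temperature step, degrees C.
#' @return `ph_temperature_sensitivity()`: change in total-scale pH per
#'   degree C (negative). `pco2_temperature_sensitivity()`: fractional
#'   change in pCO2 per degree C (positive).
#' @examples
#' ph_temperature_sensitivity(2037, 1915, 17, 30)
#' pco2_temperature_sensitivity(2037, 1915, 17, 30)
#' @export
ph_temperature_sensitivity <- function(ta, dic, temperature, salinity,
                                       dt = 1, constants = "lueker") {
  p0 <- carb_solve(temperature, salinity, ta = ta, dic = dic,
                   constants = constants)
  p1 <- carb_solve(temperature + dt, salinity, ta = ta, dic = dic,
                   constants = constants)
  (p1$ph_total - p0$ph_total) / dt
}

#' @rdname ph_temperature_sensitivity
#' @export
pco2_temperature_sensitivity <- function(ta, dic, temperature, salinity,
                                         dt = 1, constants = "lueker") {
  p0 <- carb_solve(temperature, salinity, ta = ta, dic = dic,
                   constants = constants)
  p1 <- carb_solve(temperature + dt, salinity, ta = ta, dic = dic,
                   constants = constants)
  (p1$pco2 - p0$pco2) / p0$pco2 / dt
}

#' Representative estuarine conditions for DIC error propagation
#'
#' A grid of (temperature, salinity, pH) states spanning the mid-to-high
#' salinity range of the bay (S from 20 to 32) crossed with the observed
#' sensor pH range (7.6 to 8.2), at the bay mean temperature of 17 degrees
#' C. TA at each salinity comes from the TA-salinity regression of the
#' supplied endmember model. Following the network convention, the sensor
#' pH values are carried into the speciation unconverted (i.e. used as the
#' solver's pH): this is the procedure that reproduces the published
#' sensor-derived DIC-salinity relationship, which sits within a few tens
#' of umol/kg of the bottle-sample line and therefore cannot have had a
#' 0.13 scale offset applied.
#'
#' @param salinity Salinity grid.
#' @param ph pH levels crossed with the salinity grid, carried unconverted
#'   into the solver.
#' @param temperature Temperature, degrees C.
#' @param model Endmember model supplying the TA-salinity line, see
#'   [nb_endmembers()].
#' @return A tibble with columns `temperature`, `salinity`, `ta`, `ph`.
#' @export
nb_error_conditions <- function(salinity = seq(20, 32, by = 2),
                                ph = c(7.6, 7.9, 8.2),
                                temperature = 17,
                                model = nb_endmembers()) {
  grid <- tidyr::expand_grid(salinity = salinity, ph = ph)
  tibble::tibble(
    temperature = temperature,
    salinity = grid$salinity,
    ta = ta_from_salinity(grid$salinity, model),
    ph = grid$ph
  )
}

#' Monte-Carlo propagation of TA and pH errors into calculated DIC
#'
#' When DIC is calculated from salinity-estimated TA and sensor pH, both
#' inputs carry errors. This routine draws independent zero-mean normal
#' perturbations of TA (sd `ta_sigma`, umol/kg) and pH (sd `ph_sigma`),
#' speciates each draw to DIC, and reports the per-condition standard
#' deviation of calculated DIC together with its mean across conditions.
#'
#' @param ta_sigma Standard error of TA, umol/kg.
#' @param ph_sigma Standard error of pH.
#' @param conditions Tibble of states with columns `temperature`,
#'   `salinity`, `ta`, `ph_nbs` (see [nb_error_conditions()]).
#' @param n_draws Monte-Carlo draws per condition (>= 1000).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param constants Constants set label.
#' @return A tibble, one row per condition, with `sigma_dic` (umol/kg), the
#'   central `dic`, and `relative` = sigma_dic / dic. The mean of
#'   `sigma_dic` across conditions is attached as attribute
#'   `mean_sigma_dic`.
#' @examples
#' \donttest{
#' pr <- propagate_dic_error(10, 0.1, n_draws = 2000, seed = 1)
#' attr(pr, "mean_sigma_dic")
#' }
#' @export
propagate_dic_error <- function(ta_sigma, ph_sigma,
                                conditions = nb_error_conditions(),
                                n_draws = 5000, seed = NULL,
                                constants = "lueker") {
  stopifnot(ta_sigma >= 0, ph_sigma >= 0, n_draws >= 1000)
  if (!is.null(seed)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
  }
  nc <- nrow(conditions)
  idx <- rep(seq_len(nc), each = n_draws)
  ta_draw <- conditions$ta[idx] + rnorm(nc * n_draws, 0, ta_sigma)
  ph_draw <- conditions$ph[idx] + rnorm(nc * n_draws, 0, ph_sigma)
  st <- carb_solve(conditions$temperature[idx], conditions$salinity[idx],
                   ta = ta_draw, ph = ph_draw, constants = constants)
  dic <- st$dic
  failed <- !is.finite(dic) | dic <= 0
  if (mean(failed) > 0.01) {
    stop("propagate_dic_error(): ", sum(failed), " of ", length(failed),
         " draws failed to speciate (> 1%)")
  }
  dic[failed] <- NA_real_
  per <- tibble::tibble(
    conditions,
    sigma_dic = unname(vapply(split(dic, idx), sd, numeric(1),
                              na.rm = TRUE)),
    dic = unname(vapply(split(dic, idx), mean, numeric(1), na.rm = TRUE)),
    n_failed = unname(vapply(split(failed, idx), sum, numeric(1)))
  )
  per$relative <- per$sigma_dic / per$dic
  attr(per, "mean_sigma_dic") <- mean(per$sigma_dic)
  per
}

# save/restore RNG state so seeded helpers do not disturb the caller's stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
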