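#' Frozen Narragansett Bay budget coefficients
#'
#' The driver-attribution budgets multiply observed trends by coupling
#' slopes. For reproducing the bay's published budget arithmetic exactly,
#' this profile freezes the literature-reported coefficients: the
#' oxygen-anomaly sensitivities to temperature (-3.7 umol/kg per degree C)
#' and salinity (-0.98 umol/kg per PSU), the pH-anomaly sensitivities to
#' salinity (0.0163 pH per PSU) and to oxygen (0.00156 pH per umol/kg),
#' the open-ocean atmospheric acidification rate (-0.001 to -0.002 pH/yr;
#' midpoint used as the point value), and the observed warming rates
#' (0.020 surface, 0.041 bottom, degrees C/yr). In a fresh analysis the
#' corresponding slopes come from [regress_anomalies()] and [fit_trend()]
#' instead.
#'
#' @return A named list of coefficients.
#' @export
nb_budget_coefficients <- function() {
  list(
    do_temperature_slope = -3.7,    # umol/kg per degC
    do_salinity_slope = -0.98,      # umol/kg per PSU
    ph_salinity_slope = 0.0163,     # pH per PSU
    ph_do_slope = 0.00156,          # pH per umol/kg
    oa_rate = -0.0015,              # pH per yr, open-ocean uptake
    oa_rate_range = c(-0.002, -0.001),
    surface_warming = 0.020,        # degC per yr
    bottom_warming = 0.041,         # degC per yr
    window_years = 15
  )
}

.new_budget <- function(target, terms, observed, window_years) {
  terms$cumulative <- terms$rate * window_years
  explained <- !grepl("residual", terms$driver)
  residual <- if (is.null(observed)) NA_real_ else
    observed - sum(terms$rate[explained])
  out <- tibble::new_tibble(terms, class = "attribution_budget")
  attr(out, "target") <- target
  attr(out, "observed_trend") <- observed
  attr(out, "residual") <- residual
  attr(out, "window_years") <- window_years
  out
}

#' Solubility-driven attribution of a dissolved-oxygen trend
#'
#' Decomposes an observed DO trend into the parts explained by warming and
#' salinity change acting through solubility-type sensitivities, plus a
#' biological residual: `residual = observed - (slope_T * trend_T +
#' slope_S * trend_S)`. A positive residual against a warming-driven
#' decline indicates reduced respiration (or increased production); for
#' the bay's bottom water the residual is the signature of reduced
#' organic-carbon loading after nutrient reduction.
#'
#' @param observed_trend Observed DO trend, umol/kg per yr.
#' @param temperature_trend,salinity_trend Observed trends, degC/yr and
#'   PSU/yr.
#' @param temperature_slope,salinity_slope DO sensitivities, umol/kg per
#'   degC and per PSU (e.g. from [regress_anomalies()] or the local
#'   derivatives of [o2_solubility()]).
#' @param target Label for the budget.
#' @param window_years Window used for the cumulative form of each term.
#' @return A tibble of class `attribution_budget` with one row per term
#'   (`driver`, `rate` in umol/kg/yr, `cumulative` over the window); the
#'   observed trend and the biological residual are attributes and the
#'   residual is also included as the `biological_residual` row.
#' @examples
#' do_solubility_budget(0.43, 0.041, 0, -3.7, -0.98)
#' @export
do_solubility_budget <- function(observed_trend, temperature_trend,
                                 salinity_trend, temperature_slope,
                                 salinity_slope, target = "bottom DO",
                                 window_years = 15) {
  t_term <- temperature_slope * temperature_trend
  s_term <- salinity_slope * salinity_trend
  terms <- tibble::tibble(
    driver = c("temperature_solubility", "salinity_solubility",
               "biological_residual"),
    rate = c(t_term, s_term, observed_trend - t_term - s_term),
    units = "umol/kg/yr",
    provenance = c(
      sprintf("%.3g degC/yr x %.3g umol/kg/degC", temperature_trend,
              temperature_slope),
      sprintf("%.3g PSU/yr x %.3g umol/kg/PSU", salinity_trend,
              salinity_slope),
      "observed - (temperature + salinity terms)"
    )
  )
  .new_budget(target, terms, observed_trend, window_years)
}

#' Four-process attribution of a pH trend
#'
#' Combines the four processes acting simultaneously on estuarine pH:
#' freshwater mixing (salinity change times the pH-salinity slope),
#' changing biological respiration (the biological DO rate times the
#' pH-DO slope), warming at fixed TA and DIC (warming rate times the
#' thermodynamic pH sensitivity from [ph_temperature_sensitivity()]), and
#' atmospheric CO2 uptake (an exogenous open-ocean rate). Each term is a
#' rate (pH/yr) with a cumulative form over the analysis window.
#'
#' @param salinity_trend PSU per yr.
#' @param do_bio_rate Biological DO change rate, umol/kg per yr (e.g. the
#'   `biological_residual` of [do_solubility_budget()]).
#' @param warming_rate degC per yr.
#' @param ph_salinity_slope,ph_do_slope Coupling slopes, pH per PSU and pH
#'   per umol/kg.
#' @param ph_t_sensitivity pH change per degC at fixed TA and DIC; by
#'   default computed from the carbonate solver at typical bay water
#'   (T = 17, S = 30, TA = 2037, DIC = 1915 umol/kg).
#' @param oa_rate Atmospheric acidification rate, pH/yr (negative).
#' @param observed_trend Optional observed pH trend, pH/yr, for the
#'   residual.
#' @param target Label.
#' @param window_years Window for cumulative terms.
#' @param constants Constants set used when `ph_t_sensitivity` is computed.
#' @return An `attribution_budget` tibble, one row per process.
#' @examples
#' coef <- nb_budget_coefficients()
#' ph_budget(salinity_trend = 0.02, do_bio_rate = 0.6,
#'           warming_rate = coef$bottom_warming,
#'           observed_trend = 0.0021)
#' @export
ph_budget <- function(salinity_trend, do_bio_rate, warming_rate,
                      ph_salinity_slope = nb_budget_coefficients()$ph_salinity_slope,
                      ph_do_slope = nb_budget_coefficients()$ph_do_slope,
                      ph_t_sensitivity = NULL,
                      oa_rate = nb_budget_coefficients()$oa_rate,
                      observed_trend = NULL, target = "bottom pH",
                      window_years = 15, constants = "lueker") {
  if (is.null(ph_t_sensitivity)) {
    ph_t_sensitivity <- ph_temperature_sensitivity(2037, 1915, 17, 30,
                                                   constants = constants)
  }
  terms <- tibble::tibble(
    driver = c("freshwater_mixing", "respiration_change", "warming",
               "atmospheric_co2"),
    rate = c(salinity_trend * ph_salinity_slope,
             do_bio_rate * ph_do_slope,
             warming_rate * ph_t_sensitivity,
             oa_rate),
    units = "pH/yr",
    provenance = c(
      sprintf("%.3g PSU/yr x %.3g pH/PSU", salinity_trend,
              ph_salinity_slope),
      sprintf("%.3g umol/kg/yr x %.3g pH/(umol/kg)", do_bio_rate,
              ph_do_slope),
      sprintf("%.3g degC/yr x %.4g pH/degC", warming_rate,
              ph_t_sensitivity),
      "exogenous open-ocean uptake rate"
    )
  )
  .new_budget(target, terms, observed_trend, window_years)
}

#' @export
print.attribution_budget <- function(x, ...) {
  cat("<attribution_budget: ", attr(x, "target"), ">\n", sep = "")
  df <- as.data.frame(x)
  df$rate <- signif(df$rate, 3)
  df$cumulative <- signif(df$cumulative, 3)
  print(df, row.names = FALSE)
  obs <- attr(x, "observed_trend")
  if (!is.null(obs) && !is.na(obs)) {
    cat(sprintf("  observed: %.3g /yr; sum of terms: %.3g /yr; residual: %.3g /yr\n",
                obs, sum(x$rate), attr(x, "residual")))
  }
  cat(sprintf("  cumulative over %d years\n", attr(x, "window_years")))
  invisible(x)
}
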