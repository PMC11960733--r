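#' Monthly climatology per station, layer and parameter
#'
#' The climatological seasonal cycle is the multiyear mean of each calendar
#' month's monthly mean, computed separately per station, layer and
#' parameter. Subtracting it isolates interannual variability from the
#' (dominant) seasonal cycle.
#'
#' @param monthly Long monthly table from [monthly_means()].
#' @param min_years Minimum number of contributing years for a
#'   climatological month to be reported.
#' @return A tibble with `station_id`, `layer`, `parameter`, `month`,
#'   `clim`, `n_years`.
#' @export
compute_climatology <- function(monthly, min_years = 1) {
  stopifnot(min_years >= 1)
  out <- dplyr::summarise(
    dplyr::group_by(monthly, .data$station_id, .data$layer,
                    .data$parameter, .data$month),
    clim = mean(.data$value), n_years = dplyr::n(), .groups = "drop"
  )
  dplyr::filter(out, .data$n_years >= min_years)
}

#' De-seasonalized monthly anomalies
#'
#' Subtracts the monthly climatology from each monthly mean:
#' `anomaly = value - clim` for the matching (station, layer, parameter,
#' month). Months without a climatological value are omitted. By
#' construction the anomalies of each (station, layer, parameter, month)
#' average to zero over the contributing years.
#'
#' @param monthly Long monthly table from [monthly_means()].
#' @param climatology Output of [compute_climatology()]; computed from
#'   `monthly` itself when not supplied.
#' @return `monthly` with added columns `clim` and `anomaly`.
#' @export
deseasonalize <- function(monthly, climatology = NULL) {
  if (is.null(climatology)) climatology <- compute_climatology(monthly)
  out <- dplyr::inner_join(
    monthly, dplyr::select(climatology, -"n_years"),
    by = c("station_id", "layer", "parameter", "month")
  )
  dplyr::mutate(out, anomaly = .data$value - .data$clim)
}

#' Bay-wide average of station anomalies
#'
#' Unweighted mean of the de-seasonalized monthly anomalies across the
#' analysis stations, per layer, parameter, year and month. Stations with
#' no value in a month simply drop out of that month's denominator. The
#' network's low-salinity river station (`"PD"`) is excluded by default
#' because its brackish conditions are not representative of the bay.
#'
#' @param anomalies Output of [deseasonalize()].
#' @param stations Optional character vector restricting the average to
#'   these stations.
#' @param exclude Stations to drop; default `"PD"`.
#' @return A tibble with `layer`, `parameter`, `year`, `month`, `anomaly`
#'   and the contributing `n_stations`.
#' @export
baywide_average <- function(anomalies, stations = NULL, exclude = "PD") {
  x <- anomalies
  if (!is.null(stations)) x <- dplyr::filter(x, .data$station_id %in% stations)
  if (!is.null(exclude)) x <- dplyr::filter(x, !.data$station_id %in% exclude)
  if (nrow(x) == 0) stop("baywide_average(): no stations left to average")
  dplyr::summarise(
    dplyr::group_by(x, .data$layer, .data$parameter, .data$year,
                    .data$month),
    anomaly = mean(.data$anomaly), n_stations = dplyr::n(), .groups = "drop"
  )
}

# decimal-time axis centred on month midpoints
.decimal_time <- function(year, month) year + (month - 0.5) / 12

#' Linear trends of monthly anomalies
#'
#' Ordinary least squares of the de-seasonalized anomaly on decimal time
#' (year + (month - 0.5)/12), fitted separately per series (per station if
#' a `station_id` column is present, otherwise per layer and parameter).
#' The slope, in parameter units per year, is the long-term trend. A
#' Durbin-Watson test for lag-1 autocorrelation of the residuals is
#' attached for screening only; no autocorrelation correction is applied
#' to the inference, matching the practice of reporting OLS trends when
#' most series show no significant autocorrelation.
#'
#' @param anomalies Long anomaly tibble ([deseasonalize()] or
#'   [baywide_average()] output).
#' @param min_months Minimum matched months for a reported trend.
#' @param months Calendar months to include; use `6:9` for a summer-only
#'   robustness analysis.
#' @return A tibble of class `bay_trends`: one row per series with
#'   `slope` (units/yr), `intercept`, `std_error`, `p_value`, `conf_low`,
#'   `conf_high` (95%), `n_months`, `dw_stat`, `dw_p`. The fitted `lm`
#'   objects are attached as attribute `"models"`.
#' @export
fit_trend <- function(anomalies, min_months = 24, months = 1:12) {
  x <- dplyr::filter(anomalies, .data$month %in% .env$months)
  keys <- intersect(c("station_id", "layer", "parameter"), names(x))
  x <- tidyr::nest(dplyr::group_by(x, dplyr::across(dplyr::all_of(keys))))
  fits <- purrr::map(x$data, function(d) {
    d <- dplyr::arrange(d, .data$year, .data$month)
    if (nrow(d) < min_months) return(NULL)
    t <- .decimal_time(d$year, d$month)
    if (length(unique(t)) < 3) stop("fit_trend(): degenerate time axis")
    fit <- lm(anomaly ~ t, data = data.frame(anomaly = d$anomaly, t = t))
    # degenerate (noise-free) series have zero residual variance and no
    # meaningful autocorrelation test
    dw <- tryCatch(lmtest::dwtest(fit, alternative = "two.sided"),
                   error = function(e) list(statistic = NA_real_,
                                            p.value = NA_real_))
    s <- summary(fit)$coefficients
    ci <- stats::confint(fit, "t", level = 0.95)
    tibble::tibble(
      slope = s["t", "Estimate"], intercept = s["(Intercept)", "Estimate"],
      std_error = s["t", "Std. Error"], p_value = s["t", "Pr(>|t|)"],
      conf_low = ci[1], conf_high = ci[2], n_months = nrow(d),
      dw_stat = unname(dw$statistic), dw_p = dw$p.value,
      model = list(fit), series = list(d)
    )
  })
  keep <- !vapply(fits, is.null, logical(1))
  if (!any(keep)) {
    empty <- tibble::tibble(
      slope = numeric(), intercept = numeric(), std_error = numeric(),
      p_value = numeric(), conf_low = numeric(), conf_high = numeric(),
      n_months = integer(), dw_stat = numeric(), dw_p = numeric()
    )
    out <- dplyr::bind_cols(x[0, keys], empty)
    out <- tibble::new_tibble(out, class = "bay_trends")
    attr(out, "models") <- list()
    attr(out, "series") <- list()
    attr(out, "keys") <- keys
    return(out)
  }
  out <- dplyr::bind_cols(
    dplyr::select(x[keep, ], dplyr::all_of(keys)),
    dplyr::bind_rows(fits[keep])
  )
  models <- out$model
  series <- out$series
  out$model <- NULL
  out$series <- NULL
  out <- tibble::new_tibble(out, class = "bay_trends")
  attr(out, "models") <- models
  attr(out, "series") <- series
  attr(out, "keys") <- keys
  out
}

#' @export
tidy.bay_trends <- function(x, ...) {
  keys <- attr(x, "keys")
  dplyr::select(tibble::as_tibble(x), dplyr::all_of(keys), "slope",
                "std_error", "p_value", "conf_low", "conf_high")
}

#' @export
glance.bay_trends <- function(x, ...) {
  keys <- attr(x, "keys")
  gl <- purrr::map(attr(x, "models"), function(m) {
    s <- summary(m)
    tibble::tibble(r_squared = s$r.squared, sigma = s$sigma,
                   df_residual = s$df[2])
  })
  dplyr::bind_cols(dplyr::select(tibble::as_tibble(x),
                                 dplyr::all_of(keys), "n_months",
                                 "dw_stat", "dw_p"),
                   dplyr::bind_rows(gl))
}

#' Bivariate regressions between bay-wide anomaly series
#'
#' Regresses one parameter's bay-wide monthly anomalies on another's over
#' matched (year, month) pairs, e.g. dissolved oxygen on temperature to
#' estimate the realized oxygen-temperature sensitivity, or pH on oxygen
#' to estimate the biological pH-oxygen coupling.
#'
#' @param anomalies Bay-wide anomaly tibble from [baywide_average()].
#' @param response,predictor Parameter names present in the `parameter`
#'   column.
#' @param layer_mode `"mean-of-layers"` averages the surface and bottom
#'   anomalies before regressing (appropriate when the driving process is
#'   expected to act on the whole water column); `"pooled"` stacks the two
#'   layers as separate points; `"surface"`/`"bottom"` restrict to one
#'   layer.
#' @param min_months Minimum matched pairs.
#' @return A one-row tibble: `response`, `predictor`, `layer_mode`,
#'   `slope`, `intercept`, `std_error`, `p_value`, `r`, `conf_low`,
#'   `conf_high`, `n`.
#' @export
regress_anomalies <- function(anomalies, response, predictor,
                              layer_mode = c("mean-of-layers", "pooled",
                                             "surface", "bottom"),
                              min_months = 24) {
  layer_mode <- match.arg(layer_mode)
  x <- dplyr::filter(anomalies,
                     .data$parameter %in% c(response, predictor))
  x <- switch(layer_mode,
    "mean-of-layers" = dplyr::summarise(
      dplyr::group_by(x, .data$parameter, .data$year, .data$month),
      anomaly = mean(.data$anomaly), .groups = "drop"
    ),
    "pooled" = dplyr::select(x, "layer", "parameter", "year", "month",
                             "anomaly"),
    dplyr::select(dplyr::filter(x, .data$layer == layer_mode),
                  "layer", "parameter", "year", "month", "anomaly")
  )
  wide <- tidyr::pivot_wider(x, names_from = "parameter",
                             values_from = "anomaly")
  wide <- wide[stats::complete.cases(wide[c(response, predictor)]), ]
  if (nrow(wide) < min_months) {
    stop("regress_anomalies(): only ", nrow(wide),
         " matched months; need >= ", min_months)
  }
  fit <- lm(stats::reformulate(predictor, response), data = wide)
  s <- summary(fit)$coefficients
  ci <- stats::confint(fit, predictor, level = 0.95)
  tibble::tibble(
    response = response, predictor = predictor, layer_mode = layer_mode,
    slope = s[predictor, "Estimate"],
    intercept = s["(Intercept)", "Estimate"],
    std_error = s[predictor, "Std. Error"],
    p_value = s[predictor, "Pr(>|t|)"],
    r = sign(s[predictor, "Estimate"]) * sqrt(summary(fit)$r.squared),
    conf_low = ci[1], conf_high = ci[2], n = nrow(wide)
  )
}
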