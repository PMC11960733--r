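# canonical names of the four row-removal parameters; chlorophyll is
# deliberately excluded from screening (no bottom-layer chl exists, so
# filtering on it would bias surface against bottom)
QC_PARAMETERS <- c("temperature", "salinity", "do_umolkg", "ph_nbs")

#' Collapse raw sensor records to daily means
#'
#' Averages all readings of each parameter per (station, layer, calendar
#' date). Dissolved oxygen is converted from mg/L to umol/kg reading by
#' reading (at in-situ temperature and salinity) before averaging, so a
#' day's mean oxygen refers to a fixed water mass. Parameters observed
#' fewer than `min_samples` times on a date are reported absent for that
#' date.
#'
#' @param records Record tibble from [read_sensor_csv()] or
#'   [generate_network()].
#' @param min_samples Minimum readings per parameter per day.
#' @return A tibble with one row per (station, layer, date) and columns
#'   `temperature`, `salinity`, `do_umolkg`, `ph_nbs`, `chl` plus matching
#'   `n_*` sample counts.
#' @export
daily_means <- function(records, min_samples = 1) {
  stopifnot(min_samples >= 1)
  rec <- dplyr::mutate(
    records,
    date = as.Date(.data$timestamp),
    do_umolkg = do_mgL_to_umolkg(.data$do_mgL, .data$temperature,
                                 .data$salinity)
  )
  params <- c(QC_PARAMETERS, "chl")
  key <- paste(rec$station_id, rec$layer, rec$date, sep = "\r")
  # one rowsum() pass per day-group is far faster than per-group summarise
  vals <- as.matrix(rec[params])
  present <- !is.na(vals)
  vals[!present] <- 0
  sums <- rowsum(vals, key, reorder = TRUE)
  counts <- rowsum(present + 0, key, reorder = TRUE)
  means <- sums / counts
  means[counts < min_samples] <- NA_real_
  first <- rec[!duplicated(key), c("station_id", "layer", "date")]
  first <- first[order(paste(first$station_id, first$layer, first$date,
                             sep = "\r")), ]
  out <- tibble::as_tibble(first)
  for (p in params) out[[p]] <- unname(means[, p])
  for (p in params) {
    n <- as.integer(counts[, p])
    n[n == 0] <- NA_integer_
    out[[paste0("n_", p)]] <- n
  }
  dplyr::arrange(out, .data$station_id, .data$layer, .data$date)
}

#' Interquartile-range outlier fences
#'
#' Tukey fences for a sample: values below `Q1 - 1.5 IQR` or above
#' `Q3 + 1.5 IQR` are outliers. Quartiles use linear interpolation of
#' order statistics (`stats::quantile()` type 7 by default; configurable
#' since published analyses rarely state the estimator).
#'
#' @param values Numeric vector; at least 4 finite values required.
#' @param type Quantile estimator type passed to [stats::quantile()].
#' @return A one-row tibble with `q1`, `q3`, `iqr`, `lower`, `upper`, `n`.
#' @examples
#' iqr_fences(c(2, 4, 4, 5, 5, 5, 6, 6, 20))
#' @export
iqr_fences <- function(values, type = 7) {
  v <- values[is.finite(values)]
  if (length(v) < 4) {
    stop("iqr_fences(): need at least 4 finite values, got ", length(v))
  }
  q <- quantile(v, c(0.25, 0.75), type = type, names = FALSE)
  iqr <- q[2] - q[1]
  tibble::tibble(q1 = q[1], q3 = q[2], iqr = iqr,
                 lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr,
                 n = length(v))
}

#' Iterative row-wise outlier removal
#'
#' Applies the IQR fence rule per station, layer and parameter over the
#' full daily series and removes the entire day (all parameters) whenever
#' any one of `parameters` is flagged; fences are then recomputed on the
#' reduced data and the process repeats until no day is flagged. Episodic
#' extremes (storm salinity drops, bloom oxygen spikes, hypoxic events)
#' would otherwise skew mean-state analyses. Chlorophyll is never screened
#' and never causes removal. Days missing a screened parameter are simply
#' not tested on it.
#'
#' @param daily Daily-mean tibble from [daily_means()].
#' @param parameters Which parameters trigger removal; a subset of
#'   `temperature`, `salinity`, `do_umolkg`, `ph_nbs`.
#' @param max_iter Safety cap on cascade passes.
#' @param type Quantile estimator, see [iqr_fences()].
#' @return A list with `daily` (the clean fixed-point tibble) and `report`
#'   (class `qaqc_report`): final per-group fences, every removed day with
#'   its triggering parameter(s) and iteration, the iteration count, and
#'   the overall removed fraction.
#' @export
remove_outliers_cascade <- function(daily, parameters = QC_PARAMETERS,
                                    max_iter = 50, type = 7) {
  stopifnot(all(parameters %in% QC_PARAMETERS))
  n0 <- nrow(daily)
  removed <- list()
  iter <- 0L
  repeat {
    flags <- .flag_outlier_days(daily, parameters, type)
    if (nrow(flags) == 0) break
    iter <- iter + 1L
    if (iter > max_iter) {
      rlang::abort(
        paste0("outlier cascade did not converge in ", max_iter, " passes"),
        class = "baywater_cascade_error",
        partial_report = .qaqc_report(daily, parameters, removed, iter - 1L,
                                      n0, type)
      )
    }
    flags$iteration <- iter
    removed[[iter]] <- flags
    drop_keys <- dplyr::distinct(flags, .data$station_id, .data$layer,
                                 .data$date)
    daily <- dplyr::anti_join(daily, drop_keys,
                              by = c("station_id", "layer", "date"))
  }
  list(daily = daily,
       report = .qaqc_report(daily, parameters, removed, iter, n0, type))
}

# one screening pass: returns flagged (station, layer, date, parameter, value)
.flag_outlier_days <- function(daily, parameters, type) {
  long <- tidyr::pivot_longer(
    dplyr::select(daily, "station_id", "layer", "date",
                  dplyr::all_of(parameters)),
    cols = dplyr::all_of(parameters),
    names_to = "parameter", values_to = "value"
  )
  long <- dplyr::filter(long, is.finite(.data$value))
  grp <- dplyr::group_by(long, .data$station_id, .data$layer,
                         .data$parameter)
  grp <- dplyr::filter(grp, dplyr::n() >= 4)
  grp <- dplyr::mutate(
    grp,
    q1 = quantile(.data$value, 0.25, type = .env$type, names = FALSE),
    q3 = quantile(.data$value, 0.75, type = .env$type, names = FALSE)
  )
  out <- dplyr::ungroup(dplyr::filter(
    grp,
    .data$value < .data$q1 - 1.5 * (.data$q3 - .data$q1) |
      .data$value > .data$q3 + 1.5 * (.data$q3 - .data$q1)
  ))
  dplyr::select(out, "station_id", "layer", "date", "parameter", "value")
}

.qaqc_report <- function(clean, parameters, removed, iterations, n0, type) {
  removed <- if (length(removed)) dplyr::bind_rows(removed) else
    tibble::tibble(station_id = character(), layer = character(),
                   date = as.Date(character()), parameter = character(),
                   value = numeric(), iteration = integer())
  long <- tidyr::pivot_longer(
    dplyr::select(clean, "station_id", "layer", "date",
                  dplyr::all_of(parameters)),
    cols = dplyr::all_of(parameters),
    names_to = "parameter", values_to = "value"
  )
  long <- dplyr::filter(long, is.finite(.data$value))
  grp <- dplyr::group_by(long, .data$station_id, .data$layer,
                         .data$parameter)
  fences <- dplyr::summarise(
    dplyr::filter(grp, dplyr::n() >= 4),
    iqr_fences(.data$value, type = .env$type), .groups = "drop"
  )
  n_removed <- nrow(dplyr::distinct(removed, .data$station_id, .data$layer,
                                    .data$date))
  structure(
    list(fences = fences, removed = removed, n_iterations = iterations,
         n_days_in = n0, n_days_removed = n_removed,
         removed_fraction = if (n0 > 0) n_removed / n0 else 0,
         parameters = parameters, quantile_type = type),
    class = "qaqc_report"
  )
}

#' @export
print.qaqc_report <- function(x, ...) {
  cat("<qaqc_report>\n")
  cat(sprintf("  %d of %d days removed (%.1f%%) in %d pass(es)\n",
              x$n_days_removed, x$n_days_in, 100 * x$removed_fraction,
              x$n_iterations))
  cat("  screened parameters:", paste(x$parameters, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a QA/QC report to JSON
#'
#' @param report A `qaqc_report` from [remove_outliers_cascade()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qaqc_report <- function(report, path) {
  stopifnot(inherits(report, "qaqc_report"))
  out <- report
  out$removed$date <- as.character(out$removed$date)
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Monthly means of clean daily data
#'
#' Arithmetic means per (station, layer, year, month, parameter) of the
#' daily means that survived QA/QC. Months with no surviving days are
#' absent rather than reported as `NA`.
#'
#' @param daily Clean daily tibble (the `daily` element of
#'   [remove_outliers_cascade()] output, or any [daily_means()] result).
#' @return A long tibble with columns `station_id`, `layer`, `year`,
#'   `month`, `parameter`, `value`, `n_days`.
#' @export
monthly_means <- function(daily) {
  long <- tidyr::pivot_longer(
    dplyr::select(daily, "station_id", "layer", "date",
                  dplyr::all_of(c(QC_PARAMETERS, "chl"))),
    cols = dplyr::all_of(c(QC_PARAMETERS, "chl")),
    names_to = "parameter", values_to = "value"
  )
  long <- dplyr::filter(long, !is.na(.data$value))
  long$year <- as.integer(format(long$date, "%Y"))
  long$month <- as.integer(format(long$date, "%m"))
  dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(long, .data$station_id, .data$layer, .data$year,
                      .data$month, .data$parameter),
      value = mean(.data$value), n_days = dplyr::n(), .groups = "drop"
    ),
    .data$station_id, .data$layer, .data$year, .data$month, .data$parameter
  )
}
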