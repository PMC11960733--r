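#' Read a sensor time-series CSV into a tidy record table
#'
#' Reads one-row-per-reading delimited text as produced by fixed-site
#' monitoring networks (and by [generate_network()]). Column names are
#' configurable through `column_map`; blank fields are missing values. Rows
#' whose required fields fail to parse or fall outside physical ranges
#' (salinity outside [0, 40], temperature outside [-3, 40] C, negative DO,
#' pH outside [5, 10]) are rejected and counted, never silently dropped;
#' duplicated (station, layer, timestamp) keys keep the first occurrence
#' with a warning. Chlorophyll may be absent (bottom layers) and an empty
#' chl field is kept as `NA`, which is distinct from a measured zero.
#'
#' @param path Path to the CSV file.
#' @param column_map Named character vector mapping the canonical names
#'   `station_id`, `timestamp`, `layer`, `temperature`, `salinity`,
#'   `do_mgL`, `ph_nbs`, `chl`, `depth` to the file's column names.
#'   Defaults to identity. `chl` and `depth` are optional.
#' @param tz Timezone used to parse timestamps; the network convention is
#'   local wall-clock time, so the default is `"UTC"` used as a fixed local
#'   clock.
#' @return A tibble of records ordered by station, layer and timestamp,
#'   with an `ingest_report` attribute (see [ingest_report()]).
#' @export
read_sensor_csv <- function(path, column_map = NULL, tz = "UTC") {
  stopifnot(file.exists(path))
  canon <- c("station_id", "timestamp", "layer", "temperature", "salinity",
             "do_mgL", "ph_nbs", "chl", "depth")
  map <- setNames(canon, canon)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- map[c("station_id", "timestamp", "layer", "temperature",
                    "salinity", "do_mgL", "ph_nbs")]
  missing_cols <- setdiff(unname(required), names(raw))
  if (length(missing_cols) > 0) {
    stop("read_sensor_csv(): required column(s) not in file: ",
         paste(missing_cols, collapse = ", "))
  }
  n_total <- nrow(raw)
  if (n_total == 0) {
    empty <- tibble::tibble(
      station_id = character(), timestamp = as.POSIXct(character(), tz = tz),
      layer = character(), temperature = numeric(), salinity = numeric(),
      do_mgL = numeric(), ph_nbs = numeric(), chl = numeric(),
      depth = numeric()
    )
    attr(empty, "ingest_report") <- list(n_rows = 0L, n_records = 0L,
                                         n_rejected = 0L, n_duplicates = 0L)
    return(empty)
  }

  num <- function(col) {
    if (col %in% names(raw)) suppressWarnings(as.numeric(raw[[col]]))
    else rep(NA_real_, n_total)
  }
  rec <- tibble::tibble(
    station_id = raw[[map[["station_id"]]]],
    timestamp = as.POSIXct(raw[[map[["timestamp"]]]], tz = tz,
                           tryFormats = c("%Y-%m-%d %H:%M:%OS",
                                          "%Y-%m-%dT%H:%M:%OS",
                                          "%Y-%m-%d %H:%M", "%Y-%m-%d")),
    layer = tolower(raw[[map[["layer"]]]]),
    temperature = num(map[["temperature"]]),
    salinity = num(map[["salinity"]]),
    do_mgL = num(map[["do_mgL"]]),
    ph_nbs = num(map[["ph_nbs"]]),
    chl = num(map[["chl"]]),
    depth = num(map[["depth"]])
  )

  # a row is rejected when a required field is unparseable or out of range;
  # chl never causes rejection (absent is legitimate)
  bad <- is.na(rec$station_id) | is.na(rec$timestamp) |
    !rec$layer %in% c("surface", "bottom") |
    (!is.na(rec$salinity) & (rec$salinity < 0 | rec$salinity > 40)) |
    (!is.na(rec$temperature) & (rec$temperature < -3 | rec$temperature > 40)) |
    (!is.na(rec$do_mgL) & rec$do_mgL < 0) |
    (!is.na(rec$ph_nbs) & (rec$ph_nbs < 5 | rec$ph_nbs > 10))
  # required numeric fields that failed to parse (raw non-blank, parsed NA)
  for (f in c("temperature", "salinity", "do_mgL", "ph_nbs")) {
    src <- raw[[map[[f]]]]
    bad <- bad | (!is.na(src) & src != "" & is.na(rec[[f]]))
  }
  rejected <- sum(bad)
  rec <- rec[!bad, ]
  rec <- dplyr::arrange(rec, .data$station_id, .data$layer, .data$timestamp)
  dup <- duplicated(rec[c("station_id", "layer", "timestamp")])
  if (any(dup)) {
    warning("read_sensor_csv(): ", sum(dup),
            " duplicated (station, layer, timestamp) row(s); keeping first")
    rec <- rec[!dup, ]
  }
  if (rejected > 0) {
    message("read_sensor_csv(): rejected ", rejected, " of ", n_total,
            " data row(s)")
  }
  attr(rec, "ingest_report") <- list(
    n_rows = n_total, n_records = nrow(rec),
    n_rejected = as.integer(rejected), n_duplicates = as.integer(sum(dup))
  )
  rec
}

#' Ingest report of a record table
#'
#' @param records A tibble returned by [read_sensor_csv()].
#' @return A list with `n_rows`, `n_records`, `n_rejected`, `n_duplicates`.
#' @export
ingest_report <- function(records) {
  attr(records, "ingest_report")
}

#' Write and read monthly-mean tables
#'
#' Monthly tables are long-format CSVs with columns `station_id`, `layer`,
#' `year`, `month`, `parameter`, `value`, `n_days`, sorted by (station,
#' layer, year, month, parameter). Values round-trip to 6 significant
#' digits; absent values (e.g. chlorophyll in bottom layers) are written as
#' blank fields and read back as `NA`.
#'
#' @param monthly A monthly table as produced by [monthly_means()].
#' @param path Output path.
#' @return `write_monthly_table()` returns `path` invisibly;
#'   `read_monthly_table()` returns the tibble.
#' @export
write_monthly_table <- function(monthly, path) {
  stopifnot(nrow(monthly) > 0)
  out <- dplyr::arrange(monthly, .data$station_id, .data$layer, .data$year,
                        .data$month, .data$parameter)
  out$value <- signif(out$value, 6)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_monthly_table
#' @export
read_monthly_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    station_id = "c", layer = "c", year = "i", month = "i",
    parameter = "c", value = "d", n_days = "i"
  ), progress = FALSE)
}
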