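# shared fixtures, built in code at test time

# cache expensive objects across test files within one run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# full 15-year NB-like prepared network (deterministic; seed-independent)
nb_prepared <- function() cached("nb_prepared", prepare_network(nb_profile()))

# a small two-year network realization for structural tests
small_network <- function(seed = 5) {
  cached(paste0("small_net_", seed),
         generate_network(nb_profile(years = 2005:2007), seed = seed))
}

# hand-built raw records: one station/layer, `n_days` days with `per_day`
# readings; any record column can be overridden with a constant or a
# per-reading vector
make_records <- function(n_days = 3, per_day = 1, station = "AA",
                         layer = "surface", start = "2011-06-01", ...) {
  n <- n_days * per_day
  dates <- rep(seq(as.Date(start), by = "day", length.out = n_days),
               each = per_day)
  hour <- rep(seq_len(per_day) * (24 / (per_day + 1)), times = n_days)
  chl_default <- if (identical(layer, "surface")) 5 else NA_real_
  rec <- tibble::tibble(
    station_id = station,
    timestamp = as.POSIXct(dates, tz = "UTC") + hour * 3600,
    layer = layer,
    temperature = 15, salinity = 30,
    do_mgL = 8, ph_nbs = 8,
    chl = chl_default
  )
  for (nm in names(list(...))) rec[[nm]] <- list(...)[[nm]]
  rec
}

# a daily table with a single parameter series per station/layer
make_daily <- function(values, station = "AA", layer = "surface",
                       parameter = "salinity", start = "2011-06-01") {
  n <- length(values)
  d <- tibble::tibble(
    station_id = station, layer = layer,
    date = seq(as.Date(start), by = "day", length.out = n),
    temperature = 15, salinity = 30, do_umolkg = 250, ph_nbs = 8,
    chl = NA_real_
  )
  d[[parameter]] <- values
  d
}

# long monthly table for one station/layer/parameter
make_monthly <- function(values_by_year_month, station = "AA",
                         layer = "surface", parameter = "ph_nbs") {
  tibble::tibble(
    station_id = station, layer = layer,
    year = values_by_year_month$year, month = values_by_year_month$month,
    parameter = parameter, value = values_by_year_month$value,
    n_days = 28L
  )
}

# path to the independent python reference carbonate calculator
reference_script <- function() {
  system.file("reference", "carb_reference.py", package = "baywater")
}

# run the python reference on a grid of (temperature, salinity, ta, dic)
reference_carb <- function(grid) {
  tmp <- tempfile(fileext = ".csv")
  readr::write_csv(grid[c("temperature", "salinity", "ta", "dic")], tmp)
  out <- system2("python", reference_script(), stdout = TRUE,
                 stdin = tmp)
  readr::read_csv(I(paste(out, collapse = "\n")),
                  col_types = readr::cols(.default = "d"), progress = FALSE)
}
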