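# Delimited-text formats, station QC, and profile/config serialization.
# Canonical units are enforced at read time: dates ISO-8601, temperatures
# degC, wind m/s, irradiance W/m2. The missing-value sentinel is the empty
# field; legacy numeric sentinels can be translated at ingestion.

.obs_cols <- c("station_id", "date", "tmax", "td_mean", "wind_mean",
               "srad_max")
.hc_cols <- c("station_id", "init_date", "lead", "valid_date", "member",
              "variable", "value")

.parse_numeric <- function(x, rows, what, sentinels = NULL) {
  x[x == ""] <- NA_character_
  if (!is.null(sentinels)) x[x %in% as.character(sentinels)] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop(sprintf("malformed %s value(s) at line(s): %s", what,
                 paste(rows[bad], collapse = ", ")))
  out
}

.parse_date <- function(x, rows, what) {
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad))
    stop(sprintf("malformed %s date(s) at line(s): %s", what,
                 paste(rows[bad], collapse = ", ")))
  out
}

#' Write an observation archive to CSV
#'
#' @param obs archive `data.frame` (see [generate_observations()]).
#' @param path output file; missing values become empty fields.
#' @return `path`, invisibly.
#' @export
write_observation_archive <- function(obs, path) {
  stopifnot(all(.obs_cols %in% names(obs)))
  fwrite(as.data.table(obs)[, .obs_cols, with = FALSE], path, na = "")
  invisible(path)
}

#' Read an observation archive from CSV
#'
#' Columns `station_id, date, tmax, td_mean, wind_mean, srad_max`; empty
#' cells are missing values (never zero). Rows are sorted by station and
#' date; malformed rows are reported with their line numbers.
#'
#' @param path CSV file.
#' @param sentinels optional legacy missing-value sentinels (e.g. -999) to
#'   translate to missing at ingestion.
#' @return the archive `data.frame`.
#' @export
read_observation_archive <- function(path, sentinels = NULL) {
  raw <- fread(path, colClasses = "character", na.strings = NULL)
  miss <- setdiff(.obs_cols, names(raw))
  if (length(miss))
    stop("observation archive missing column(s): ",
         paste(miss, collapse = ", "))
  rows <- seq_len(nrow(raw)) + 1L  # header is line 1
  out <- data.frame(
    station_id = raw$station_id,
    date = .parse_date(raw$date, rows, "observation"),
    tmax = .parse_numeric(raw$tmax, rows, "tmax", sentinels),
    td_mean = .parse_numeric(raw$td_mean, rows, "td_mean", sentinels),
    wind_mean = .parse_numeric(raw$wind_mean, rows, "wind_mean", sentinels),
    srad_max = .parse_numeric(raw$srad_max, rows, "srad_max", sentinels),
    stringsAsFactors = FALSE)
  if (anyNA(out$date)) {
    bad <- rows[is.na(out$date)]
    stop("missing observation date at line(s): ", paste(bad, collapse = ", "))
  }
  out <- out[order(out$station_id, out$date), ]
  rownames(out) <- NULL
  out
}

#' Write a forecast/hindcast table to CSV
#'
#' @param fc long table (see [generate_hindcast()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hindcast <- function(fc, path) {
  stopifnot(all(.hc_cols %in% names(fc)))
  fwrite(as.data.table(fc)[, .hc_cols, with = FALSE], path, na = "")
  invisible(path)
}

#' Read a forecast/hindcast table from CSV
#'
#' @param path CSV file written by [write_hindcast()].
#' @return the long forecast `data.frame`.
#' @export
read_hindcast <- function(path) {
  raw <- fread(path, colClasses = "character", na.strings = NULL)
  miss <- setdiff(.hc_cols, names(raw))
  if (length(miss))
    stop("forecast table missing column(s): ", paste(miss, collapse = ", "))
  rows <- seq_len(nrow(raw)) + 1L
  out <- data.frame(
    station_id = raw$station_id,
    init_date = .parse_date(raw$init_date, rows, "init"),
    lead = as.integer(.parse_numeric(raw$lead, rows, "lead")),
    valid_date = .parse_date(raw$valid_date, rows, "valid"),
    member = as.integer(.parse_numeric(raw$member, rows, "member")),
    variable = raw$variable,
    value = .parse_numeric(raw$value, rows, "value"),
    stringsAsFactors = FALSE)
  out
}

#' Write a station network to CSV
#' @param stations network `data.frame`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stations <- function(stations, path) {
  fwrite(as.data.table(stations), path, na = "")
  invisible(path)
}

#' Read a station network from CSV
#' @param path CSV with columns `id, name, lat, lon, altitude, source`.
#' @return the network `data.frame`.
#' @export
read_stations <- function(path) {
  st <- as.data.frame(fread(path))
  need <- c("id", "lat", "lon", "altitude")
  miss <- setdiff(need, names(st))
  if (length(miss))
    stop("station table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(st$id)) stop("duplicate station ids")
  if (any(st$lat < -90 | st$lat > 90) || any(st$lon < -180 | st$lon > 180))
    stop("station coordinates out of range")
  st
}

#' Quality-control filter on station missingness
#'
#' Drops stations whose fraction of missing observation cells (over the
#' four variables, within the evaluation period) strictly exceeds
#' `max_missing`; a station at exactly the threshold is retained.
#'
#' @param obs observation archive.
#' @param max_missing maximum tolerated missing fraction, default 0.20.
#' @param period optional `c(start, end)` dates of the evaluation period;
#'   default the full archive span.
#' @return a list: `archive` (surviving rows) and `report` (per-station
#'   `n_days`, `missing_fraction`, `dropped`).
#' @export
qc_filter_stations <- function(obs, max_missing = 0.20, period = NULL) {
  if (is.null(obs) || nrow(obs) == 0) stop("empty observation archive")
  dt <- as.data.table(obs)
  if (!is.null(period)) {
    period <- as.Date(period)
    dt <- dt[date >= period[1] & date <= period[2]]
    if (nrow(dt) == 0) stop("no observations in the evaluation period")
  }
  vars <- c("tmax", "td_mean", "wind_mean", "srad_max")
  rep_dt <- dt[, .(n_days = .N,
                   missing_fraction =
                     sum(is.na(.SD)) / (.N * length(vars))),
               by = station_id, .SDcols = vars]
  rep_dt[, dropped := missing_fraction > max_missing]
  keep <- rep_dt$station_id[!rep_dt$dropped]
  list(archive = as.data.frame(dt[station_id %in% keep]),
       report = as.data.frame(rep_dt))
}

#' Write a worker profile to JSON
#'
#' @param profile a [worker_profile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_worker_profile <- function(profile, path) {
  stopifnot(inherits(profile, "worker_profile"))
  payload <- list(format = "heatwarn-worker-profile", version = 1L,
                  height = profile$height, weight = profile$weight,
                  iso_level = profile$iso_level,
                  environment = profile$environment,
                  clothing_key = profile$clothing_key,
                  station_id = profile$station_id,
                  cav_table = as.list(profile$cav_table),
                  collapse_quantile = profile$collapse_quantile,
                  acclimatized = profile$acclimatized,
                  exposure_days = profile$exposure_days)
  if (!is.na(profile$last_qualifying))
    payload$last_qualifying <- format(profile$last_qualifying)
  if (!is.na(profile$last_date))
    payload$last_date <- format(profile$last_date)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a worker profile from JSON
#'
#' @param path file written by [write_worker_profile()].
#' @return a [worker_profile()].
#' @export
read_worker_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "heatwarn-worker-profile"))
    stop("not a worker profile file: ", path)
  p <- worker_profile(height = x$height, weight = x$weight,
                      activity = as.integer(x$iso_level),
                      environment = x$environment,
                      clothing_key = x$clothing_key,
                      station_id = if (is.null(x$station_id)) NA_character_
                                   else x$station_id,
                      cav_table = unlist(x$cav_table),
                      collapse_quantile = x$collapse_quantile)
  p$acclimatized <- isTRUE(x$acclimatized)
  p$exposure_days <- as.integer(x$exposure_days)
  if (!is.null(x$last_qualifying))
    p$last_qualifying <- as.Date(x$last_qualifying)
  if (!is.null(x$last_date)) p$last_date <- as.Date(x$last_date)
  p
}
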