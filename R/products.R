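# Forecast products: daily/weekly exceedance probabilities, short-term
# (5-day) personalized risk with alert triggering, the 6-46-day long-term
# calendar, and the nearest-station lookup.

#' Ensemble exceedance probability
#'
#' Fraction of members strictly above the threshold (ties at the threshold
#' do not count as exceedances).
#'
#' @param members member values.
#' @param threshold threshold in the members' units.
#' @return probability in `[0, 1]`.
#' @export
exceedance_probability <- function(members, threshold) {
  members <- members[is.finite(members)]
  if (length(members) == 0) stop("empty ensemble")
  mean(members > threshold)
}

# first Monday on or after a date
.next_monday <- function(date) {
  wd <- as.POSIXlt(date)$wday  # 0 = Sunday
  date + (8 - ifelse(wd == 0, 8, wd)) %% 7
}

#' Weekly maximum exceedance-probability product
#'
#' For each of the upcoming Monday-to-Sunday weeks, the maximum daily
#' probability of exceeding the WBGT threshold within the week. Weeks are
#' anchored to the first Monday on or after the init date; leading days
#' before that Monday are not part of the four-week product.
#'
#' @param wbgt_fc member WBGT table with columns `station_id`,
#'   `valid_date`, `member` and the exposure column (`wbgt_sun` or
#'   `wbgt_shade`).
#' @param init_date forecast initialization date.
#' @param threshold WBGT threshold, degC; the operational default is 27 on
#'   sun exposure.
#' @param exposure `"sun"` or `"shade"`.
#' @param n_weeks number of upcoming weeks, default 4.
#' @return a `data.frame` with one row per station and week: `station_id`,
#'   `week`, `week_start`, `week_end`, `probability`, `threshold`,
#'   `exposure`.
#' @export
weekly_exceedance <- function(wbgt_fc, init_date, threshold = 27,
                              exposure = c("sun", "shade"), n_weeks = 4L) {
  exposure <- match.arg(exposure)
  col <- paste0("wbgt_", exposure)
  if (!col %in% names(wbgt_fc)) stop("missing column: ", col)
  init_date <- as.Date(init_date)
  anchor <- .next_monday(init_date)
  dt <- as.data.table(wbgt_fc)
  dt <- dt[is.finite(dt[[col]])]
  daily <- dt[, .(probability = mean(.SD[[1]] > threshold)),
              by = .(station_id, valid_date), .SDcols = col]
  out <- list()
  for (w in seq_len(n_weeks)) {
    ws <- anchor + 7 * (w - 1)
    we <- ws + 6
    sub <- daily[valid_date >= ws & valid_date <= we]
    if (nrow(sub) == 0)
      stop(sprintf("no forecast days in week %d (%s to %s)", w, ws, we))
    agg <- sub[, .(probability = max(probability)), by = station_id]
    out[[w]] <- data.frame(station_id = agg$station_id, week = w,
                           week_start = ws, week_end = we,
                           probability = agg$probability,
                           threshold = threshold, exposure = exposure,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$station_id, res$week), ]
  rownames(res) <- NULL
  res
}

# member WBGT values per valid date for one station/exposure
.member_wbgt_by_day <- function(wbgt_fc, station, exposure, dates) {
  col <- paste0("wbgt_", exposure)
  dt <- as.data.table(wbgt_fc)
  if ("station_id" %in% names(dt)) dt <- dt[station_id == station]
  lapply(dates, function(d) dt[valid_date == d][[col]])
}

#' Short-term (5-day) personalized risk
#'
#' One risk assessment per day for the first `n_days` forecast days, the
#' acclimatization state updated in date order, plus the alert record.
#'
#' @param profile a [worker_profile()].
#' @param wbgt_fc member WBGT table (`station_id`, `valid_date`, `member`,
#'   `wbgt_sun`, `wbgt_shade`).
#' @param init_date forecast initialization date; days 1..`n_days` are
#'   `init_date + 1 ...`.
#' @param n_days short-term horizon, default 5.
#' @return a list: `assessments` (one dated row per day), `profile` (the
#'   updated profile), `alert` (see [alert_check()]).
#' @export
short_term_risk <- function(profile, wbgt_fc, init_date, n_days = 5L) {
  stopifnot(inherits(profile, "worker_profile"))
  init_date <- as.Date(init_date)
  days <- init_date + seq_len(n_days)
  station <- if (is.na(profile$station_id) ||
                 !"station_id" %in% names(wbgt_fc)) NULL else profile$station_id
  dt <- as.data.table(wbgt_fc)
  if (!is.null(station)) dt <- dt[station_id == station]
  col <- paste0("wbgt_", profile$environment)
  rows <- list()
  for (i in seq_along(days)) {
    members <- dt[valid_date == days[i]][[col]]
    members <- members[is.finite(members)]
    if (length(members) == 0)
      stop("forecast does not cover day ", format(days[i]))
    a <- assess_day(profile, members, days[i])
    profile <- update_acclimatization(profile, a)
    rows[[i]] <- a
  }
  assessments <- do.call(rbind, rows)
  list(assessments = assessments, profile = profile,
       alert = alert_check(assessments))
}

#' Long-term risk calendar (days 6-46)
#'
#' Banded daily risk for planning, computed like [assess_day()] with the
#' worker's current acclimatization state (the long-range calendar is a
#' planning product and does not advance the state machine).
#'
#' @inheritParams short_term_risk
#' @param days lead days to cover, default 6:46.
#' @return a `data.frame` with one row per day: `date`, `lead`,
#'   `wbgt_eff`, `risk_pct`, `band`.
#' @export
long_term_calendar <- function(profile, wbgt_fc, init_date, days = 6:46) {
  stopifnot(inherits(profile, "worker_profile"))
  init_date <- as.Date(init_date)
  dt <- as.data.table(wbgt_fc)
  if (!is.na(profile$station_id) && "station_id" %in% names(dt))
    dt <- dt[station_id == profile$station_id]
  col <- paste0("wbgt_", profile$environment)
  rows <- lapply(days, function(l) {
    d <- init_date + l
    members <- dt[valid_date == d][[col]]
    members <- members[is.finite(members)]
    if (length(members) == 0)
      stop("forecast does not cover lead day ", l)
    a <- assess_day(profile, members, d)
    data.frame(date = d, lead = l, wbgt_eff = a$wbgt_eff,
               risk_pct = a$risk_pct, band = a$band,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Alert check over short-term assessments
#'
#' An alert fires when at least one short-term day reaches at least the
#' moderate band. Message rendering only; no transport.
#'
#' @param assessments rows from [assess_day()] for the short-term days.
#' @return `NULL` when no alert; otherwise a list with `dates` (the
#'   qualifying days), `worst_band` and `message`.
#' @export
alert_check <- function(assessments) {
  ranks <- .band_rank(assessments$band)
  hit <- ranks >= .band_rank("moderate")
  if (!any(hit)) return(NULL)
  worst <- .risk_bands[max(ranks)]
  dates <- as.Date(assessments$date[hit])
  list(dates = dates, worst_band = worst,
       message = sprintf(
         "Heat warning: %s heat stress risk expected on %s.",
         gsub("_", " ", worst),
         paste(format(dates), collapse = ", ")))
}

#' Nearest station with similar altitude
#'
#' Minimizes the great-circle distance plus an altitude penalty (by default
#' 1 km of horizontal distance per 100 m of altitude difference); ties are
#' broken by station id.
#'
#' @param lat,lon query coordinates, degrees.
#' @param altitude query altitude, m.
#' @param network station network (`id`, `lat`, `lon`, `altitude`).
#' @param alt_penalty km of equivalent horizontal distance per m of
#'   altitude difference (default 1/100).
#' @return the selected station id.
#' @export
nearest_station <- function(lat, lon, altitude, network,
                            alt_penalty = 1 / 100) {
  if (is.null(network) || nrow(network) == 0) stop("empty station network")
  dist_km <- geosphere::distHaversine(
    c(lon, lat), cbind(network$lon, network$lat)) / 1000
  score <- dist_km + abs(network$altitude - altitude) * alt_penalty
  network$id[order(score, network$id)][1]
}
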