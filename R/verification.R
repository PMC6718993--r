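# Probabilistic forecast verification: ensemble CRPS (kernel form), the
# climatological pseudo-ensemble reference, skill scores, and aggregation
# into the weekly lead bins used for reporting (week 1 = lead days 5-11,
# week 2 = 12-18, week 3 = 19-25, week 4 = 26-32).

.verif_weeks <- data.frame(week = 1:4,
                           lead_min = c(5L, 12L, 19L, 26L),
                           lead_max = c(11L, 18L, 25L, 32L))

#' Continuous ranked probability score of an ensemble forecast
#'
#' Kernel form `mean(|x_i - y|) - 0.5 * mean(|x_i - x_j|)` over members
#' `x_i` and observation `y`; the ensemble generalization of the mean
#' absolute error (a single-member ensemble scores exactly `|x - y|`).
#'
#' @param members ensemble member values.
#' @param obs the verifying observation.
#' @return the CRPS (same units as the members), non-negative.
#' @examples
#' crps_ensemble(c(1, 3), 2)  # 0.5
#' @export
crps_ensemble <- function(members, obs) {
  members <- members[is.finite(members)]
  if (length(members) == 0) stop("empty ensemble")
  if (!is.finite(obs)) stop("observation must be finite")
  mean(abs(members - obs)) -
    0.5 * mean(abs(outer(members, members, "-")))
}

#' Climatological pseudo-ensemble for a date
#'
#' One member per archive year: the observed value at the same calendar day
#' (within a +/- `window`-day tolerance, the value closest to the target
#' calendar day that is not missing). With a 20-year archive this mimics a
#' 20-member climatological forecast.
#'
#' @param archive daily series for one station: columns `date` and the
#'   value column named by `variable`.
#' @param date target date.
#' @param variable value column name.
#' @param n_years members required (most recent years used), default 20.
#' @param window calendar-day tolerance, days.
#' @return numeric vector of `n_years` members.
#' @export
climatological_reference <- function(archive, date, variable = "tmax",
                                     n_years = 20L, window = 7L) {
  if (!variable %in% names(archive)) stop("missing column: ", variable)
  date <- as.Date(date)
  doy_target <- as.POSIXlt(date)$yday
  lt <- as.POSIXlt(archive$date)
  doy <- lt$yday
  # circular calendar distance
  delta <- abs(doy - doy_target)
  delta <- pmin(delta, 365 - delta)
  ok <- delta <= window & is.finite(archive[[variable]])
  cand <- data.frame(year = lt$year[ok] + 1900L, delta = delta[ok],
                     value = archive[[variable]][ok])
  if (nrow(cand) == 0) stop("insufficient archive for climatological reference")
  cand <- cand[order(cand$year, cand$delta), ]
  per_year <- cand[!duplicated(cand$year), ]
  if (nrow(per_year) < n_years)
    stop(sprintf("insufficient archive: %d year(s) available, %d required",
                 nrow(per_year), n_years))
  tail(per_year, n_years)$value
}

#' Continuous ranked probability skill score
#'
#' `1 - crps_fc / crps_ref`: 1 for a perfect forecast, 0 when the forecast
#' matches the reference, negative when it is worse.
#'
#' @param crps_fc forecast CRPS (>= 0).
#' @param crps_ref reference CRPS (> 0).
#' @return the skill score (<= 1).
#' @export
crpss <- function(crps_fc, crps_ref) {
  if (any(crps_ref <= 0))
    stop("reference CRPS must be positive for a skill score")
  1 - crps_fc / crps_ref
}

#' Daily CRPS table for a member forecast against observations
#'
#' @param fc long member table with `station_id`, `init_date`, `lead`,
#'   `valid_date`, `member` and the value column `col`.
#' @param obs observed daily values: `station_id`, `date` and the column
#'   `obs_col`.
#' @param col forecast value column, e.g. `"wbgt_shade"`.
#' @param obs_col observation column; defaults to `col`.
#' @return a `data.frame` with one row per (station, init, lead):
#'   `station_id`, `init_date`, `lead`, `valid_date`, `crps`.
#' @export
daily_crps <- function(fc, obs, col, obs_col = col) {
  dt <- as.data.table(fc)
  ob <- as.data.table(obs)
  ob <- ob[, .(station_id, date, obs_value = ob[[obs_col]])]
  dt <- merge(dt, ob, by.x = c("station_id", "valid_date"),
              by.y = c("station_id", "date"), all.x = TRUE)
  dt <- dt[is.finite(obs_value) & is.finite(dt[[col]])]
  res <- dt[, .(crps = crps_ensemble(.SD[[1]], obs_value[1]),
                valid_date = valid_date[1]),
            by = .(station_id, init_date, lead), .SDcols = col]
  as.data.frame(res)
}

#' Weekly skill records from daily CRPS values
#'
#' Daily CRPS values of the forecast and the reference are averaged
#' separately within each weekly lead bin (days 5-11, 12-18, 19-25, 26-32),
#' then one skill score per week is computed from the weekly means (not an
#' average of daily skill scores).
#'
#' @param daily a `data.frame` with columns `lead`, `crps_fc`, `crps_ref`
#'   and optionally `station_id` (aggregation is per station if present).
#' @param weeks the lead-week definition (week, lead_min, lead_max).
#' @return a `data.frame` of skill records: (`station_id`,) `week`,
#'   `lead_min`, `lead_max`, `crps_fc`, `crps_ref`, `crpss`.
#' @export
weekly_skill <- function(daily, weeks = NULL) {
  if (is.null(weeks)) weeks <- .verif_weeks
  dt <- as.data.table(daily)
  by_station <- "station_id" %in% names(dt)
  out <- list()
  for (w in seq_len(nrow(weeks))) {
    sub <- dt[lead >= weeks$lead_min[w] & lead <= weeks$lead_max[w]]
    if (nrow(sub) == 0)
      stop(sprintf("no daily records in lead week %d (days %d-%d)",
                   weeks$week[w], weeks$lead_min[w], weeks$lead_max[w]))
    agg <- if (by_station) {
      sub[, .(crps_fc = mean(crps_fc), crps_ref = mean(crps_ref)),
          by = station_id]
    } else {
      sub[, .(station_id = NA_character_, crps_fc = mean(crps_fc),
              crps_ref = mean(crps_ref))]
    }
    agg[, `:=`(week = weeks$week[w], lead_min = weeks$lead_min[w],
               lead_max = weeks$lead_max[w])]
    out[[w]] <- agg
  }
  res <- as.data.frame(rbindlist(out))
  res$crpss <- crpss(res$crps_fc, res$crps_ref)
  cols <- c(if (by_station) "station_id", "week", "lead_min", "lead_max",
            "crps_fc", "crps_ref", "crpss")
  res[, cols]
}

#' Verify member WBGT forecasts against observations
#'
#' Computes daily CRPS of the forecast and of a reference - either a raw
#' (uncorrected) member forecast or the climatological pseudo-ensemble
#' drawn from the observation archive - and aggregates into weekly skill
#' records per station.
#'
#' @param fc corrected member table (see [daily_crps()]).
#' @param obs observed daily values of the verified quantity.
#' @param col value column to verify, e.g. `"wbgt_shade"`.
#' @param reference `"climatology"` or `"raw"`.
#' @param raw_fc raw member table (required for `reference = "raw"`).
#' @param archive observation archive for the climatological reference
#'   (defaults to `obs`).
#' @param n_years,window climatology settings, see
#'   [climatological_reference()].
#' @return weekly skill records, see [weekly_skill()].
#' @export
verify_forecast <- function(fc, obs, col,
                            reference = c("climatology", "raw"),
                            raw_fc = NULL, archive = NULL,
                            n_years = 20L, window = 7L) {
  reference <- match.arg(reference)
  d_fc <- daily_crps(fc, obs, col)
  names(d_fc)[names(d_fc) == "crps"] <- "crps_fc"
  if (reference == "raw") {
    if (is.null(raw_fc)) stop("raw_fc required for reference = 'raw'")
    d_ref <- daily_crps(raw_fc, obs, col)
  } else {
    if (is.null(archive)) archive <- obs
    ob <- as.data.table(obs)
    setnames(ob, old = col, new = "obs_value", skip_absent = TRUE)
    targets <- unique(d_fc[, c("station_id", "valid_date", "init_date",
                               "lead")])
    crps_ref <- numeric(nrow(targets))
    for (i in seq_len(nrow(targets))) {
      arch <- archive[archive$station_id == targets$station_id[i], ]
      members <- climatological_reference(arch, targets$valid_date[i],
                                          variable = col,
                                          n_years = n_years,
                                          window = window)
      y <- ob[station_id == targets$station_id[i] &
                date == targets$valid_date[i]]$obs_value
      crps_ref[i] <- crps_ensemble(members, y[1])
    }
    d_ref <- cbind(targets, crps = crps_ref)
  }
  names(d_ref)[names(d_ref) == "crps"] <- "crps_ref"
  daily <- merge(d_fc, d_ref[, c("station_id", "init_date", "lead",
                                 "crps_ref")],
                 by = c("station_id", "init_date", "lead"))
  weekly_skill(daily)
}
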