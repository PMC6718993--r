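# Synthetic station networks, observation archives and biased ensemble
# hindcasts. The generator defines the study conditions the rest of the
# package is exercised under: a 20-year daily archive, a 51-member ensemble
# out to 46 days initialized Mondays and Thursdays, known additive biases
# and lead-growing spread, and optional uniform-at-random missingness.

.synth_vars <- c("tmax", "td", "wind", "srad")

#' Configuration of the synthetic data generator
#'
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param n_stations number of stations in the network.
#' @param n_years length of the observation archive, years.
#' @param n_members ensemble size.
#' @param max_lead forecast range, days.
#' @param bias additive forecast bias per variable, native units
#'   (degC, degC, m/s, W/m2).
#' @param sigma0 ensemble noise standard deviation at lead 1, per variable.
#' @param spread_growth per-lead-day multiplicative growth of the noise
#'   standard deviation.
#' @param missing_fraction fraction of observation cells set missing,
#'   uniformly at random, in `[0, 1]`.
#' @param srad_mean_factor the irradiance forecast emulates a daily-mean
#'   product: member values are this fraction of the truth's daily maximum
#'   (before bias/noise), so that the mean-to-max radiation quantile map has
#'   a real job to do.
#' @param start_year first calendar year of the archive.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_stations = 5L, n_years = 20L,
                         n_members = 51L, max_lead = 46L,
                         bias = c(tmax = 2, td = 1, wind = 0.5, srad = 50),
                         sigma0 = c(tmax = 1.5, td = 1.5, wind = 0.8,
                                    srad = 60),
                         spread_growth = 1.02,
                         missing_fraction = 0,
                         srad_mean_factor = 0.45,
                         start_year = 1998L) {
  stopifnot(n_stations >= 1, n_years >= 1, n_members >= 1, max_lead >= 1,
            missing_fraction >= 0, missing_fraction <= 1,
            spread_growth > 0, srad_mean_factor > 0)
  if (!all(.synth_vars %in% names(bias)))
    stop("bias must name all of: ", paste(.synth_vars, collapse = ", "))
  if (!all(.synth_vars %in% names(sigma0)))
    stop("sigma0 must name all of: ", paste(.synth_vars, collapse = ", "))
  structure(list(seed = as.integer(seed), n_stations = as.integer(n_stations),
                 n_years = as.integer(n_years),
                 n_members = as.integer(n_members),
                 max_lead = as.integer(max_lead),
                 bias = bias[.synth_vars], sigma0 = sigma0[.synth_vars],
                 spread_growth = spread_growth,
                 missing_fraction = missing_fraction,
                 srad_mean_factor = srad_mean_factor,
                 start_year = as.integer(start_year)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic data configuration\n")
  cat(sprintf("  %d station(s), %d year(s) from %d\n",
              x$n_stations, x$n_years, x$start_year))
  cat(sprintf("  ensemble: %d members, %d-day range, spread growth %.3f\n",
              x$n_members, x$max_lead, x$spread_growth))
  cat("  bias:", paste(sprintf("%s %+g", names(x$bias), x$bias),
                       collapse = ", "), "\n")
  cat(sprintf("  missing fraction: %.2f, seed: %d\n",
              x$missing_fraction, x$seed))
  invisible(x)
}

# deterministic per-station RNG stream offset, kept well below 2^31
.station_seed <- function(cfg, station_id, salt = 0L) {
  h <- sum(utf8ToInt(as.character(station_id)) *
             seq_along(utf8ToInt(as.character(station_id))))
  as.integer((abs(cfg$seed) * 7919 + h * 131 + salt) %% 2147483647L)
}

#' Generate a synthetic station network
#'
#' Stations are scattered over a Europe-like bounding box (lat 35-70 N,
#' lon 10 W-30 E) with non-negative altitudes.
#'
#' @param cfg a [synth_config()].
#' @return a `data.frame` with columns `id`, `name`, `lat`, `lon`,
#'   `altitude`, `source`.
#' @export
make_station_network <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_stations < 1) stop("n_stations must be >= 1")
  set.seed(cfg$seed)
  n <- cfg$n_stations
  width <- max(4L, nchar(as.character(n)))
  id <- sprintf(paste0("ST%0", width, "d"), seq_len(n))
  data.frame(id = id,
             name = paste("Station", id),
             lat = round(runif(n, 35, 70), 4),
             lon = round(runif(n, -10, 30), 4),
             altitude = round(pmin(stats::rexp(n, rate = 1 / 250), 3000)),
             source = "synthetic",
             stringsAsFactors = FALSE)
}

# AR(1) with stationary standard deviation sigma
.ar1 <- function(n, phi, sigma) {
  innov <- rnorm(n, 0, sigma * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

#' Generate a daily observation series for one station
#'
#' The truth process per variable is a seasonal sinusoid plus AR(1) Gaussian
#' noise; the dew point is the air temperature minus a positive depression
#' so it can never exceed it, wind and irradiance are floored at zero.
#' Missingness is injected per variable cell, uniformly at random.
#'
#' @param station one row of the network from [make_station_network()] (or
#'   any list with `id`, `lat`, `altitude`).
#' @param cfg a [synth_config()].
#' @return a `data.frame` with columns `station_id`, `date`, `tmax`,
#'   `td_mean`, `wind_mean`, `srad_max`.
#' @export
generate_observations <- function(station, cfg) {
  stopifnot(inherits(cfg, "synth_config"), cfg$n_years >= 1)
  set.seed(.station_seed(cfg, station$id, salt = 1L))
  d0 <- as.Date(sprintf("%d-01-01", cfg$start_year))
  d1 <- as.Date(sprintf("%d-12-31", cfg$start_year + cfg$n_years - 1L))
  dates <- seq(d0, d1, by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  base <- 16 - 0.25 * (station$lat - 45) - 0.006 * station$altitude
  tmax <- base + 12 * cos(2 * pi * (doy - 200) / 365.25) + .ar1(n, 0.7, 3)
  depression <- pmax(0.5, 6 + .ar1(n, 0.5, 2.5))
  td <- tmax - depression
  wind <- pmax(0, 3 + .ar1(n, 0.5, 1.5))
  srad <- pmax(0, 600 + 320 * cos(2 * pi * (doy - 172) / 365.25) +
                 rnorm(n, 0, 70))
  out <- data.frame(station_id = station$id, date = dates,
                    tmax = tmax, td_mean = td, wind_mean = wind,
                    srad_max = srad, stringsAsFactors = FALSE)
  if (cfg$missing_fraction > 0) {
    for (v in c("tmax", "td_mean", "wind_mean", "srad_max")) {
      out[[v]][runif(n) < cfg$missing_fraction] <- NA_real_
    }
  }
  out
}

#' Monday/Thursday initialization dates
#'
#' All Mondays and Thursdays within `dates` for which the full forecast
#' range is still covered by the series; optionally thinned to `n` evenly
#' spaced dates and/or restricted to given months.
#'
#' @param dates the available truth dates (a `Date` vector).
#' @param max_lead forecast range, days.
#' @param n optional number of init dates to keep (evenly spaced subset).
#' @param months optional integer months to restrict to (e.g. `4:9`).
#' @return a `Date` vector of init dates.
#' @export
select_init_dates <- function(dates, max_lead = 46L, n = NULL,
                              months = NULL) {
  wd <- as.POSIXlt(dates)$wday  # 1 = Monday, 4 = Thursday
  ok <- wd %in% c(1L, 4L) & (dates + max_lead) <= max(dates)
  if (!is.null(months)) ok <- ok & (as.POSIXlt(dates)$mon + 1L) %in% months
  cand <- sort(dates[ok])
  if (length(cand) == 0) stop("no valid Monday/Thursday init dates")
  if (!is.null(n) && n < length(cand)) {
    cand <- cand[unique(round(seq(1, length(cand), length.out = n)))]
  }
  cand
}

#' Generate a biased, dispersed ensemble hindcast for one station
#'
#' Each member value is the truth at the valid date plus the configured
#' additive bias plus Gaussian noise whose standard deviation grows with
#' lead as `sigma0 * spread_growth^(lead - 1)`. The irradiance members
#' emulate a daily-mean forecast product,
#' `srad_mean_factor * truth_daily_max + bias + noise`. Init dates must be
#' Mondays or Thursdays.
#'
#' @param truth a daily series from [generate_observations()] for one
#'   station.
#' @param cfg a [synth_config()].
#' @param init_dates init dates; defaults to all valid Monday/Thursday
#'   dates in the truth series.
#' @return a long `data.frame` with columns `station_id`, `init_date`,
#'   `lead`, `valid_date`, `member`, `variable`, `value`.
#' @export
generate_hindcast <- function(truth, cfg, init_dates = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  station_id <- unique(truth$station_id)
  if (length(station_id) != 1) stop("truth must cover exactly one station")
  if (is.null(init_dates)) {
    init_dates <- select_init_dates(truth$date, cfg$max_lead)
  }
  init_dates <- as.Date(init_dates)
  wd <- as.POSIXlt(init_dates)$wday
  if (!all(wd %in% c(1L, 4L)))
    stop("init dates must fall on Mondays or Thursdays")
  if (any(init_dates < min(truth$date)) ||
      any(init_dates + cfg$max_lead > max(truth$date)))
    stop("truth series shorter than the requested lead range")

  set.seed(.station_seed(cfg, station_id, salt = 2L))
  n_i <- length(init_dates); n_l <- cfg$max_lead; n_m <- cfg$n_members
  # grid: init x lead x member, per variable
  init <- rep(init_dates, each = n_l * n_m)
  lead <- rep(rep(seq_len(n_l), each = n_m), times = n_i)
  member <- rep(seq_len(n_m), times = n_i * n_l)
  valid <- init + lead
  truth_lookup <- setNames(seq_len(nrow(truth)), as.character(truth$date))
  idx <- truth_lookup[as.character(valid)]
  sig <- cfg$sigma0
  sg <- cfg$spread_growth
  pieces <- lapply(.synth_vars, function(v) {
    col <- switch(v, tmax = "tmax", td = "td_mean", wind = "wind_mean",
                  srad = "srad_max")
    tr <- truth[[col]][idx]
    fac <- if (v == "srad") cfg$srad_mean_factor else 1
    val <- fac * tr + cfg$bias[[v]] +
      rnorm(length(tr), 0, sig[[v]] * sg^(lead - 1))
    if (v %in% c("wind", "srad")) val <- pmax(val, 0)
    data.frame(station_id = station_id, init_date = init, lead = lead,
               valid_date = valid, member = member, variable = v,
               value = val, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Generate a full synthetic system
#'
#' Convenience wrapper: network, per-station observation archives and
#' hindcasts for the given init dates.
#'
#' @param cfg a [synth_config()].
#' @param init_dates passed to [generate_hindcast()]; `NULL` for all valid
#'   Monday/Thursday dates (can be large).
#' @param inits_per_year if `init_dates` is `NULL`, thin to this many
#'   warm-season (Apr-Sep) init dates per year.
#' @return a list with `stations`, `observations`, `hindcast`.
#' @export
simulate_system <- function(cfg, init_dates = NULL, inits_per_year = 2) {
  stations <- make_station_network(cfg)
  obs <- do.call(rbind, lapply(seq_len(nrow(stations)), function(i) {
    generate_observations(stations[i, ], cfg)
  }))
  if (is.null(init_dates)) {
    init_dates <- select_init_dates(unique(obs$date), cfg$max_lead,
                                    n = inits_per_year * cfg$n_years,
                                    months = 4:9)
  }
  hc <- do.call(rbind, lapply(seq_len(nrow(stations)), function(i) {
    generate_hindcast(obs[obs$station_id == stations$id[i], ], cfg,
                      init_dates)
  }))
  list(stations = stations, observations = obs, hindcast = hc)
}
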