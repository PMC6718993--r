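# Empirical quantile mapping between hindcast and observed distributions,
# fitted per station, variable and lead-time bin, with the daily-mean to
# daily-max radiation mapping handled as a quantile map with a
# non-negativity constraint.

#' Fit an empirical quantile map
#'
#' Establishes the quantile-dependent correction between a forecast sample
#' and an observation sample: the map's source quantiles are the empirical
#' quantiles of `fcst` on the probability grid and its target quantiles
#' those of `obs`. Applying the map (see [predict.eqm()]) interpolates
#' piecewise-linearly between paired quantiles and uses a constant
#' correction beyond the outermost grid points.
#'
#' @param obs observation sample (missing values dropped).
#' @param fcst forecast sample (missing values dropped).
#' @param probs ascending probability grid in (0, 1); default the 99
#'   percentiles 0.01 ... 0.99.
#' @param min_n minimum sample size on each side after missing-value
#'   removal.
#' @param nonneg clamp corrected values at zero (wind, irradiance).
#' @param station,variable,lead_bin optional labels carried in the object.
#' @return an object of class `eqm`.
#' @examples
#' m <- eqm(obs = rnorm(500), fcst = rnorm(500) + 2)
#' mean(predict(m, rnorm(200) + 2))  # approximately unbiased
#' @export
eqm <- function(obs, fcst, probs = seq(0.01, 0.99, by = 0.01),
                min_n = 100, nonneg = FALSE,
                station = NA_character_, variable = NA_character_,
                lead_bin = NA_character_) {
  obs <- obs[is.finite(obs)]
  fcst <- fcst[is.finite(fcst)]
  if (length(obs) < min_n || length(fcst) < min_n)
    stop(sprintf("insufficient sample for EQM fit (need >= %d, have obs %d / fcst %d)",
                 min_n, length(obs), length(fcst)))
  if (is.unsorted(probs, strictly = TRUE) || any(probs <= 0 | probs >= 1))
    stop("probs must be strictly ascending within (0, 1)")
  if (sd(fcst) == 0) stop("degenerate (constant) forecast sample")
  structure(list(probs = probs,
                 source = unname(quantile(fcst, probs, type = 7)),
                 target = unname(quantile(obs, probs, type = 7)),
                 nonneg = isTRUE(nonneg),
                 station = station, variable = variable, lead_bin = lead_bin,
                 n_obs = length(obs), n_fcst = length(fcst)),
            class = "eqm")
}

#' @export
print.eqm <- function(x, ...) {
  cat("Empirical quantile map")
  lab <- c(x$station, x$variable, x$lead_bin)
  lab <- lab[!is.na(lab)]
  if (length(lab)) cat(" [", paste(lab, collapse = " / "), "]", sep = "")
  cat(sprintf("\n  %d grid points, fitted on %d obs / %d fcst values\n",
              length(x$probs), x$n_obs, x$n_fcst))
  cat(sprintf("  median correction: %+.3f\n",
              x$target[which.min(abs(x$probs - 0.5))] -
                x$source[which.min(abs(x$probs - 0.5))]))
  invisible(x)
}

#' Apply an empirical quantile map
#'
#' Piecewise-linear interpolation of the source-to-target quantile relation;
#' outside the calibrated range the correction of the nearest extreme
#' quantile is applied as a constant offset, so the mapping is defined (and
#' monotone nondecreasing) everywhere.
#'
#' @param object an [eqm()] fit.
#' @param newdata values on the forecast scale.
#' @param ... unused.
#' @return corrected values on the observation scale.
#' @export
predict.eqm <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  src <- object$source
  tgt <- object$target
  # collapse duplicated source quantiles (discrete samples) for interpolation
  if (anyDuplicated(src)) {
    tgt <- as.numeric(tapply(tgt, match(src, src), mean))
    src <- unique(src)
  }
  n <- length(src)
  y <- x
  ok <- is.finite(x)
  if (n == 1) {
    y[ok] <- x[ok] + (tgt[1] - src[1])
  } else {
    inside <- ok & x >= src[1] & x <= src[n]
    if (any(inside))
      y[inside] <- approx(src, tgt, xout = x[inside], ties = "ordered")$y
    lo <- ok & x < src[1]
    hi <- ok & x > src[n]
    y[lo] <- x[lo] + (tgt[1] - src[1])
    y[hi] <- x[hi] + (tgt[n] - src[n])
  }
  if (object$nonneg) y[ok] <- pmax(y[ok], 0)
  y
}

#' Radiation daily-mean to daily-max quantile map
#'
#' The extended-range model provides daily mean irradiance while the heat
#' stress index needs the daily maximum; this map carries forecast daily
#' means onto the observed daily-max scale as part of the bias correction.
#' Outputs are clamped non-negative.
#'
#' @param fcst_daily_mean forecast daily mean irradiance sample, W/m2.
#' @param obs_daily_max observed daily maximum irradiance sample, W/m2.
#' @inheritParams eqm
#' @return an object of class `eqm` with `nonneg = TRUE`.
#' @export
fit_radiation_max_map <- function(fcst_daily_mean, obs_daily_max,
                                  probs = seq(0.01, 0.99, by = 0.01),
                                  min_n = 100, station = NA_character_,
                                  lead_bin = NA_character_) {
  eqm(obs = obs_daily_max, fcst = fcst_daily_mean, probs = probs,
      min_n = min_n, nonneg = TRUE, station = station, variable = "srad",
      lead_bin = lead_bin)
}

#' Weekly lead-time bins
#'
#' @param max_lead forecast range, days.
#' @param width bin width in days (weekly by default); the last bin is
#'   truncated at `max_lead`.
#' @return a `data.frame` with columns `bin`, `lead_min`, `lead_max`,
#'   `label`.
#' @export
make_lead_bins <- function(max_lead = 46L, width = 7L) {
  starts <- seq(1L, max_lead, by = width)
  ends <- pmin(starts + width - 1L, max_lead)
  data.frame(bin = seq_along(starts), lead_min = starts, lead_max = ends,
             label = sprintf("%d-%d", starts, ends))
}

#' Map lead days to bin indices
#'
#' @param lead lead days.
#' @param bins from [make_lead_bins()].
#' @return integer bin index per lead.
#' @export
lead_bin_index <- function(lead, bins) {
  idx <- findInterval(lead, bins$lead_min)
  idx[lead < 1 | lead > max(bins$lead_max)] <- NA_integer_
  idx
}

.map_key <- function(station, variable, bin) {
  paste(station, variable, bin, sep = "|")
}

# observation archive in long form keyed by forecast variable names
.obs_long <- function(obs) {
  dt <- as.data.table(obs)
  long <- melt(dt, id.vars = c("station_id", "date"),
               measure.vars = c("tmax", "td_mean", "wind_mean", "srad_max"),
               variable.name = "obs_col", value.name = "obs_value",
               variable.factor = FALSE)
  long[, variable := c(tmax = "tmax", td_mean = "td", wind_mean = "wind",
                       srad_max = "srad")[obs_col]]
  long[, obs_col := NULL]
  long
}

#' Calibrate a quantile-map store from paired hindcasts and observations
#'
#' Fits one empirical quantile map per (station, variable, lead-week bin),
#' pooling all members and init dates falling in the bin. Pairs with a
#' missing observation are dropped. The irradiance map is the daily-mean to
#' daily-max mapping (observed side: daily maximum irradiance); wind and
#' irradiance maps clamp corrected values at zero.
#'
#' @param obs observation archive (`station_id`, `date`, `tmax`, `td_mean`,
#'   `wind_mean`, `srad_max`).
#' @param hindcast long hindcast table from [generate_hindcast()] (or the
#'   same layout read from file).
#' @param probs probability grid, as in [eqm()].
#' @param bins lead bins from [make_lead_bins()]; default weekly over the
#'   hindcast's lead range.
#' @param min_n minimum paired sample per map.
#' @return an object of class `eqm_store`: a list of [eqm()] fits keyed by
#'   `station|variable|bin`, plus the bin table.
#' @export
fit_eqm_store <- function(obs, hindcast, probs = seq(0.01, 0.99, by = 0.01),
                          bins = NULL, min_n = 100) {
  hc <- as.data.table(hindcast)
  if (is.null(bins)) bins <- make_lead_bins(max(hc$lead))
  hc[, bin := lead_bin_index(lead, bins)]
  ol <- .obs_long(obs)
  hc <- merge(hc, ol, by.x = c("station_id", "valid_date", "variable"),
              by.y = c("station_id", "date", "variable"), all.x = TRUE)
  hc <- hc[is.finite(obs_value) & is.finite(value)]
  maps <- list()
  groups <- hc[, .N, by = .(station_id, variable, bin)]
  for (g in seq_len(nrow(groups))) {
    st <- groups$station_id[g]; vr <- groups$variable[g]
    bn <- groups$bin[g]
    sub <- hc[station_id == st & variable == vr & bin == bn]
    lab <- bins$label[bins$bin == bn]
    m <- if (vr == "srad") {
      fit_radiation_max_map(sub$value, sub$obs_value, probs = probs,
                            min_n = min_n, station = st, lead_bin = lab)
    } else {
      eqm(obs = sub$obs_value, fcst = sub$value, probs = probs,
          min_n = min_n, nonneg = vr == "wind", station = st,
          variable = vr, lead_bin = lab)
    }
    maps[[.map_key(st, vr, bn)]] <- m
  }
  structure(list(maps = maps, bins = bins, probs = probs), class = "eqm_store")
}

#' @export
print.eqm_store <- function(x, ...) {
  cat(sprintf("Quantile-map store: %d maps, %d lead bins, %d grid points\n",
              length(x$maps), nrow(x$bins), length(x$probs)))
  invisible(x)
}

#' Bias-correct an ensemble forecast with a quantile-map store
#'
#' Every member value is corrected with the map of its station, variable
#' and lead bin; member count and row order are preserved. A missing map is
#' an explicit error naming the gap.
#'
#' @param fcst long forecast table (`station_id`, `lead`, `member`,
#'   `variable`, `value`, ...).
#' @param store an `eqm_store` from [fit_eqm_store()].
#' @return the forecast table with corrected `value`.
#' @export
correct_ensemble <- function(fcst, store) {
  stopifnot(inherits(store, "eqm_store"))
  dt <- as.data.table(fcst)
  dt[, `__row` := .I]
  dt[, bin := lead_bin_index(lead, store$bins)]
  if (anyNA(dt$bin)) stop("forecast lead outside the calibrated bin range")
  groups <- unique(dt[, .(station_id, variable, bin)])
  for (g in seq_len(nrow(groups))) {
    key <- .map_key(groups$station_id[g], groups$variable[g], groups$bin[g])
    m <- store$maps[[key]]
    if (is.null(m)) {
      lab <- store$bins$label[store$bins$bin == groups$bin[g]]
      stop(sprintf("no quantile map for station %s, variable %s, lead bin %s",
                   groups$station_id[g], groups$variable[g], lab))
    }
    sel <- dt$station_id == groups$station_id[g] &
      dt$variable == groups$variable[g] & dt$bin == groups$bin[g]
    dt$value[sel] <- predict(m, dt$value[sel])
  }
  setorderv(dt, "__row")
  dt[, c("__row", "bin") := NULL]
  out <- as.data.frame(dt)
  rownames(out) <- NULL
  out
}

#' Serialize a quantile-map store to JSON
#'
#' @param store an `eqm_store`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_map_store <- function(store, path) {
  stopifnot(inherits(store, "eqm_store"))
  payload <- list(
    format = "heatwarn-eqm-store",
    version = 1L,
    probs = store$probs,
    bins = store$bins,
    maps = lapply(store$maps, function(m) {
      list(station = m$station, variable = m$variable, lead_bin = m$lead_bin,
           nonneg = m$nonneg, n_obs = m$n_obs, n_fcst = m$n_fcst,
           probs = m$probs, source = m$source, target = m$target)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a quantile-map store from JSON
#'
#' @param path file written by [write_map_store()].
#' @return an `eqm_store`.
#' @export
read_map_store <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "heatwarn-eqm-store"))
    stop("not a quantile-map store file: ", path)
  maps <- lapply(payload$maps, function(m) {
    structure(list(probs = as.numeric(m$probs),
                   source = as.numeric(m$source),
                   target = as.numeric(m$target),
                   nonneg = isTRUE(m$nonneg),
                   station = m$station, variable = m$variable,
                   lead_bin = m$lead_bin,
                   n_obs = as.integer(m$n_obs),
                   n_fcst = as.integer(m$n_fcst)), class = "eqm")
  })
  structure(list(maps = maps,
                 bins = as.data.frame(payload$bins),
                 probs = as.numeric(payload$probs)),
            class = "eqm_store")
}
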