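# Pipeline glue: member-resolved WBGT from a long forecast table and
# observed daily WBGT from an archive.

#' Member-resolved daily maximum WBGT from a long forecast table
#'
#' Pivots the (bias-corrected) long forecast table wide per
#' (station, init, lead, member) and computes the daily maximum sun and
#' shade WBGT for every member, using the station altitude for the
#' pressure adjustment when a network is supplied.
#'
#' @param fc long forecast table with variables `tmax`, `td`, `wind`,
#'   `srad`.
#' @param stations optional station network (for altitude-based pressure).
#' @return a `data.frame`: `station_id`, `init_date`, `lead`,
#'   `valid_date`, `member`, `wbgt_sun`, `wbgt_shade`.
#' @export
ensemble_wbgt <- function(fc, stations = NULL) {
  dt <- as.data.table(fc)
  wide <- dcast(dt, station_id + init_date + lead + valid_date + member ~
                  variable, value.var = "value")
  need <- c("tmax", "td", "wind")
  miss <- setdiff(need, names(wide))
  if (length(miss))
    stop("forecast table missing variable(s): ", paste(miss, collapse = ", "))
  if (!"srad" %in% names(wide)) wide[, srad := NA_real_]
  pressure <- 1013.25
  if (!is.null(stations)) {
    alt <- setNames(stations$altitude, stations$id)[wide$station_id]
    alt[is.na(alt)] <- 0
    pressure <- station_pressure(alt)
  }
  w <- daily_max_wbgt(wide$tmax, wide$td, pmax(wide$wind, 0),
                      wide$srad, pressure)
  out <- as.data.frame(wide[, .(station_id, init_date, lead, valid_date,
                                member)])
  out$wbgt_sun <- w$wbgt_sun
  out$wbgt_shade <- w$wbgt_shade
  out
}

#' Observed daily maximum WBGT for an archive
#'
#' @param obs observation archive.
#' @param stations optional network for the pressure adjustment.
#' @return the archive with `wbgt_sun` and `wbgt_shade` columns appended.
#' @export
archive_wbgt <- function(obs, stations = NULL) {
  pressure <- 1013.25
  if (!is.null(stations)) {
    alt <- setNames(stations$altitude, stations$id)[obs$station_id]
    alt[is.na(alt)] <- 0
    pressure <- station_pressure(alt)
  }
  w <- daily_max_wbgt(obs$tmax, obs$td_mean, obs$wind_mean, obs$srad_max,
                      pressure)
  out <- obs
  out$wbgt_sun <- w$wbgt_sun
  out$wbgt_shade <- w$wbgt_shade
  out
}
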