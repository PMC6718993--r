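# Personalized occupational heat-risk computation: Du Bois body surface
# area, ISO 8996-style metabolic rate, NIOSH recommended alert/exposure
# limits (RAL for unacclimatized, REL for acclimatized workers), clothing
# adjustment, percentage risk level, banding, recommendations and the
# acclimatization state machine.

.risk_bands <- c("not_significant", "low", "moderate", "high")

.band_rank <- function(band) match(band, .risk_bands)

.activity_levels <- c(low = 2L, moderate = 3L, high = 4L, very_high = 5L)

# metabolic class used by the recommendation table
.mr_class <- function(iso_level) {
  c("L", "L", "M", "H", "VH")[iso_level]
}

#' Body surface area (Du Bois)
#'
#' `BSA (m2) = weight^0.425 * height^0.725 * 0.20247` with weight in kg and
#' height in m.
#'
#' @param weight body weight, kg (20-300).
#' @param height body height, m (0.5-2.5).
#' @return body surface area, m2.
#' @examples
#' body_surface_area(70, 1.75)  # ~1.85 m2
#' @export
body_surface_area <- function(weight, height) {
  if (any(weight <= 20 | weight >= 300))
    stop("weight must lie in (20, 300) kg")
  if (any(height <= 0.5 | height >= 2.5))
    stop("height must lie in (0.5, 2.5) m")
  weight^0.425 * height^0.725 * 0.20247
}

#' Metabolic rate from body surface area and activity level
#'
#' `MR (W) = BSA * ISOlevel * 50`, the activity level being the ordinal
#' 1 (resting) to 5 (very high) class.
#'
#' @param bsa body surface area, m2.
#' @param iso_level activity class, integer 1-5.
#' @return metabolic rate, W.
#' @export
metabolic_rate <- function(bsa, iso_level) {
  if (any(!(iso_level %in% 1:5))) stop("iso_level must be in 1..5")
  bsa * iso_level * 50
}

#' NIOSH recommended alert limit (unacclimatized workers)
#'
#' `RAL (degC-WBGT) = 59.9 - 14.1 * log10(MR)`.
#'
#' @param mr metabolic rate, W (> 0).
#' @return WBGT ceiling, degC.
#' @export
ral <- function(mr) {
  if (any(mr <= 0)) stop("metabolic rate must be positive")
  59.9 - 14.1 * log10(mr)
}

#' NIOSH recommended exposure limit (acclimatized workers)
#'
#' `REL (degC-WBGT) = 56.7 - 11.5 * log10(MR)`; exceeds the alert limit for
#' any metabolic rate above 17 W, reflecting the higher tolerance of
#' acclimatized workers.
#'
#' @inheritParams ral
#' @return WBGT ceiling, degC.
#' @export
rel <- function(mr) {
  if (any(mr <= 0)) stop("metabolic rate must be positive")
  56.7 - 11.5 * log10(mr)
}

#' Default clothing adjustment values
#'
#' Additive WBGT corrections (degC) for clothing ensembles that impede heat
#' loss, following the standard occupational convention; the conventional
#' one-layer work ensemble is the zero reference. Shipped as an editable
#' table (see also the JSON copy under `extdata`).
#'
#' @return a named numeric vector of CAVs.
#' @export
default_cav_table <- function() {
  c(conventional = 0, cloth_coveralls = 0, sms_coveralls = 0.5,
    polyolefin_coveralls = 1, double_layer = 3, vapor_barrier = 11)
}

#' Read a clothing adjustment table from JSON
#'
#' @param path JSON file of `{"clothing_key": cav, ...}`.
#' @return a named numeric vector.
#' @export
read_cav_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- unlist(x)
  if (!is.numeric(out) || is.null(names(out)))
    stop("CAV table must be a JSON object of named numbers")
  out
}

#' Effective WBGT after clothing adjustment
#'
#' @param wbgt forecast WBGT, degC.
#' @param clothing_key entry of the CAV table.
#' @param cav_table named CAV vector, see [default_cav_table()].
#' @return effective WBGT, degC.
#' @export
effective_wbgt <- function(wbgt, clothing_key,
                           cav_table = default_cav_table()) {
  if (!clothing_key %in% names(cav_table))
    stop("unknown clothing key: ", clothing_key)
  wbgt + unname(cav_table[[clothing_key]])
}

#' Heat-stress risk level
#'
#' `risk (%) = 100 * WBGT_eff / limit`, the limit being the worker's RAL or
#' REL.
#'
#' @param wbgt_eff effective WBGT, degC.
#' @param limit RAL or REL, degC-WBGT (> 0).
#' @return risk level, percent.
#' @export
risk_level <- function(wbgt_eff, limit) {
  if (any(limit <= 0)) stop("exposure limit must be positive")
  100 * wbgt_eff / limit
}

#' Classify a risk percentage into a band
#'
#' Bands: not significant (<= 80), low (80-100), moderate (100-120,
#' inclusive below), high (>= 120).
#'
#' @param risk_pct risk level, percent (>= 0).
#' @return character vector of band names.
#' @export
classify_risk <- function(risk_pct) {
  if (any(risk_pct < 0)) stop("risk percentage must be >= 0")
  ifelse(risk_pct <= 80, "not_significant",
         ifelse(risk_pct < 100, "low",
                ifelse(risk_pct < 120, "moderate", "high")))
}

#' Reconstruct a band-boundary WBGT value
#'
#' The WBGT at which a band boundary sits for a given metabolic rate:
#' `(boundary_pct / 100) * limit(mr)` rounded to the nearest 0.5 degC, the
#' granularity of the published band table.
#'
#' @param mr metabolic rate, W.
#' @param limit_type `"RAL"` or `"REL"`.
#' @param boundary_pct one of 80, 100, 120.
#' @return boundary WBGT, degC, rounded to the nearest 0.5.
#' @export
table1_boundary <- function(mr, limit_type = c("RAL", "REL"),
                            boundary_pct) {
  limit_type <- match.arg(limit_type)
  if (!all(boundary_pct %in% c(80, 100, 120)))
    stop("boundary_pct must be one of 80, 100, 120")
  lim <- if (limit_type == "RAL") ral(mr) else rel(mr)
  round(boundary_pct / 100 * lim * 2) / 2
}

# advisory texts keyed by band (platform wording, abridged)
.advisories <- c(
  not_significant = "No special precautions are required; keep normal work and hydration routines.",
  low = "Pre-alarm: pay attention to frequent drinking and plan small breaks.",
  moderate = "Alarm: drink frequently, increase the number of breaks and use cooling during them.",
  high = "Emergency: severe heat stress; drink often, even more than 1 L/h, and schedule frequent breaks in shaded or cool areas."
)

# hydration drop codes by band and metabolic class (1 drop ~0.5 L/h,
# 2 drops ~1 L/h, 3 drops >1 L/h); monotone in band within each class
.hydration_codes <- rbind(
  not_significant = c(L = 1L, M = 2L, H = 2L, VH = 2L),
  low             = c(L = 2L, M = 2L, H = 3L, VH = 3L),
  moderate        = c(L = 2L, M = 2L, H = 3L, VH = 3L),
  high            = c(L = 3L, M = 3L, H = 3L, VH = 3L)
)

#' Break and hydration recommendations for a risk band
#'
#' Break codes escalate 1 (no extra breaks) to 4 (frequent breaks) with the
#' band; hydration codes 1-3 (about 0.5 L/h, about 1 L/h, more than 1 L/h)
#' depend on the band and the metabolic class.
#'
#' @param band risk band name.
#' @param iso_level activity class 1-5 (determines the metabolic class).
#' @return a list with `break_code`, `hydration_code`, `advisory_key`,
#'   `advisory`.
#' @export
recommendations <- function(band, iso_level) {
  if (!band %in% .risk_bands) stop("unknown risk band: ", band)
  if (!iso_level %in% 1:5) stop("iso_level must be in 1..5")
  cls <- .mr_class(iso_level)
  list(break_code = .band_rank(band),
       hydration_code = unname(.hydration_codes[band, cls]),
       advisory_key = band,
       advisory = unname(.advisories[[band]]))
}

#' Create a worker profile
#'
#' Carries the registration fields the personalized forecast needs:
#' anthropometrics, activity level, work environment, clothing and the
#' acclimatization state. A newly registered worker is unacclimatized and
#' the alert limit (RAL) applies; after five qualifying days (at least
#' moderate forecast risk) the exposure limit (REL) takes over.
#'
#' @param height body height, m.
#' @param weight body weight, kg.
#' @param activity one of `"low"`, `"moderate"`, `"high"`, `"very_high"`
#'   (the registration labels, mapped to activity classes 2-5), or an
#'   integer class 1-5 directly.
#' @param environment `"sun"` or `"shade"`.
#' @param clothing_key entry of the CAV table.
#' @param station_id station the worker is attached to.
#' @param cav_table named CAV vector.
#' @param collapse_quantile ensemble quantile shown as the personal daily
#'   value (0.5 = median member; risk-averse users may raise it).
#' @return an object of class `worker_profile`.
#' @export
worker_profile <- function(height, weight, activity = "moderate",
                           environment = c("sun", "shade"),
                           clothing_key = "conventional",
                           station_id = NA_character_,
                           cav_table = default_cav_table(),
                           collapse_quantile = 0.5) {
  environment <- match.arg(environment)
  iso_level <- if (is.numeric(activity)) {
    if (!activity %in% 1:5) stop("numeric activity must be in 1..5")
    as.integer(activity)
  } else {
    if (!activity %in% names(.activity_levels))
      stop("activity must be one of: ",
           paste(names(.activity_levels), collapse = ", "))
    .activity_levels[[activity]]
  }
  if (collapse_quantile <= 0 || collapse_quantile >= 1)
    stop("collapse_quantile must lie in (0, 1)")
  bsa <- body_surface_area(weight, height)  # validates ranges
  if (!clothing_key %in% names(cav_table))
    stop("unknown clothing key: ", clothing_key)
  structure(list(height = height, weight = weight, iso_level = iso_level,
                 environment = environment, clothing_key = clothing_key,
                 station_id = station_id, cav_table = cav_table,
                 collapse_quantile = collapse_quantile,
                 bsa = bsa, mr = metabolic_rate(bsa, iso_level),
                 acclimatized = FALSE, exposure_days = 0L,
                 last_qualifying = as.Date(NA), last_date = as.Date(NA)),
            class = "worker_profile")
}

#' @export
print.worker_profile <- function(x, ...) {
  cat("Worker profile\n")
  cat(sprintf("  %.2f m, %.0f kg (BSA %.2f m2), activity class %d -> MR %.0f W\n",
              x$height, x$weight, x$bsa, x$iso_level, x$mr))
  cat(sprintf("  environment: %s, clothing: %s (CAV %+.1f degC)\n",
              x$environment, x$clothing_key,
              x$cav_table[[x$clothing_key]]))
  cat(sprintf("  %s (limit %s = %.2f degC-WBGT), qualifying days: %d\n",
              if (x$acclimatized) "acclimatized" else "unacclimatized",
              if (x$acclimatized) "REL" else "RAL",
              if (x$acclimatized) rel(x$mr) else ral(x$mr),
              x$exposure_days))
  invisible(x)
}

#' Assess one forecast day for a worker
#'
#' Collapses the member WBGT values of the worker's exposure to a single
#' value at the profile's collapse quantile (median by default), applies
#' the clothing adjustment, the worker's current limit (RAL or REL), the
#' percentage risk level, the band and the recommendations.
#'
#' @param profile a [worker_profile()].
#' @param members member WBGT values for the day, degC (worker's exposure).
#' @param date the forecast day.
#' @return one-row `data.frame` (class `risk_assessment`): `date`,
#'   `wbgt_raw`, `cav`, `wbgt_eff`, `limit_type`, `limit`, `risk_pct`,
#'   `band`, `break_code`, `hydration_code`, `advisory_key`.
#' @export
assess_day <- function(profile, members, date = Sys.Date()) {
  stopifnot(inherits(profile, "worker_profile"))
  members <- members[is.finite(members)]
  if (length(members) == 0) stop("empty ensemble for risk assessment")
  wbgt_raw <- unname(quantile(members, profile$collapse_quantile, type = 7))
  cav <- unname(profile$cav_table[[profile$clothing_key]])
  wbgt_eff <- wbgt_raw + cav
  limit_type <- if (profile$acclimatized) "REL" else "RAL"
  limit <- if (profile$acclimatized) rel(profile$mr) else ral(profile$mr)
  pct <- risk_level(wbgt_eff, limit)
  pct <- max(pct, 0)  # clamp: sub-zero effective WBGT carries no heat risk
  band <- classify_risk(pct)
  rec <- recommendations(band, profile$iso_level)
  out <- data.frame(date = as.Date(date), wbgt_raw = wbgt_raw, cav = cav,
                    wbgt_eff = wbgt_eff, limit_type = limit_type,
                    limit = limit, risk_pct = pct, band = band,
                    break_code = rec$break_code,
                    hydration_code = rec$hydration_code,
                    advisory_key = rec$advisory_key,
                    stringsAsFactors = FALSE)
  class(out) <- c("risk_assessment", class(out))
  out
}

#' Update a worker's acclimatization state with one day's assessment
#'
#' Qualifying days (band at least moderate) increment the exposure counter;
#' at five qualifying days the worker flips to acclimatized and the REL
#' applies from the next assessment on. Qualifying days need not be
#' consecutive, but after `reset_days` without a qualifying day the counter
#' (and the acclimatized state) resets - the warm season is over.
#' Assessments must be processed in date order.
#'
#' @param profile a [worker_profile()].
#' @param assessment a row from [assess_day()].
#' @param qualifying_days days of at least moderate risk needed, default 5.
#' @param reset_days season boundary: days without a qualifying day after
#'   which the state resets.
#' @return the updated profile.
#' @export
update_acclimatization <- function(profile, assessment, qualifying_days = 5L,
                                   reset_days = 30L) {
  stopifnot(inherits(profile, "worker_profile"))
  day <- as.Date(assessment$date)
  if (!is.na(profile$last_date) && day < profile$last_date)
    stop("assessments must be processed in date order")
  if (!is.na(profile$last_qualifying) &&
      as.numeric(day - profile$last_qualifying) > reset_days) {
    profile$exposure_days <- 0L
    profile$acclimatized <- FALSE
    profile$last_qualifying <- as.Date(NA)
  }
  if (.band_rank(assessment$band) >= .band_rank("moderate")) {
    profile$exposure_days <- profile$exposure_days + 1L
    profile$last_qualifying <- day
    if (profile$exposure_days >= qualifying_days) profile$acclimatized <- TRUE
  }
  profile$last_date <- day
  profile
}
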