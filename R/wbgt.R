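# Wet-Bulb Globe Temperature from standard meteorological variables.
#
# Sun exposure uses the energy-balance formulation of the black globe and the
# wetted wick (Liljegren-type solvers); shade exposure uses the wind-dependent
# relation between the natural and the psychrometric wet-bulb temperature
# (Bernard-type). All temperatures degC, wind m/s, irradiance W/m2,
# pressure hPa.

# physical constants and instrument geometry, frozen from the cited
# instrument-scale formulations
.wbgt_const <- list(
  stefanb    = 5.6696e-8,  # Stefan-Boltzmann, W m-2 K-4
  cp         = 1003.5,     # specific heat of dry air, J kg-1 K-1
  m_air      = 28.97,      # g mol-1
  m_h2o      = 18.015,     # g mol-1
  r_air      = 8314.34 / 28.97,   # gas constant of dry air, J kg-1 K-1
  emis_globe = 0.95,
  alb_globe  = 0.05,
  diam_globe = 0.0508,     # m (standard 2-inch globe)
  emis_wick  = 0.95,
  alb_wick   = 0.4,
  diam_wick  = 0.007,      # m
  len_wick   = 0.0254,     # m
  emis_sfc   = 0.999,
  alb_sfc    = 0.45,       # ground short-wave reflectance
  wind_floor = 0.13,       # m/s; avoids singular transfer/log terms in calm air
  tol        = 1e-4,       # degC, solver convergence
  max_iter   = 200
)

.wbgt_pr <- .wbgt_const$cp / (.wbgt_const$cp + 1.25 * .wbgt_const$r_air)

#' Saturation vapor pressure over water
#'
#' Buck-type formulation, `6.1121 * exp(17.502 * t / (240.97 + t))`.
#'
#' @param t temperature, degC; must lie in `[-60, 60]`.
#' @return saturation vapor pressure, hPa.
#' @examples
#' saturation_vapor_pressure(c(0, 20))
#' @export
saturation_vapor_pressure <- function(t) {
  if (any(!is.finite(t)) || any(t < -60 | t > 60))
    stop("temperature out of supported range [-60, 60] degC")
  6.1121 * exp(17.502 * t / (240.97 + t))
}

# dynamic viscosity of air, kg m-1 s-1 (tk in Kelvin)
.air_viscosity <- function(tk) {
  omega <- (tk / 97 - 2.9) / 0.4 * (-0.034) + 1.048
  2.6693e-6 * sqrt(.wbgt_const$m_air * tk) / (3.617^2 * omega)
}

# thermal conductivity of air, W m-1 K-1
.air_conductivity <- function(tk) {
  (.wbgt_const$cp + 1.25 * .wbgt_const$r_air) * .air_viscosity(tk)
}

# diffusivity of water vapor in air, m2 s-1
.h2o_diffusivity <- function(tk, pressure) {
  2.471e-5 * (tk / 273.15)^1.81 * (1013.25 / pressure)
}

# long-wave sky emissivity from ambient vapor pressure (hPa)
.sky_emissivity <- function(e) pmin(1, 0.575 * e^0.143)

# convective transfer coefficient of the globe, W m-2 K-1
.h_sphere <- function(tk, pressure, speed) {
  k <- .wbgt_const
  dens <- pressure * 100 / (k$r_air * tk)
  re <- speed * dens * k$diam_globe / .air_viscosity(tk)
  nu <- 2 + 0.6 * sqrt(re) * .wbgt_pr^(1 / 3)
  nu * .air_conductivity(tk) / k$diam_globe
}

# convective transfer coefficient of the wick (cylinder), W m-2 K-1
.h_cylinder <- function(tk, pressure, speed) {
  k <- .wbgt_const
  dens <- pressure * 100 / (k$r_air * tk)
  re <- speed * dens * k$diam_wick / .air_viscosity(tk)
  nu <- 0.281 * re^0.6 * .wbgt_pr^0.44
  nu * .air_conductivity(tk) / k$diam_wick
}

# latent heat of vaporization, J kg-1 (tk in Kelvin)
.latent_heat <- function(tk) (313.15 - tk) / 30 * (-71100) + 2.4073e6

.check_meteo <- function(ta, td, v, S = 0, pressure = 1013.25) {
  if (any(!is.finite(ta)) || any(!is.finite(td)) || any(!is.finite(v)))
    stop("non-finite meteorological input")
  if (any(td > ta + 1e-9)) stop("dew point exceeds air temperature")
  if (any(v < 0)) stop("negative wind speed")
  if (any(S < 0)) stop("negative solar irradiance")
  if (any(pressure <= 0)) stop("non-positive pressure")
  invisible(TRUE)
}

#' Psychrometric (aspirated) wet-bulb temperature
#'
#' Solves the psychrometer balance `esat(tw) - e = gamma * (ta - tw)` with
#' `gamma = 6.67e-4 * pressure` by bracketed root finding on `[td, ta]`.
#'
#' @param ta air temperature, degC.
#' @param td dew point temperature, degC (`td <= ta`).
#' @param pressure air pressure, hPa.
#' @return wet-bulb temperature, degC, in `[td, ta]`.
#' @export
psychrometric_wet_bulb <- function(ta, td, pressure = 1013.25) {
  .check_meteo(ta, td, v = 0, pressure = pressure)
  n <- max(length(ta), length(td), length(pressure))
  ta <- rep_len(ta, n); td <- rep_len(td, n); pressure <- rep_len(pressure, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (ta[i] - td[i] < 1e-9) { out[i] <- ta[i]; next }
    e <- saturation_vapor_pressure(td[i])
    gamma <- 6.67e-4 * pressure[i]
    f <- function(tw) saturation_vapor_pressure(tw) - e - gamma * (ta[i] - tw)
    out[i] <- uniroot(f, c(td[i], ta[i]), tol = 1e-7)$root
  }
  out
}

#' Natural wet-bulb temperature in the shade
#'
#' Wind-dependent relation between the natural and the psychrometric wet
#' bulb: `tnwb = ta - C(v) * (ta - tpwb)` with
#' `C(v) = min(1, 0.96 + 0.069 * log10(v))` and the wind speed floored at
#' 0.13 m/s. As wind grows the natural wet bulb approaches the psychrometric
#' wet bulb; in calm air it sits closer to the dry bulb.
#'
#' @inheritParams psychrometric_wet_bulb
#' @param v wind speed, m/s.
#' @return natural wet-bulb temperature, degC.
#' @export
natural_wet_bulb_shade <- function(ta, td, v, pressure = 1013.25) {
  .check_meteo(ta, td, v, pressure = pressure)
  v <- pmax(v, .wbgt_const$wind_floor)
  cc <- pmin(1, 0.96 + 0.069 * log10(v))
  tpwb <- psychrometric_wet_bulb(ta, td, pressure)
  ta - cc * (ta - tpwb)
}

# shared driver for the damped fixed-point solvers; `step` maps the current
# iterate (Kelvin) to the next, vectorized. Falls back to bracketed root
# finding per element if the iteration has not converged at the cap.
.fixed_point <- function(start, step, residual, lower, upper) {
  k <- .wbgt_const
  x <- start
  active <- rep(TRUE, length(x))
  for (it in seq_len(k$max_iter)) {
    if (!any(active)) break
    xn <- step(x)
    delta <- abs(xn - x)
    x[active] <- 0.9 * x[active] + 0.1 * xn[active]
    active <- active & (delta > k$tol) & is.finite(x)
    if (any(!is.finite(x))) break
  }
  bad <- active | !is.finite(x)
  if (any(bad)) {
    for (i in which(bad)) {
      x[i] <- tryCatch(
        uniroot(function(z) residual(z, i), c(lower[i], upper[i]),
                tol = 1e-6, extendInt = "no")$root,
        error = function(e) stop("WBGT solver failed to converge: ",
                                 conditionMessage(e))
      )
    }
  }
  x
}

#' Black globe temperature
#'
#' Equilibrium temperature of a standard 15-cm black globe from the balance
#' of absorbed short- and long-wave radiation against convective exchange
#' and re-emission. Solved by a damped fixed point with a bracketed
#' root-finding fallback.
#'
#' @inheritParams natural_wet_bulb_shade
#' @param S solar irradiance on a horizontal plane, W/m2 (0 in shade).
#' @param fdir fraction of `S` that is direct beam; the remainder diffuse.
#' @param zenith solar zenith angle, degrees. The default corresponds to the
#'   high sun implied by a daily-maximum irradiance.
#' @param emis_sky long-wave sky emissivity; by default derived from the
#'   ambient vapor pressure. Set to 1 for an isothermal radiative
#'   environment at air temperature.
#' @return globe temperature, degC.
#' @export
globe_temperature <- function(ta, td, v, S = 0, pressure = 1013.25,
                              fdir = 0.75, zenith = 30, emis_sky = NULL) {
  .check_meteo(ta, td, v, S, pressure)
  k <- .wbgt_const
  n <- max(length(ta), length(td), length(v), length(S), length(pressure))
  ta <- rep_len(ta, n); td <- rep_len(td, n); v <- rep_len(v, n)
  S <- rep_len(S, n); pressure <- rep_len(pressure, n)
  v <- pmax(v, k$wind_floor)
  tk <- ta + 273.15
  ea <- saturation_vapor_pressure(td)
  eatm <- if (is.null(emis_sky)) .sky_emissivity(ea) else rep_len(emis_sky, n)
  cza <- cos(zenith * pi / 180)
  if (cza <= 0.05) stop("sun too low: zenith angle must be < ~87 degrees")
  rad <- S / (2 * k$stefanb * k$emis_globe) * (1 - k$alb_globe) *
    (fdir * (1 / (2 * cza) - 1) + 1 + k$alb_sfc)
  lw <- 0.5 * (eatm + k$emis_sfc) * tk^4

  step <- function(tg) {
    tref <- 0.5 * (tg + tk)
    h <- .h_sphere(tref, pressure, v)
    base <- pmax(lw - h / (k$stefanb * k$emis_globe) * (tg - tk) + rad, 150^4)
    base^0.25
  }
  residual <- function(tg, i) {
    tref <- 0.5 * (tg + tk[i])
    h <- .h_sphere(tref, pressure[i], v[i])
    k$stefanb * k$emis_globe * (tg^4 - lw[i] - rad[i]) + h * (tg - tk[i])
  }
  tg <- .fixed_point(tk, step, residual, lower = tk - 60, upper = tk + 120)
  tg - 273.15
}

#' Natural wet-bulb temperature in the sun
#'
#' Energy and mass balance of a freely ventilated wetted wick including the
#' solar load and long-wave exchange, solved by damped fixed point with a
#' bracketed fallback.
#'
#' @inheritParams globe_temperature
#' @return natural wet-bulb temperature, degC.
#' @export
natural_wet_bulb_sun <- function(ta, td, v, S = 0, pressure = 1013.25,
                                 fdir = 0.75, zenith = 30, emis_sky = NULL) {
  .check_meteo(ta, td, v, S, pressure)
  k <- .wbgt_const
  n <- max(length(ta), length(td), length(v), length(S), length(pressure))
  ta <- rep_len(ta, n); td <- rep_len(td, n); v <- rep_len(v, n)
  S <- rep_len(S, n); pressure <- rep_len(pressure, n)
  v <- pmax(v, k$wind_floor)
  tk <- ta + 273.15
  ea <- saturation_vapor_pressure(td)
  eatm <- if (is.null(emis_sky)) .sky_emissivity(ea) else rep_len(emis_sky, n)
  zr <- zenith * pi / 180
  ratio <- k$cp * k$m_air / k$m_h2o
  wick_geom <- 0.25 * k$diam_wick / k$len_wick
  srad_abs <- (1 - k$alb_wick) * S *
    ((1 - fdir) * (1 + wick_geom) + fdir * (tan(zr) / pi + wick_geom) +
       k$alb_sfc)
  lw <- 0.5 * (eatm + k$emis_sfc) * tk^4

  tw_next <- function(tw) {
    tref <- 0.5 * (tw + tk)
    h <- .h_cylinder(tref, pressure, v)
    fatm <- k$stefanb * k$emis_wick * (lw - tw^4) + srad_abs
    ewick <- saturation_vapor_pressure(pmin(pmax(tw - 273.15, -60), 60))
    dens <- pressure * 100 / (k$r_air * tref)
    sc <- .air_viscosity(tref) / (dens * .h2o_diffusivity(tref, pressure))
    tk - .latent_heat(tref) / ratio * (ewick - ea) / (pressure - ewick) *
      (.wbgt_pr / sc)^0.56 + fatm / h
  }
  residual <- function(tw, i) {
    tref <- 0.5 * (tw + tk[i])
    h <- .h_cylinder(tref, pressure[i], v[i])
    fatm <- k$stefanb * k$emis_wick * (lw[i] - tw^4) + srad_abs[i]
    ewick <- saturation_vapor_pressure(min(max(tw - 273.15, -60), 60))
    dens <- pressure[i] * 100 / (k$r_air * tref)
    sc <- .air_viscosity(tref) / (dens * .h2o_diffusivity(tref, pressure[i]))
    tw - (tk[i] - .latent_heat(tref) / ratio * (ewick - ea[i]) /
            (pressure[i] - ewick) * (.wbgt_pr / sc)^0.56 + fatm / h)
  }
  tw <- .fixed_point(td + 273.15, tw_next, residual,
                     lower = td + 273.15 - 20, upper = tk + 25)
  tw - 273.15
}

#' Combine WBGT components
#'
#' Weighted combination of the natural wet-bulb, globe and air temperatures:
#' `0.7 * tnwb + 0.2 * tg + 0.1 * ta` in the sun and `0.7 * tnwb + 0.3 * tg`
#' in the shade. The natural wet bulb is the dominant (70%) component; the
#' globe term carries 20% in the sun (with a 10% air term) and 30% in the
#' shade.
#'
#' @param tnwb natural wet-bulb temperature, degC.
#' @param tg globe temperature, degC.
#' @param ta air temperature, degC (ignored for shade).
#' @param exposure `"sun"` or `"shade"`.
#' @return WBGT, degC.
#' @export
wbgt_combine <- function(tnwb, tg, ta = NULL, exposure = c("sun", "shade")) {
  exposure <- match.arg(exposure)
  if (exposure == "sun") {
    if (is.null(ta)) stop("air temperature required for sun WBGT")
    0.7 * tnwb + 0.2 * tg + 0.1 * ta
  } else {
    0.7 * tnwb + 0.3 * tg
  }
}

#' WBGT for sun exposure
#'
#' @inheritParams globe_temperature
#' @return a `data.frame` with columns `t_nwb`, `t_g`, `wbgt`, `exposure`.
#' @examples
#' wbgt_sun(ta = 32, td = 24, v = 1, S = 700)
#' @export
wbgt_sun <- function(ta, td, v, S, pressure = 1013.25, fdir = 0.75,
                     zenith = 30, emis_sky = NULL) {
  tnwb <- natural_wet_bulb_sun(ta, td, v, S, pressure, fdir, zenith, emis_sky)
  tg <- globe_temperature(ta, td, v, S, pressure, fdir, zenith, emis_sky)
  data.frame(t_nwb = tnwb, t_g = tg,
             wbgt = wbgt_combine(tnwb, tg, ta, "sun"),
             exposure = "sun", stringsAsFactors = FALSE)
}

#' WBGT for shade exposure
#'
#' Natural wet bulb from the shade relation; the globe term is either solved
#' radiatively with zero short-wave load (default) or set equal to the air
#' temperature (`globe_mode = "air"`).
#'
#' @inheritParams globe_temperature
#' @param globe_mode `"solve"` (radiative balance at S = 0) or `"air"`
#'   (globe equals air temperature).
#' @return a `data.frame` with columns `t_nwb`, `t_g`, `wbgt`, `exposure`.
#' @export
wbgt_shade <- function(ta, td, v, pressure = 1013.25,
                       globe_mode = c("solve", "air"), emis_sky = NULL) {
  globe_mode <- match.arg(globe_mode)
  tnwb <- natural_wet_bulb_shade(ta, td, v, pressure)
  tg <- if (globe_mode == "air") {
    n <- max(length(ta), length(td), length(v)); rep_len(ta, n)
  } else {
    globe_temperature(ta, td, v, S = 0, pressure = pressure,
                      emis_sky = emis_sky)
  }
  data.frame(t_nwb = tnwb, t_g = tg,
             wbgt = wbgt_combine(tnwb, tg, exposure = "shade"),
             exposure = "shade", stringsAsFactors = FALSE)
}

#' Station pressure from altitude
#'
#' Standard-atmosphere barometric adjustment used when a station carries an
#' altitude but no pressure record.
#'
#' @param altitude station altitude, m.
#' @return pressure, hPa.
#' @export
station_pressure <- function(altitude) {
  1013.25 * (1 - 2.25577e-5 * pmax(altitude, 0))^5.25588
}

#' Daily maximum WBGT (sun and shade)
#'
#' Computes the day's maximum heat stress from the daily maximum air
#' temperature and irradiance together with the daily mean dew point and
#' wind, the aggregation the warning platform operates on. Rows with a
#' missing irradiance get a shade value but a missing sun value; rows
#' missing any of temperature, dew point or wind are missing in both.
#'
#' @param tmax daily maximum air temperature, degC.
#' @param td_mean daily mean dew point, degC.
#' @param wind_mean daily mean wind speed, m/s.
#' @param srad_max daily maximum solar irradiance, W/m2.
#' @param pressure air pressure, hPa (scalar or per-row).
#' @param ... further arguments passed to the sun/shade solvers.
#' @return a `data.frame` with columns `wbgt_sun` and `wbgt_shade`.
#' @export
daily_max_wbgt <- function(tmax, td_mean, wind_mean, srad_max,
                           pressure = 1013.25, ...) {
  n <- max(length(tmax), length(td_mean), length(wind_mean),
           length(srad_max))
  tmax <- rep_len(tmax, n); td_mean <- rep_len(td_mean, n)
  wind_mean <- rep_len(wind_mean, n); srad_max <- rep_len(srad_max, n)
  pressure <- rep_len(pressure, n)
  td_mean <- pmin(td_mean, tmax)  # daily aggregates can cross; clamp
  out <- data.frame(wbgt_sun = rep(NA_real_, n),
                    wbgt_shade = rep(NA_real_, n))
  base_ok <- !is.na(tmax) & !is.na(td_mean) & !is.na(wind_mean)
  if (any(base_ok)) {
    sh <- wbgt_shade(tmax[base_ok], td_mean[base_ok], wind_mean[base_ok],
                     pressure[base_ok], ...)
    out$wbgt_shade[base_ok] <- sh$wbgt
  }
  sun_ok <- base_ok & !is.na(srad_max)
  if (any(sun_ok)) {
    sn <- wbgt_sun(tmax[sun_ok], td_mean[sun_ok], wind_mean[sun_ok],
                   srad_max[sun_ok], pressure[sun_ok], ...)
    out$wbgt_sun[sun_ok] <- sn$wbgt
  }
  out
}
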