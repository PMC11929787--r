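# Ground-truth astronomy: solar position, sunrise/sunset, day length,
# true solar declination, simulated geomagnetic inclination and a clear-sky
# blue-irradiance proxy.
#
# The solar ephemeris follows the low-accuracy solar-position equations
# published by the NOAA Global Monitoring Laboratory (fractional year,
# equation of time, declination as truncated Fourier series, hour angle from
# true solar time).  Accuracy is a few hundredths of a degree for
# 2020-2030, well inside the 0.5 degree contract.
#
# Time base: hours since Jan 1 00:00 UTC of the simulation year.  Local
# solar time is derived from longitude; no civil time zones.

#' Radius of the earth (m) used for all spherical geometry
#' @export
EARTH_RADIUS <- 6378137

#' Construct a point on the globe
#'
#' @param latitude degrees in `[-90, 90]`, south negative.
#' @param longitude degrees, west negative; normalised to `[-180, 180)`.
#' @return an object of class `geo_point` (a named list).
#' @export
geo_point <- function(latitude, longitude) {
  stopifnot(is.finite(latitude), is.finite(longitude),
            latitude >= -90, latitude <= 90)
  structure(list(latitude = latitude, longitude = wrap180(longitude)),
            class = "geo_point")
}

#' @export
print.geo_point <- function(x, ...) {
  cat(sprintf("<geo_point %.4f%s, %.4f%s>\n",
              abs(x$latitude), if (x$latitude < 0) "S" else "N",
              abs(x$longitude), if (x$longitude < 0) "W" else "E"))
  invisible(x)
}

days_in_year <- function(year) {
  if ((year %% 4 == 0 && year %% 100 != 0) || year %% 400 == 0) 366 else 365
}

# Fractional year (radians), NOAA convention, from day of year (1-based)
# and UTC decimal hour.
.noaa_gamma <- function(doy, hour_utc, ndays) {
  2 * pi / ndays * (doy - 1 + (hour_utc - 12) / 24)
}

# Equation of time (minutes) and solar declination (radians).
.noaa_eqtime <- function(g) {
  229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
            0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
}

.noaa_decl <- function(g) {
  0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) - 0.006758 * cos(2 * g) +
    0.000907 * sin(2 * g) - 0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
}

#' Solar azimuth and elevation
#'
#' NOAA solar-position algorithm.  Timestamps are hours since Jan 1
#' 00:00 UTC of `year`.
#'
#' @param location a [geo_point()].
#' @param timestamp hours since the start of the year (vectorised).
#' @param year calendar year (sets the leap-year day count).
#' @return data frame with columns `azimuth` (degrees clockwise from true
#'   north, in `[0, 360)`) and `elevation` (degrees above the geometric
#'   horizon).
#' @export
solar_position <- function(location, timestamp, year = 2024) {
  stopifnot(inherits(location, "geo_point"), all(timestamp >= 0))
  ndays <- days_in_year(year)
  doy <- floor(timestamp / 24) + 1
  hour <- timestamp %% 24
  g <- .noaa_gamma(doy, hour, ndays)
  eqtime <- .noaa_eqtime(g)
  decl <- .noaa_decl(g)
  # true solar time in minutes; hour angle in radians (afternoon positive)
  tst <- hour * 60 + eqtime + 4 * location$longitude
  ha <- deg2rad(tst / 4 - 180)
  lat <- deg2rad(location$latitude)
  cosz <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  cosz <- pmin(1, pmax(-1, cosz))
  elev <- 90 - rad2deg(acos(cosz))
  east <- -cos(decl) * sin(ha)
  north <- cos(lat) * sin(decl) - sin(lat) * cos(decl) * cos(ha)
  az <- wrap360(rad2deg(atan2(east, north)))
  data.frame(azimuth = az, elevation = elev)
}

#' Sunrise, sunset and day length
#'
#' Sunrise/sunset are the crossings of the geometric horizon (sun centre at
#' zero elevation; no atmospheric refraction), in hours UTC of the day, with
#' the day-of-year offset added so values are on the same hours-since-Jan-1
#' axis as [solar_position()].
#'
#' @param location a [geo_point()].
#' @param day_index integer day of year (1-based).
#' @param year calendar year.
#' @return list with `sunrise`, `sunset` (hours since Jan 1 UTC),
#'   `day_length` (hours), and `condition` (`"normal"`, `"polar_day"` or
#'   `"polar_night"`).  During polar day/night the times are `NA`.
#' @export
sunrise_sunset <- function(location, day_index, year = 2024) {
  stopifnot(inherits(location, "geo_point"), day_index >= 1)
  ndays <- days_in_year(year)
  g <- .noaa_gamma(day_index, 12, ndays)
  eqtime <- .noaa_eqtime(g)
  decl <- .noaa_decl(g)
  lat <- deg2rad(location$latitude)
  cos_ha0 <- -tan(lat) * tan(decl)
  if (cos_ha0 < -1) {
    return(list(sunrise = NA_real_, sunset = NA_real_,
                day_length = 24, condition = "polar_day"))
  }
  if (cos_ha0 > 1) {
    return(list(sunrise = NA_real_, sunset = NA_real_,
                day_length = 0, condition = "polar_night"))
  }
  ha0 <- rad2deg(acos(cos_ha0))
  base <- (day_index - 1) * 24
  sunrise <- base + (720 - 4 * (location$longitude + ha0) - eqtime) / 60
  sunset <- base + (720 - 4 * (location$longitude - ha0) - eqtime) / 60
  list(sunrise = sunrise, sunset = sunset,
       day_length = sunset - sunrise, condition = "normal")
}

#' Internal model of the solar declination
#'
#' The insect's annual oscillator: a single sinusoid with a fixed 365-day
#' period, `delta(t) = 23.45 sin(360 (284 + t/24) / 365)` degrees.  This is
#' the animal's internal approximation, distinct from the NOAA declination
#' used by the ephemeris.
#'
#' @param timestamp hours since Jan 1 (vectorised).
#' @return declination in degrees, in `[-23.45, 23.45]`.
#' @export
solar_declination_true <- function(timestamp) {
  stopifnot(all(timestamp >= 0))
  23.45 * sin(deg2rad((284 + timestamp / 24) / 365 * 360))
}

#' Geomagnetic inclination from geometric latitude
#'
#' Dipole-field approximation `mu = atan(-2 tan(phi))`.  With this sign
#' convention the inclination is negative in the northern hemisphere; the
#' only requirement downstream is mutual consistency with
#' [latitude_from_inclination()], its exact algebraic inverse.
#'
#' @param latitude degrees, `|latitude| <= 90` (vectorised).
#' @return inclination in degrees in `[-90, 90]`.
#' @export
magnetic_inclination <- function(latitude) {
  stopifnot(all(abs(latitude) <= 90))
  ifelse(abs(latitude) == 90, -sign(latitude) * 90,
         rad2deg(atan(-2 * tan(deg2rad(latitude)))))
}

#' Clear-sky blue-irradiance proxy
#'
#' `I_sky = I0 * max(0, sin(elevation))^gamma`: zero below the horizon,
#' smooth and strictly increasing in sun elevation above it.  A stand-in
#' for a ray-traced sky radiance model; the day-length estimator only needs
#' a signal whose daily integral tracks day length, and its gain/offset are
#' refit against whatever light regime is used.
#'
#' @param location a [geo_point()].
#' @param timestamp hours since Jan 1 UTC (vectorised).
#' @param year calendar year.
#' @param I0 peak irradiance (W m-2 sr-1) at the zenith. Default 1.
#' @param gamma shape exponent. Default 1.
#' @return irradiance values, same length as `timestamp`.
#' @export
sky_irradiance <- function(location, timestamp, year = 2024, I0 = 1, gamma = 1) {
  pos <- solar_position(location, timestamp, year)
  I0 * pmax(0, sin(deg2rad(pos$elevation)))^gamma
}
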