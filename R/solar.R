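# Solar geometry (NOAA low-precision solar position approximations).
# Angles in degrees, times in UTC. Elevation accurate to ~0.1 deg, which is
# ample for threshold light-level geolocation (logger noise dominates).

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# Fractional-year angle (radians) from a fractional UTC day-of-year
# (1.0 = 00:00 UTC on 1 January).
.frac_year <- function(doy_frac) 2 * pi / 365 * (doy_frac - 1)

#' Solar declination
#'
#' @param doy_frac fractional UTC day-of-year (1 = 00:00 UTC, 1 January).
#' @return declination in degrees.
#' @export
solar_declination <- function(doy_frac) {
  g <- .frac_year(doy_frac)
  d <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  .rad2deg(d)
}

#' Equation of time
#'
#' Difference between apparent and mean solar time.
#'
#' @inheritParams solar_declination
#' @return minutes.
#' @export
equation_of_time <- function(doy_frac) {
  g <- .frac_year(doy_frac)
  229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
              0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
}

#' Solar elevation angle
#'
#' @inheritParams solar_declination
#' @param lat,lon position in degrees (longitude east-positive).
#' @return elevation above the horizon in degrees (no refraction; fold
#'   refraction into a calibrated sun angle instead).
#' @export
solar_elevation <- function(doy_frac, lat, lon) {
  decl <- .deg2rad(solar_declination(doy_frac))
  eqt <- equation_of_time(doy_frac)
  min_utc <- (doy_frac %% 1) * 1440
  tst <- min_utc + eqt + 4 * lon          # true solar time, minutes
  ha <- .deg2rad(tst / 4 - 180)           # hour angle
  latr <- .deg2rad(lat)
  sin_el <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
  .rad2deg(asin(pmin(1, pmax(-1, sin_el))))
}

#' Closed-form day length at a reference sun angle
#'
#' Time between the sun crossing `sun_angle` on the way up and on the way
#' down, from the standard sunrise equation.
#'
#' @param doy day-of-year (may be fractional; declination taken at local noon
#'   of that day).
#' @param lat latitude in degrees.
#' @param sun_angle reference elevation in degrees (negative = below horizon).
#' @return day length in hours; 0 for polar night, 24 for polar day.
#' @export
solar_day_length <- function(doy, lat, sun_angle = 0) {
  decl <- .deg2rad(solar_declination(doy + 0.5))
  latr <- .deg2rad(lat)
  cos_h0 <- (sin(.deg2rad(sun_angle)) - sin(latr) * sin(decl)) /
    (cos(latr) * cos(decl))
  ifelse(cos_h0 > 1, 0, ifelse(cos_h0 < -1, 24, 2 * .rad2deg(acos(cos_h0)) / 15))
}

#' Logger light response used by the trace simulator
#'
#' Clipped linear mapping from solar elevation to light units on a 0-64
#' scale. A reading of 2 units (the conventional twilight threshold)
#' corresponds to a sun elevation of about -3.1 degrees, inside the 3.0-3.6
#' degrees-below-horizon range typical of calibrated leg-mounted loggers.
#' Absolute units are arbitrary: all downstream processing is
#' threshold-based, so only monotonicity matters.
#'
#' @param elevation solar elevation in degrees.
#' @return light level in arbitrary units, 0-64.
#' @export
light_from_elevation <- function(elevation) {
  e_dark <- -3.5
  e_bright <- 8.5
  64 * pmin(1, pmax(0, (elevation - e_dark) / (e_bright - e_dark)))
}

# POSIXct (UTC) -> fractional day-of-year, 1 = 00:00 UTC 1 Jan.
.doy_frac <- function(time) {
  yr <- as.integer(format(time, "%Y", tz = "UTC"))
  jan1 <- as.POSIXct(paste0(yr, "-01-01"), tz = "UTC")
  as.numeric(difftime(time, jan1, units = "days")) + 1
}

# year + fractional doy -> POSIXct UTC
.doy_to_time <- function(year, doy_frac) {
  jan1 <- as.POSIXct(paste0(year, "-01-01"), tz = "UTC")
  jan1 + (doy_frac - 1) * 86400
}
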