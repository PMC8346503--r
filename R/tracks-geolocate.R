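# Threshold light-level geolocation: twilight times from threshold
# crossings; longitude from the sunrise/sunset midpoint vs solar time;
# latitude by inverting the day-length relation at a calibrated sun angle.

#' Find twilight times by threshold crossing
#'
#' Linear interpolation between samples gives sub-interval crossing times.
#'
#' @param trace data.frame with `timestamp`, `light`.
#' @param light_threshold threshold in the logger's arbitrary units.
#' @return data.frame `time` (POSIXct), `rise` (TRUE for a sunrise-direction
#'   crossing).
#' @export
find_twilights <- function(trace, light_threshold = 2) {
  .check_trace(trace)
  above <- trace$light >= light_threshold
  ix <- which(diff(above) != 0)
  if (length(ix) == 0) {
    return(data.frame(time = as.POSIXct(character(), tz = "UTC"),
                      rise = logical()))
  }
  t1 <- as.numeric(trace$timestamp[ix]); t2 <- as.numeric(trace$timestamp[ix + 1])
  l1 <- trace$light[ix]; l2 <- trace$light[ix + 1]
  frac <- (light_threshold - l1) / (l2 - l1)
  data.frame(time = as.POSIXct(t1 + frac * (t2 - t1),
                               origin = "1970-01-01", tz = "UTC"),
             rise = !above[ix])
}

#' Calibrate the reference sun angle at a known location
#'
#' The calibrated angle is the median solar elevation at the known site at
#' the detected twilight times; atmospheric refraction and the logger's
#' response are folded into this one number.
#'
#' @param trace data.frame with `timestamp`, `light` (bird stationary at the
#'   known site over the calibration period).
#' @param lat,lon known position, degrees.
#' @param light_threshold twilight threshold.
#' @return list `sun_angle` (degrees, typically negative), `n_twilights`.
#' @export
calibrate_sun_angle <- function(trace, lat, lon, light_threshold = 2) {
  tw <- find_twilights(trace, light_threshold)
  if (nrow(tw) == 0) stop("no twilights in calibration period")
  el <- solar_elevation(.doy_frac(tw$time), lat, lon)
  list(sun_angle = stats::median(el), n_twilights = nrow(tw))
}

# latitude from day length: solve sin(a) = sin(lat)sin(d) + cos(lat)cos(d)cos(h0)
.lat_from_daylength <- function(day_length_h, decl, sun_angle, lat_range) {
  h0 <- .deg2rad(day_length_h * 15 / 2)
  f <- function(lat) {
    latr <- .deg2rad(lat)
    sin(latr) * sin(.deg2rad(decl)) +
      cos(latr) * cos(.deg2rad(decl)) * cos(h0) - sin(.deg2rad(sun_angle))
  }
  grid <- seq(lat_range[1], lat_range[2], by = 0.5)
  fg <- vapply(grid, f, numeric(1))
  sgn <- which(diff(sign(fg)) != 0)
  if (length(sgn) == 0) return(NA_real_)
  if (length(sgn) > 1) return(NA_real_)  # ambiguous within range
  stats::uniroot(f, c(grid[sgn], grid[sgn + 1]), tol = 1e-6)$root
}

#' Threshold geolocation of a stationary period
#'
#' For each day in the window with a sunrise followed by a sunset, estimates
#' longitude from the solar-noon midpoint and latitude by inverting the
#' day-length relation at the calibrated sun angle. Days without twilight
#' crossings (24-h daylight) are skipped; near the equinox
#' (`|declination| < min_decl`) day length carries no latitude information
#' and latitude is flagged inestimable while longitude is still returned.
#' The location estimate is the median of daily positions with a 95% extent.
#'
#' @param trace data.frame with `timestamp`, `light`.
#' @param sun_angle calibrated reference sun elevation, degrees (from
#'   [calibrate_sun_angle()]).
#' @param window optional `c(first_doy, last_doy)` restricting estimation to
#'   a stationary period; default uses the whole trace.
#' @param light_threshold twilight threshold.
#' @param lat_range latitudes searched when inverting day length.
#' @param min_decl |solar declination| below which latitude is inestimable.
#' @param split_lat latitude of the North/South region boundary.
#' @return list of class `breeding_location`: `lat`, `lon`, `lat_ci`,
#'   `lon_ci` (95% extents), `region`, `daily` (per-day estimates with
#'   `equinox` flags), `n_days`, `sun_angle`.
#' @export
threshold_geolocate <- function(trace, sun_angle, window = NULL,
                                light_threshold = 2, lat_range = c(-60, 75),
                                min_decl = 1, split_lat = 64) {
  tw <- find_twilights(trace, light_threshold)
  if (!is.null(window)) {
    dd <- floor(.doy_frac(tw$time))
    tw <- tw[dd >= window[1] & dd <= window[2], , drop = FALSE]
  }
  daily <- list()
  rises <- which(tw$rise)
  for (i in rises) {
    if (i + 1 > nrow(tw) || tw$rise[i + 1]) next
    sr <- tw$time[i]; ss <- tw$time[i + 1]
    mid <- sr + (as.numeric(ss) - as.numeric(sr)) / 2
    doy_mid <- .doy_frac(mid)
    eqt <- equation_of_time(doy_mid)
    min_utc <- (doy_mid %% 1) * 1440
    lon <- (720 - eqt - min_utc) / 4
    lon <- ((lon + 180) %% 360) - 180
    decl <- solar_declination(doy_mid)
    dl <- as.numeric(difftime(ss, sr, units = "hours"))
    equinox <- abs(decl) < min_decl
    lat <- if (equinox) NA_real_ else {
      .lat_from_daylength(dl, decl, sun_angle, lat_range)
    }
    daily[[length(daily) + 1]] <- data.frame(
      doy = floor(doy_mid), lat = lat, lon = lon, day_length_h = dl,
      declination = decl, equinox = equinox)
  }
  if (length(daily) == 0) {
    return(structure(list(lat = NA_real_, lon = NA_real_,
                          lat_ci = c(NA_real_, NA_real_),
                          lon_ci = c(NA_real_, NA_real_), region = NA_character_,
                          daily = data.frame(), n_days = 0L,
                          sun_angle = sun_angle),
                     class = "breeding_location"))
  }
  daily <- do.call(rbind, daily)
  lat_est <- stats::median(daily$lat, na.rm = TRUE)
  lon_est <- stats::median(daily$lon, na.rm = TRUE)
  qr <- function(x) if (all(is.na(x))) c(NA_real_, NA_real_) else
    unname(stats::quantile(x, c(0.025, 0.975), na.rm = TRUE))
  structure(list(lat = lat_est, lon = lon_est,
                 lat_ci = qr(daily$lat), lon_ci = qr(daily$lon),
                 region = assign_region(lat_est, lon_est, split_lat = split_lat),
                 daily = daily, n_days = nrow(daily), sun_angle = sun_angle),
            class = "breeding_location")
}

#' Assign a breeding region from latitude
#'
#' Strict comparison at the split latitude (64 N by default): above is
#' North, below is South, exactly on it is `"Boundary"`. When latitude is
#' missing but the longitude evidence places the bird well east along the
#' Arctic coast (loggers saturated in 24-h daylight), a North override is
#' permitted.
#'
#' @param lat latitude, degrees (may be `NA`).
#' @param lon optional longitude used only for the missing-latitude Arctic
#'   override.
#' @param split_lat boundary latitude.
#' @param arctic_lon_east_of longitude (degrees, negative = west) east of
#'   which a missing-latitude bird is assumed a northern breeder.
#' @return `"North"`, `"South"`, `"Boundary"`, or `NA`.
#' @export
assign_region <- function(lat, lon = NA, split_lat = 64,
                          arctic_lon_east_of = -160) {
  if (is.na(lat)) {
    if (!is.na(lon) && lon > arctic_lon_east_of && lon < 0) return("North")
    return(NA_character_)
  }
  if (lat > split_lat) "North" else if (lat < split_lat) "South" else "Boundary"
}
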