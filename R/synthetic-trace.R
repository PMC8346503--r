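# Synthetic geolocator traces: light follows solar elevation at the bird's
# (piecewise) position; conductivity is wet at tidal cadence on land and dry
# in flight. Ground-truth event times ride along for parameter recovery.

# fixed geography of the simulated flyway
.NZ_SITE <- c(lat = -40.47, lon = 175.22)   # non-breeding estuary
.YS_SITE <- c(lat = 37.0, lon = 122.0)      # Yellow Sea stopover

#' Specification for a synthetic geolocator trace
#'
#' One bird-year: pre-migration residence at the New Zealand non-breeding
#' site, a long non-stop flight to the Yellow Sea, a stopover, a second
#' flight to the Alaska breeding site, and (optionally) daily incubation
#' shading bouts starting some days after arrival.
#'
#' @param year calendar year of the northward migration.
#' @param sampling_interval logger sampling interval in minutes; must divide
#'   24 h.
#' @param start_doy first day-of-year of the trace (bird at the NZ site).
#' @param flight1_start departure from New Zealand as a fractional
#'   day-of-year (e.g. 79.5 = noon UTC on day 79).
#' @param flight1_duration,flight2_duration non-stop flight durations in
#'   days; must exceed 3 d (the published flights run ~6-9 d).
#' @param stopover_duration Yellow Sea stopover length in days.
#' @param incubation_start_offset days after Alaska arrival at which
#'   incubation begins (published tracks: within 6-25 d of arrival).
#' @param incubation_bout_hours daily incubation shading bout length, hours;
#'   validated against the published 4-13 h range unless
#'   `check_bout_range = FALSE` (useful for testing that out-of-range bouts
#'   are never called as incubation).
#' @param incubation_days number of consecutive incubation days (0 = none).
#' @param site_lat,site_lon Alaska breeding site, degrees.
#' @param noise_wet_prob probability that an in-flight reading is a spurious
#'   wet.
#' @param noise_light_sd SD of additive light noise (arbitrary units).
#' @param end_doy last day-of-year of the trace; default covers incubation
#'   plus 5 d.
#' @param check_bout_range validate `incubation_bout_hours` in [4, 13].
#' @param seed integer seed.
#' @return an object of class `trace_spec`.
#' @export
trace_spec <- function(year = 2013, sampling_interval = 10, start_doy = 45,
                       flight1_start = 79.5, flight1_duration = 7.5,
                       stopover_duration = 40, flight2_duration = 7,
                       incubation_start_offset = 12, incubation_bout_hours = 8,
                       incubation_days = 20, site_lat = 62, site_lon = -162,
                       noise_wet_prob = 0.02, noise_light_sd = 0,
                       end_doy = NULL, check_bout_range = TRUE, seed = 1L) {
  if ((1440 %% sampling_interval) != 0) stop("sampling_interval must divide 24 h")
  if (flight1_duration <= 3 || flight2_duration <= 3) {
    stop("flight durations must exceed 3 d")
  }
  if (incubation_days > 0 && check_bout_range &&
      (incubation_bout_hours < 4 || incubation_bout_hours > 13)) {
    stop("incubation_bout_hours must lie in [4, 13] h")
  }
  if (stopover_duration < 0 || incubation_days < 0) stop("durations must be >= 0")
  ys_arr <- flight1_start + flight1_duration
  ys_dep <- ys_arr + stopover_duration
  ak_arr <- ys_dep + flight2_duration
  if (flight1_start <= start_doy) stop("flight1 must start after start_doy")
  inc_start <- if (incubation_days > 0) floor(ak_arr) + incubation_start_offset else NA_real_
  if (is.null(end_doy)) {
    end_doy <- max(ak_arr + 5, if (incubation_days > 0) inc_start + incubation_days + 5 else 0)
  }
  if (!is.na(inc_start) && inc_start < ak_arr) stop("incubation overlaps flight 2")
  structure(list(year = as.integer(year), sampling_interval = sampling_interval,
                 start_doy = start_doy, flight1_start = flight1_start,
                 flight1_duration = flight1_duration,
                 stopover_duration = stopover_duration,
                 flight2_duration = flight2_duration,
                 incubation_start_offset = incubation_start_offset,
                 incubation_bout_hours = incubation_bout_hours,
                 incubation_days = incubation_days,
                 site_lat = site_lat, site_lon = site_lon,
                 noise_wet_prob = noise_wet_prob,
                 noise_light_sd = noise_light_sd, end_doy = end_doy,
                 seed = as.integer(seed)),
            class = "trace_spec")
}

#' Generate a synthetic geolocator trace
#'
#' Builds the light and wet/dry channels at the spec's sampling interval.
#' Light is the clipped, scaled solar-elevation response of
#' [light_from_elevation()] at the bird's current position (linearly
#' interpolated along flights), with incubation bouts forced dark. The
#' conductivity channel is wet at tidal cadence (12.42 h cycle) on land and
#' dry in flight apart from `noise_wet_prob` spurious wets; readings in the
#' 3 h bracketing each flight are forced wet (birds forage on intertidal
#' flats immediately before departure and after arrival), so ground-truth
#' flight boundaries are recoverable to the sampling interval.
#'
#' @param spec a [trace_spec()].
#' @return list with elements `trace` (data.frame `timestamp`, `light`,
#'   `wet`) and `truth` (ground-truth event times: fractional instants
#'   `nzdep`, `ysarr`, `ysdep`, `akarr`; whole-day `NZdep`, `YSarr`, `YSdep`,
#'   `AKarr`, `YSdur`, `IncSt`).
#' @export
generate_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  withr::with_seed(spec$seed, {
    step <- spec$sampling_interval / 1440          # days
    doy <- seq(spec$start_doy, spec$end_doy, by = step)
    n <- length(doy)
    t1s <- spec$flight1_start
    t1e <- t1s + spec$flight1_duration
    t2s <- t1e + spec$stopover_duration
    t2e <- t2s + spec$flight2_duration

    # piecewise position
    lat <- numeric(n); lon <- numeric(n)
    seg <- findInterval(doy, c(t1s, t1e, t2s, t2e))
    f1 <- (doy - t1s) / spec$flight1_duration
    f2 <- (doy - t2s) / spec$flight2_duration
    lat <- ifelse(seg == 0, .NZ_SITE["lat"],
           ifelse(seg == 1, .NZ_SITE["lat"] + f1 * (.YS_SITE["lat"] - .NZ_SITE["lat"]),
           ifelse(seg == 2, .YS_SITE["lat"],
           ifelse(seg == 3, .YS_SITE["lat"] + f2 * (spec$site_lat - .YS_SITE["lat"]),
                  spec$site_lat))))
    # go westwards across the dateline: NZ 175E -> YS 122E is a real westward
    # hop; YS 122E -> AK -162 crosses 180, interpolate via +198
    lon_ak <- if (spec$site_lon < 0) spec$site_lon + 360 else spec$site_lon
    lon <- ifelse(seg == 0, .NZ_SITE["lon"],
           ifelse(seg == 1, .NZ_SITE["lon"] + f1 * (.YS_SITE["lon"] - .NZ_SITE["lon"]),
           ifelse(seg == 2, .YS_SITE["lon"],
           ifelse(seg == 3, .YS_SITE["lon"] + f2 * (lon_ak - .YS_SITE["lon"]),
                  lon_ak))))
    lon <- ifelse(lon > 180, lon - 360, lon)

    light <- light_from_elevation(solar_elevation(doy, lat, lon))
    if (spec$noise_light_sd > 0) {
      light <- pmax(0, light + stats::rnorm(n, 0, spec$noise_light_sd))
    }

    # incubation shading: one daytime bout per day, centred on local noon
    inc_start_day <- NA_real_
    if (spec$incubation_days > 0) {
      inc_start_day <- floor(t2e) + spec$incubation_start_offset
      noon_utc_frac <- (12 - spec$site_lon / 15) / 24   # local solar noon, UTC
      half <- spec$incubation_bout_hours / 48           # half bout in days
      for (k in seq_len(spec$incubation_days) - 1) {
        centre <- inc_start_day + k + noon_utc_frac
        light[doy >= centre - half & doy < centre + half] <- 0
      }
    }

    in_flight <- (doy >= t1s & doy < t1e) | (doy >= t2s & doy < t2e)
    tide <- sin(2 * pi * doy / (12.42 / 24)) > 0
    wet <- ifelse(in_flight,
                  as.integer(stats::runif(n) < spec$noise_wet_prob),
                  as.integer(tide))
    margin <- 3 / 24
    near_bound <- (doy >= t1s - margin & doy < t1s) |
      (doy >= t1e & doy < t1e + margin) |
      (doy >= t2s - margin & doy < t2s) |
      (doy >= t2e & doy < t2e + margin)
    wet[near_bound] <- 1L

    trace <- data.frame(timestamp = .doy_to_time(spec$year, doy),
                        light = light, wet = wet)
    truth <- list(nzdep = t1s, ysarr = t1e, ysdep = t2s, akarr = t2e,
                  NZdep = floor(t1s), YSarr = floor(t1e),
                  YSdep = floor(t2s), AKarr = floor(t2e),
                  YSdur = floor(t2s) - floor(t1e),
                  IncSt = if (spec$incubation_days > 0) inc_start_day else NA_real_,
                  site_lat = spec$site_lat, site_lon = spec$site_lon)
    list(trace = trace, truth = truth)
  })
}
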