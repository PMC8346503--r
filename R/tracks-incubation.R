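# Incubation detection from daytime shading of a leg-mounted logger.
# During incubation the unit is shaded by the sitting bird for semi-regular
# bouts of 4-13 h overlaid on the day/night light pattern.

#' Detect the start of incubation from light shading
#'
#' A shading event is a maximal run of sub-threshold light. Events are
#' classified as night or shading by their clock-time midpoint: the night
#' anchor is the median midpoint of dark runs on the baseline days between
#' arrival and the opening of the search window; if those days have no dark
#' runs (24-h daylight, as north of 64 N) every dark run in the window is a
#' candidate shading event. An event qualifies when its duration lies in
#' `bout_range` (with one sampling interval of slack at each end, the
#' measurement resolution). Qualifying events within 36 h of each other form
#' runs of consecutive incubation days; incubation start (`IncSt`) is the
#' whole day-of-year of the first event of the first run of at least
#' `min_consecutive_days` events whose start lies within `search_window`
#' days of arrival.
#'
#' @param trace data.frame with columns `timestamp`, `light`, `wet`.
#' @param AKarr Alaska arrival day-of-year (whole day).
#' @param bout_range qualifying bout durations, hours.
#' @param min_consecutive_days minimum consecutive qualifying days.
#' @param search_window days after arrival within which incubation may start.
#' @param light_threshold light level below which the logger counts as dark.
#' @param night_tol_hours events with midpoints within this clock-time
#'   distance of the night anchor are treated as night.
#' @return list with `IncSt` (day-of-year or `NA`) and `status`:
#'   `"detected"`, `"absent"`, or `"undetermined"` (trace ends before the
#'   search window closes).
#' @export
detect_incubation <- function(trace, AKarr, bout_range = c(4, 13),
                              min_consecutive_days = 3,
                              search_window = c(6, 25),
                              light_threshold = 2, night_tol_hours = 3) {
  .check_trace(trace)
  step_h <- .trace_interval_days(trace) * 24
  doy <- .doy_frac(trace$timestamp)
  sub <- trace[doy >= AKarr, , drop = FALSE]
  doy <- doy[doy >= AKarr]
  trace_end <- if (length(doy)) max(doy) else AKarr
  undetermined <- trace_end < AKarr + search_window[2]
  none <- list(IncSt = NA_real_,
               status = if (undetermined) "undetermined" else "absent")
  if (nrow(sub) < 2) return(none)

  dark <- sub$light < light_threshold
  r <- rle(dark)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  di <- which(r$values)
  if (length(di) == 0) return(none)
  ev <- data.frame(start_doy = doy[starts[di]],
                   dur_h = r$lengths[di] * step_h)
  ev$mid_tod <- ((ev$start_doy + ev$dur_h / 48) %% 1) * 24  # clock h of midpoint

  # night anchor from baseline days before the search window opens
  base <- ev[ev$start_doy < AKarr + search_window[1], , drop = FALSE]
  is_night <- rep(FALSE, nrow(ev))
  if (nrow(base) > 0) {
    anchor <- stats::median(base$mid_tod)
    dist <- abs(ev$mid_tod - anchor)
    dist <- pmin(dist, 24 - dist)  # circular clock distance
    is_night <- dist < night_tol_hours
  }
  slack <- step_h
  qual <- !is_night &
    ev$dur_h >= bout_range[1] - slack & ev$dur_h <= bout_range[2] + slack &
    ev$start_doy >= AKarr + search_window[1]
  ev <- ev[qual, , drop = FALSE]
  if (nrow(ev) == 0) return(none)
  ev <- ev[order(ev$start_doy), , drop = FALSE]
  run_id <- cumsum(c(1, diff(ev$start_doy) > 1.5))  # new run if gap > 36 h
  for (rid in unique(run_id)) {
    rr <- ev[run_id == rid, , drop = FALSE]
    if (nrow(rr) >= min_consecutive_days &&
        rr$start_doy[1] <= AKarr + search_window[2]) {
      return(list(IncSt = floor(rr$start_doy[1]), status = "detected"))
    }
  }
  none
}
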