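# Conductivity-based flight detection and migration timing. Extended dry
# runs in the wet/dry channel identify the non-stop over-water flights; the
# first two long flights of the northward season bracket the Yellow Sea
# stopover.

.trace_interval_days <- function(trace) {
  dt <- diff(as.numeric(trace$timestamp))
  if (length(dt) == 0) stop("trace too short")
  if (max(dt) - min(dt) > 1e-6) stop("trace must have a constant sampling interval")
  dt[1] / 86400
}

.check_trace <- function(trace) {
  need <- c("timestamp", "light", "wet")
  if (!all(need %in% names(trace))) {
    stop("trace needs columns ", paste(need, collapse = ", "))
  }
  if (is.unsorted(trace$timestamp, strictly = TRUE)) {
    stop("timestamps must be strictly increasing")
  }
  invisible(trace)
}

#' Detect non-stop flights from the conductivity channel
#'
#' Finds maximal dry runs: wet gaps shorter than `bridge_hours` (isolated
#' spurious wets from rain or spray) are closed first, then contiguous dry
#' runs of at least `min_duration_days` whose fraction of originally dry
#' readings is at least `purity` are returned in time order.
#'
#' @param trace data.frame with columns `timestamp` (POSIXct UTC, constant
#'   interval), `light`, `wet` (1/0).
#' @param min_duration_days minimum dry-run length to call a flight. 3 d
#'   separates the ~6-9 d migratory flights from roost-dry spells.
#' @param purity minimum fraction of dry readings within a run.
#' @param bridge_hours wet gaps shorter than this are bridged.
#' @return data.frame with one row per flight: `start`, `end` (POSIXct),
#'   `duration_days`, `dry_fraction`; zero rows if no flight qualifies.
#' @export
detect_flights <- function(trace, min_duration_days = 3, purity = 0.95,
                           bridge_hours = 2) {
  .check_trace(trace)
  out0 <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                     end = as.POSIXct(character(), tz = "UTC"),
                     duration_days = numeric(), dry_fraction = numeric())
  if (nrow(trace) < 2 || all(trace$wet == 1)) return(out0)
  step <- .trace_interval_days(trace)
  dry <- trace$wet == 0
  r <- rle(dry)
  # bridge short wet runs that are flanked by dry on both sides
  nrun <- length(r$values)
  if (nrun >= 3) {
    bridge <- !r$values & (r$lengths * step * 24 < bridge_hours)
    bridge[c(1, nrun)] <- FALSE
    idx <- which(bridge)
    idx <- idx[r$values[idx - 1] & r$values[idx + 1]]
    r$values[idx] <- TRUE
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  flights <- list()
  for (i in which(r$values)) {
    len_days <- r$lengths[i] * step
    if (len_days < min_duration_days) next
    ix <- starts[i]:ends[i]
    dfrac <- mean(dry[ix])
    if (dfrac < purity) next
    flights[[length(flights) + 1]] <- data.frame(
      start = trace$timestamp[starts[i]],
      end = trace$timestamp[ends[i]] + step * 86400,
      duration_days = len_days, dry_fraction = dfrac)
  }
  if (length(flights) == 0) return(out0)
  out <- do.call(rbind, flights)
  out[order(out$start), , drop = FALSE]
}

#' Derive migration timing from detected flights
#'
#' The first qualifying flight of the northward season gives departure from
#' New Zealand (`NZdep`, flight start) and Yellow Sea arrival (`YSarr`,
#' flight end); the second gives Yellow Sea departure (`YSdep`) and first
#' Alaska arrival (`AKarr`). Stopover duration `YSdur = YSdep - YSarr`.
#' Dates are whole days-of-year (1 = 1 January, UTC, fractional days
#' floored). With more than two qualifying flights the longest two are used
#' (with a warning); with fewer, the missing fields are `NA`.
#'
#' @param flights data.frame from [detect_flights()].
#' @param season_bounds optional `c(first_doy, last_doy)` window; only
#'   flights starting inside it are considered.
#' @return list of class `migration_timing` with `NZdep`, `YSarr`, `YSdep`,
#'   `AKarr`, `YSdur`, `IncSt` (NA here; filled by [detect_incubation()]),
#'   and `n_flights_used`.
#' @export
derive_timing <- function(flights, season_bounds = NULL) {
  if (!is.null(season_bounds) && nrow(flights) > 0) {
    sd_ <- floor(.doy_frac(flights$start))
    flights <- flights[sd_ >= season_bounds[1] & sd_ <= season_bounds[2], ,
                       drop = FALSE]
  }
  if (nrow(flights) > 2) {
    warning(nrow(flights), " qualifying flights; using the longest two")
    flights <- flights[order(-flights$duration_days)[1:2], , drop = FALSE]
    flights <- flights[order(flights$start), , drop = FALSE]
  }
  tm <- list(NZdep = NA_real_, YSarr = NA_real_, YSdep = NA_real_,
             AKarr = NA_real_, YSdur = NA_real_, IncSt = NA_real_,
             n_flights_used = nrow(flights))
  if (nrow(flights) >= 1) {
    tm$NZdep <- floor(.doy_frac(flights$start[1]))
    tm$YSarr <- floor(.doy_frac(flights$end[1]))
  }
  if (nrow(flights) >= 2) {
    tm$YSdep <- floor(.doy_frac(flights$start[2]))
    tm$AKarr <- floor(.doy_frac(flights$end[2]))
    tm$YSdur <- tm$YSdep - tm$YSarr
  }
  class(tm) <- "migration_timing"
  validate_timing(tm)
  tm
}

#' Validate the ordering invariant of a migration timing record
#'
#' `NZdep < YSarr <= YSdep < AKarr` within one season, `YSdur >= 0`, and
#' `IncSt >= AKarr` when present. Missing fields are skipped.
#'
#' @param tm a `migration_timing` list.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_timing <- function(tm) {
  ok <- function(a, b, strict = TRUE) {
    is.na(a) || is.na(b) || (if (strict) a < b else a <= b)
  }
  if (!ok(tm$NZdep, tm$YSarr)) stop("ordering violated: NZdep >= YSarr")
  if (!ok(tm$YSarr, tm$YSdep, strict = FALSE)) stop("ordering violated: YSarr > YSdep")
  if (!ok(tm$YSdep, tm$AKarr)) stop("ordering violated: YSdep >= AKarr")
  if (!is.na(tm$YSdur) && tm$YSdur < 0) stop("YSdur < 0")
  if (!is.na(tm$IncSt) && !is.na(tm$AKarr) && tm$IncSt < tm$AKarr) {
    stop("IncSt before AKarr")
  }
  invisible(TRUE)
}
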