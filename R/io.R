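# Plain-CSV readers/writers for the three data streams. Schemas:
#   panel: id, year, depart_doy, observed (1/0)
#   trace: timestamp (ISO-8601 UTC), light, wet (1/0)
#   grid:  cell_id, lat, lon, year, doy, value, channel (snow|ndvi)

#' Write / read a departure panel CSV
#'
#' @param panel data.frame with columns `id`, `year`, `depart_doy`,
#'   `observed`.
#' @param path file path.
#' @return `read_departure_panel` returns the panel data.frame.
#' @export
write_departure_panel <- function(panel, path) {
  utils::write.csv(panel[c("id", "year", "depart_doy", "observed")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_departure_panel
#' @export
read_departure_panel <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_panel(p)
  p
}

#' Write / read a geolocator trace CSV
#'
#' @param trace data.frame with columns `timestamp`, `light`, `wet`.
#' @param path file path.
#' @return `read_trace` returns the trace with POSIXct UTC timestamps.
#' @export
write_trace <- function(trace, path) {
  out <- trace
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out[c("timestamp", "light", "wet")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  tr$timestamp <- as.POSIXct(tr$timestamp, format = "%Y-%m-%dT%H:%M:%OSZ",
                             tz = "UTC")
  .check_trace(tr)
  tr
}

#' Write / read a phenology grid CSV
#'
#' @param grid long data.frame with columns `cell_id`, `lat`, `lon`, `year`,
#'   `doy`, `value`, `channel`.
#' @param path file path.
#' @return `read_phenology_grid` returns the grid data.frame.
#' @export
write_phenology_grid <- function(grid, path) {
  utils::write.csv(grid[c("cell_id", "lat", "lon", "year", "doy", "value",
                          "channel")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenology_grid
#' @export
read_phenology_grid <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(g$channel %in% c("snow", "ndvi")))
  g
}
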