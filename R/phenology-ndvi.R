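# NDVI green-up (start of season): penalized cubic smoothing spline through
# the focal cell's weekly NDVI pooled with neighbours within 15 km
# (Gaussian distance weights, SD 4 km), interpolated daily on
# neighbourhood-snow-free days; green-up is the first day the rising curve
# exceeds its start by 15% of the start-to-maximum amplitude.

#' Great-circle distance
#'
#' @param lat1,lon1,lat2,lon2 degrees.
#' @return distance in km (haversine, R = 6371 km).
#' @export
gc_distance_km <- function(lat1, lon1, lat2, lon2) {
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dphi <- .deg2rad(lat2 - lat1); dl <- .deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Fit the green-up date for a focal cell
#'
#' @param focal list or data.frame for the focal cell with `lat`, `lon` and
#'   observations `doy`, `value` (weekly NDVI).
#' @param neighbors optional list of neighbour cells with the same fields;
#'   those within `radius_km` contribute with Gaussian distance weights.
#' @param snow_free_doys optional integer days on which at least one cell in
#'   the neighbourhood was snow-free; daily interpolation is restricted to
#'   these (default: all days spanned by the observations).
#' @param radius_km neighbourhood radius.
#' @param sd_km SD of the Gaussian distance weighting.
#' @param threshold_frac green-up threshold as a fraction of the
#'   start-to-maximum amplitude.
#' @param min_obs minimum pooled observations.
#' @param min_df floor on the spline's effective degrees of freedom (guards
#'   against flat GCV fits on sparse weekly data).
#' @param amplitude_tol amplitudes below this leave green-up undefined.
#' @return list of class `greenup_fit`: `greenup_doy`, `max_doy`,
#'   `start_doy`, `start_value`, `max_value`, `amplitude`, `spline_df`,
#'   `n_obs`, `n_neighbors`.
#' @export
fit_greenup <- function(focal, neighbors = NULL, snow_free_doys = NULL,
                        radius_km = 15, sd_km = 4, threshold_frac = 0.15,
                        min_obs = 4, min_df = 4, amplitude_tol = 1e-3) {
  pool_doy <- focal$doy; pool_val <- focal$value
  pool_w <- rep(1, length(focal$doy))
  n_used <- 0L
  if (!is.null(neighbors)) {
    for (nb in neighbors) {
      d <- gc_distance_km(focal$lat, focal$lon, nb$lat, nb$lon)
      if (!is.finite(d) || d > radius_km) next
      w <- exp(-d^2 / (2 * sd_km^2))
      pool_doy <- c(pool_doy, nb$doy)
      pool_val <- c(pool_val, nb$value)
      pool_w <- c(pool_w, rep(w, length(nb$doy)))
      n_used <- n_used + 1L
    }
  }
  keep <- is.finite(pool_val) & is.finite(pool_doy)
  pool_doy <- pool_doy[keep]; pool_val <- pool_val[keep]; pool_w <- pool_w[keep]
  if (length(pool_doy) < min_obs) {
    stop("fewer than ", min_obs, " usable NDVI observations in the neighbourhood")
  }
  if (is.null(snow_free_doys)) {
    snow_free_doys <- seq(ceiling(min(pool_doy)), floor(max(pool_doy)))
  }
  snow_free_doys <- sort(unique(as.integer(snow_free_doys)))
  snow_free_doys <- snow_free_doys[snow_free_doys >= min(pool_doy) &
                                     snow_free_doys <= max(pool_doy)]
  if (length(snow_free_doys) == 0) {
    stop("no snow-free days in the neighbourhood: green-up undefined")
  }
  sp <- stats::smooth.spline(pool_doy, pool_val, w = pool_w, cv = FALSE)
  if (sp$df < min_df) {
    sp <- stats::smooth.spline(pool_doy, pool_val, w = pool_w, df = min_df)
  }
  pred <- stats::predict(sp, snow_free_doys)$y
  i_max <- which.max(pred)
  max_doy <- snow_free_doys[i_max]
  rising <- seq_len(i_max)
  i_min <- which.min(pred[rising])
  start_doy <- snow_free_doys[i_min]
  start_value <- pred[i_min]
  amplitude <- pred[i_max] - start_value
  greenup <- NA_real_
  if (amplitude > amplitude_tol) {
    thr <- start_value + threshold_frac * amplitude
    limb <- rising[rising >= i_min]
    hit <- limb[pred[limb] > thr]
    if (length(hit)) greenup <- snow_free_doys[hit[1]]
  }
  structure(list(greenup_doy = greenup, max_doy = max_doy,
                 start_doy = start_doy, start_value = start_value,
                 max_value = pred[i_max], amplitude = amplitude,
                 spline_df = sp$df, n_obs = length(pool_doy),
                 n_neighbors = n_used),
            class = "greenup_fit")
}
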