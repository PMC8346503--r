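# Synthetic gridded breeding-range phenology: daily binary snow status and
# weekly NDVI per 4x4 km cell, with latitude-dependent timing, a linear year
# trend, and cell-year weather noise. Ground-truth snowmelt (1/3-crossing)
# and green-up (15%-of-amplitude) dates are returned per cell-year.

#' Specification for a synthetic phenology grid
#'
#' Each cell-year has an asymmetric-Gaussian snow-free probability curve
#' \deqn{s(t) = p_{max} \exp(-\tfrac12 ((t-\mu)/\sigma)^2)}
#' with \eqn{\sigma = \sigma_L} left of the peak and \eqn{\sigma_R} right of
#' it; daily snow status is a Bernoulli draw from \eqn{s(t)}. The true
#' snowmelt date is the analytic first 1/3-crossing
#' \eqn{\mu - \sigma_L \sqrt{2 \ln(3 p_{max})}}. The peak \eqn{\mu} is linear
#' in latitude and year plus cell-year noise (interannual weather). The NDVI
#' seasonal curve is an asymmetric Gaussian whose rising limb crosses
#' baseline + 15% of amplitude at the true green-up date, tied to the cell's
#' snowmelt by a fixed lag plus independent noise; weekly observations add
#' Gaussian noise.
#'
#' @param n_cells number of grid cells.
#' @param lat_range latitude range, degrees (cells uniform within).
#' @param lon_range longitude range, degrees.
#' @param years integer years.
#' @param p_max peak snow-free probability, in (0, 1].
#' @param melt_mu0 snow-free peak doy at `lat_range[1]` in `years[1]`.
#' @param melt_lat_slope d/degree latitude shift of the peak.
#' @param melt_year_slope d/yr trend of the peak (and hence of snowmelt).
#' @param sigma_left,sigma_right asymmetric-Gaussian widths, days.
#' @param sd_melt_noise SD of cell-year weather noise on the peak, days.
#' @param greenup_lag mean days from snowmelt to green-up.
#' @param sd_greenup_noise SD of green-up noise independent of snowmelt, days.
#' @param ndvi_baseline,ndvi_amplitude NDVI curve baseline and amplitude
#'   (amplitude >= 0).
#' @param ndvi_sigma_left,ndvi_sigma_right NDVI curve widths, days.
#' @param ndvi_noise_sd SD of weekly NDVI observation noise.
#' @param snow_doys days-of-year with daily snow observations.
#' @param ndvi_doys days-of-year with weekly NDVI observations (7-day step).
#' @param seed integer seed.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_cells = 60, lat_range = c(61, 70),
                      lon_range = c(-165, -150), years = 2008:2020,
                      p_max = 1, melt_mu0 = 165, melt_lat_slope = 2.5,
                      melt_year_slope = -0.65, sigma_left = 30,
                      sigma_right = 60, sd_melt_noise = 5,
                      greenup_lag = 8, sd_greenup_noise = 3,
                      ndvi_baseline = 0.08, ndvi_amplitude = 0.5,
                      ndvi_sigma_left = 25, ndvi_sigma_right = 40,
                      ndvi_noise_sd = 0.02,
                      snow_doys = 1:365, ndvi_doys = seq(32, 300, by = 7),
                      seed = 1L) {
  if (p_max <= 0 || p_max > 1) stop("p_max must be in (0, 1]")
  if (ndvi_amplitude < 0) stop("NDVI amplitude must be >= 0")
  if (sigma_left <= 0 || sigma_right <= 0) stop("sigmas must be > 0")
  if (length(ndvi_doys) > 1 && any(diff(ndvi_doys) != 7)) {
    stop("ndvi_doys must be weekly (7-day step)")
  }
  structure(as.list(environment()), class = "grid_spec")
}

# asymmetric Gaussian evaluated at t
.asym_gauss <- function(t, peak, mu, sL, sR) {
  s <- ifelse(t < mu, sL, sR)
  peak * exp(-0.5 * ((t - mu) / s)^2)
}

# first 1/3-crossing of the rising limb; NA if the curve never reaches 1/3
.snow_crossing <- function(p_max, mu, sL, threshold = 1 / 3) {
  if (p_max <= threshold) return(NA_real_)
  mu - sL * sqrt(2 * log(p_max / threshold))
}

# multiplier q such that the rising limb is at frac of amplitude at
# mu - q * sigma_left (15% default: q = 1.9479)
.rise_mult <- function(frac = 0.15) sqrt(2 * log(1 / frac))

#' Generate a synthetic phenology grid
#'
#' @param spec a [grid_spec()].
#' @return list with `grid` (long data.frame `cell_id`, `lat`, `lon`,
#'   `year`, `doy`, `value`, `channel` in snow|ndvi) and `truth` (per
#'   cell-year `snowmelt` and `greenup` dates).
#' @export
generate_phenology_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  withr::with_seed(spec$seed, {
    cells <- data.frame(
      cell_id = sprintf("C%04d", seq_len(spec$n_cells)),
      lat = stats::runif(spec$n_cells, spec$lat_range[1], spec$lat_range[2]),
      lon = stats::runif(spec$n_cells, spec$lon_range[1], spec$lon_range[2]))
    y0 <- spec$years[1]
    grid_rows <- list(); truth_rows <- list()
    k <- 0L
    for (ci in seq_len(spec$n_cells)) {
      for (yr in spec$years) {
        k <- k + 1L
        mu <- spec$melt_mu0 +
          spec$melt_lat_slope * (cells$lat[ci] - spec$lat_range[1]) +
          spec$melt_year_slope * (yr - y0) +
          stats::rnorm(1, 0, spec$sd_melt_noise)
        melt <- .snow_crossing(spec$p_max, mu, spec$sigma_left)
        snow_free <- stats::rbinom(length(spec$snow_doys), 1,
          .asym_gauss(spec$snow_doys, spec$p_max, mu, spec$sigma_left,
                      spec$sigma_right))
        greenup <- melt + spec$greenup_lag +
          stats::rnorm(1, 0, spec$sd_greenup_noise)
        ndvi_mu <- greenup + .rise_mult(0.15) * spec$ndvi_sigma_left
        ndvi <- spec$ndvi_baseline +
          .asym_gauss(spec$ndvi_doys, spec$ndvi_amplitude, ndvi_mu,
                      spec$ndvi_sigma_left, spec$ndvi_sigma_right) +
          stats::rnorm(length(spec$ndvi_doys), 0, spec$ndvi_noise_sd)
        grid_rows[[k]] <- data.frame(
          cell_id = cells$cell_id[ci], lat = cells$lat[ci], lon = cells$lon[ci],
          year = yr,
          doy = c(spec$snow_doys, spec$ndvi_doys),
          value = c(snow_free, ndvi),
          channel = rep(c("snow", "ndvi"),
                        c(length(spec$snow_doys), length(spec$ndvi_doys))),
          stringsAsFactors = FALSE)
        truth_rows[[k]] <- data.frame(
          cell_id = cells$cell_id[ci], lat = cells$lat[ci], lon = cells$lon[ci],
          year = yr, snowmelt = melt, greenup = greenup,
          stringsAsFactors = FALSE)
      }
    }
    grid <- do.call(rbind, grid_rows); rownames(grid) <- NULL
    truth <- do.call(rbind, truth_rows); rownames(truth) <- NULL
    list(grid = grid, truth = truth)
  })
}
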