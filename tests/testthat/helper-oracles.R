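# Independent oracles and small fixture builders used across the suite.

# Brute-force one-way ANOVA ICC: plain double-loop sums of squares,
# independent of the repeatability() implementation path.
oracle_icc <- function(panel) {
  ids <- unique(panel$id)
  k <- length(ids)
  ni <- numeric(k)
  means <- numeric(k)
  for (j in seq_len(k)) {
    x <- panel$depart_doy[panel$id == ids[j]]
    ni[j] <- length(x)
    means[j] <- sum(x) / length(x)
  }
  N <- sum(ni)
  gm <- sum(panel$depart_doy) / N
  ss_a <- 0; ss_w <- 0
  for (j in seq_len(k)) {
    x <- panel$depart_doy[panel$id == ids[j]]
    ss_a <- ss_a + ni[j] * (means[j] - gm)^2
    for (v in x) ss_w <- ss_w + (v - means[j])^2
  }
  ms_a <- ss_a / (k - 1)
  ms_w <- ss_w / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  list(r = (ms_a - ms_w) / (ms_a + (n0 - 1) * ms_w), F = ms_a / ms_w, n0 = n0)
}

# Closed-form OLS slope via the normal equations.
oracle_ols_slope <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

# Random small panel for oracle-equivalence checks.
random_small_panel <- function(n_ids = 5, max_years = 6) {
  rows <- list()
  for (i in seq_len(n_ids)) {
    yrs <- sort(sample(2008:2020, sample(2:max_years, 1)))
    rows[[i]] <- data.frame(id = sprintf("X%02d", i), year = yrs,
                            depart_doy = round(rnorm(length(yrs), 80, 8)),
                            observed = 1L)
  }
  do.call(rbind, rows)
}

# year + fractional day-of-year -> POSIXct UTC instant
doy_instant <- function(year, doy) {
  as.POSIXct(paste0(year, "-01-01"), tz = "UTC") + (doy - 1) * 86400
}

# Stationary noiseless trace at a fixed site (light only; wet = 1).
stationary_trace <- function(lat, lon, doy0, doy1, year = 2013,
                             interval_min = 10) {
  doy <- seq(doy0, doy1, by = interval_min / 1440)
  data.frame(
    timestamp = as.POSIXct(paste0(year, "-01-01"), tz = "UTC") + (doy - 1) * 86400,
    light = light_from_elevation(solar_elevation(doy, lat, lon)),
    wet = 1L)
}

# Calibrated sun angle at the New Zealand deployment site, reused by the
# geolocation tests.
nz_calibrated_angle <- function() {
  cal <- stationary_trace(-40.47, 175.22, 46, 60)
  calibrate_sun_angle(cal, -40.47, 175.22)$sun_angle
}
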