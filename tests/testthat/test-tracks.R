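# Geolocator annotation: flight detection, timing arithmetic, incubation,
# threshold geolocation, region assignment, timing trend models.

test_that("detect_flights: degenerate inputs and construction recovery", {
  tr <- generate_trace(trace_spec(noise_wet_prob = 0, incubation_days = 0,
                                  seed = 2))$trace
  allwet <- transform(tr, wet = 1L)
  expect_equal(nrow(detect_flights(allwet)), 0)

  fl <- detect_flights(tr)
  expect_equal(nrow(fl), 2)
  expect_true(all(diff(as.numeric(fl$start)) > 0))
  expect_true(all(fl$dry_fraction >= 0.95))
})

test_that("detect_flights is idempotent and invariant to all-wet padding", {
  out <- generate_trace(trace_spec(seed = 6))
  tr <- out$trace
  fl1 <- detect_flights(tr)
  step <- as.numeric(difftime(tr$timestamp[2], tr$timestamp[1], units = "secs"))
  pad_before <- data.frame(
    timestamp = tr$timestamp[1] - rev(seq_len(100)) * step,
    light = 0, wet = 1L)
  pad_after <- data.frame(
    timestamp = tr$timestamp[nrow(tr)] + seq_len(100) * step,
    light = 0, wet = 1L)
  fl2 <- detect_flights(rbind(pad_before, tr, pad_after))
  expect_equal(fl1$start, fl2$start)
  expect_equal(fl1$duration_days, fl2$duration_days)
})

test_that("bridging closes short wet gaps but purity rejects dirty runs", {
  tr <- generate_trace(trace_spec(noise_wet_prob = 0, incubation_days = 0,
                                  seed = 3))$trace
  fl0 <- detect_flights(tr)
  # inject one isolated spurious wet mid-flight: still one run, same bounds
  mid <- which(tr$timestamp == fl0$start[1]) + 300
  tr2 <- tr; tr2$wet[mid] <- 1L
  fl <- detect_flights(tr2)
  expect_equal(nrow(fl), nrow(fl0))
  expect_equal(fl$start[1], fl0$start[1])
  expect_lt(fl$dry_fraction[1], 1)
  # a heavily contaminated run fails the purity screen
  idx <- which(tr$timestamp >= fl0$start[1] & tr$timestamp < fl0$end[1])
  tr3 <- tr
  tr3$wet[idx[seq(1, length(idx), by = 10)]] <- 1L  # 10% wets, spaced
  expect_lt(nrow(detect_flights(tr3)), nrow(fl0))
})

test_that("derive_timing arithmetic and partial results", {
  mk_flight <- function(start_doy, dur) {
    start <- as.POSIXct("2013-01-01", tz = "UTC") + (start_doy - 1) * 86400
    data.frame(start = start, end = start + dur * 86400,
               duration_days = dur, dry_fraction = 1)
  }
  fl <- rbind(mk_flight(79, 8), mk_flight(127, 7))
  tm <- derive_timing(fl)
  expect_equal(tm$NZdep, 79); expect_equal(tm$YSarr, 87)
  expect_equal(tm$YSdep, 127); expect_equal(tm$AKarr, 134)
  expect_equal(tm$YSdur, 40)

  one <- derive_timing(mk_flight(79, 8))
  expect_equal(one$NZdep, 79)
  expect_true(is.na(one$YSdep) && is.na(one$AKarr))

  three <- rbind(fl, mk_flight(150, 4))
  expect_warning(tm3 <- derive_timing(three), "longest two")
  expect_equal(tm3$NZdep, 79); expect_equal(tm3$AKarr, 134)

  bad <- list(NZdep = 90, YSarr = 80, YSdep = NA, AKarr = NA, YSdur = NA,
              IncSt = NA)
  expect_error(validate_timing(bad), "ordering")
})

test_that("conductivity-derived NZdep matches the observed departure day", {
  # co-observed synthetic birds: the generated (observed) departure instant
  # and the dry-run start agree to the same whole day
  for (s in 1:5) {
    out <- generate_trace(trace_spec(flight1_start = 75.3 + s, seed = s))
    tm <- derive_timing(detect_flights(out$trace))
    expect_identical(tm$NZdep, out$truth$NZdep)
    expect_identical(tm$AKarr, out$truth$AKarr)
  }
})

test_that("incubation detection: construction, boundaries, undetermined", {
  out <- generate_trace(trace_spec(incubation_start_offset = 12,
                                   incubation_bout_hours = 6,
                                   incubation_days = 20, seed = 7))
  inc <- detect_incubation(out$trace, out$truth$AKarr)
  expect_equal(inc$status, "detected")
  expect_equal(inc$IncSt, out$truth$AKarr + 12)

  # no shading -> absent
  none <- generate_trace(trace_spec(incubation_days = 0, end_doy = 175, seed = 7))
  expect_equal(detect_incubation(none$trace, none$truth$AKarr)$status, "absent")

  # out-of-range bouts (too short / too long) are never called
  for (b in c(2, 15)) {
    oo <- generate_trace(trace_spec(incubation_bout_hours = b,
                                    incubation_days = 20,
                                    check_bout_range = FALSE, seed = 8))
    res <- detect_incubation(oo$trace, oo$truth$AKarr)
    expect_true(is.na(res$IncSt))
  }

  # trace truncated before the search window closes -> undetermined
  tr <- none$trace
  short <- tr[.POSIXct(tr$timestamp) <
                as.POSIXct("2013-01-01", tz = "UTC") +
                (none$truth$AKarr + 10 - 1) * 86400, ]
  expect_equal(detect_incubation(short, none$truth$AKarr)$status, "undetermined")
})

test_that("threshold geolocation recovers a noiseless mid-June site", {
  angle <- nz_calibrated_angle()
  bt <- stationary_trace(62, -162, 160, 172)
  loc <- threshold_geolocate(bt, angle, lat_range = c(0, 75))
  expect_lt(abs(loc$lat - 62), 0.5)
  expect_lt(abs(loc$lon - -162), 0.5)
  expect_equal(loc$region, "South")
  expect_gt(loc$n_days, 5)
})

test_that("equinox latitude is flagged inestimable; longitude still accurate", {
  angle <- nz_calibrated_angle()
  eq <- stationary_trace(-40.47, 175.22, 78, 81)
  loc <- threshold_geolocate(eq, angle)
  expect_true(all(loc$daily$equinox))
  expect_true(is.na(loc$lat))
  expect_lt(abs(loc$lon - 175.22), 0.5)
})

test_that("latitude error grows towards the equinox", {
  angle <- nz_calibrated_angle()
  errs <- sapply(c(100, 125, 165), function(d0) {
    tr <- stationary_trace(62, -162, d0, d0 + 4)
    abs(threshold_geolocate(tr, angle, lat_range = c(0, 75))$lat - 62)
  })
  expect_gt(errs[1], errs[3])
})

test_that("calibration at the deployment site reproduces the response angle", {
  # the calibrated angle equals the elevation at which the logger response
  # crosses the threshold, recovered to a small fraction of a degree
  angle <- nz_calibrated_angle()
  resp <- uniroot(function(e) light_from_elevation(e) - 2, c(-3.5, 8.5))$root
  expect_lt(abs(angle - resp), 0.5)
})

test_that("assign_region boundary and Arctic override behaviour", {
  expect_equal(assign_region(70.2), "North")
  expect_equal(assign_region(62), "South")
  expect_equal(assign_region(64), "Boundary")
  expect_equal(assign_region(NA, lon = -150), "North")
  expect_true(is.na(assign_region(NA, lon = -170)))
})

test_that("timing_trend_models recovers injected slopes and screens interaction", {
  tg <- generate_timings(slopes = c(NZdep = -0.8, YSarr = -0.8, YSdep = -0.3,
                                    AKarr = -0.2, YSdur = 0.7, IncSt = 0),
                         seed = 12)
  fits <- timing_trend_models(tg)
  expect_setequal(fits$parameter,
                  c("NZdep", "YSarr", "YSdep", "AKarr", "YSdur", "IncSt"))
  truth <- attr(tg, "truth")$slopes
  for (p in names(truth)) {
    row <- fits[fits$parameter == p, ]
    expect_lt(abs(row$slope - truth[[p]]), 3 * row$se)
  }
  ys <- fits[fits$parameter == "YSdur", ]
  expect_lt(ys$p, 0.1)  # +0.7 d/yr is detectable at this scale
  expect_true(all(is.na(fits$interaction_p) | fits$interaction_p >= 0 |
                    fits$interaction_p <= 1))

  # sparse parameter is skipped with a warning
  tg$IncSt[seq_len(nrow(tg) - 3)] <- NA
  expect_warning(f2 <- timing_trend_models(tg), "skipped")
  expect_false("IncSt" %in% f2$parameter)
})

test_that("timing_trend_models null slopes give roughly uniform p-values", {
  ps <- sapply(1:20, function(s) {
    tg <- generate_timings(slopes = c(NZdep = 0, YSarr = 0, YSdep = 0,
                                      AKarr = 0, YSdur = 0, IncSt = 0),
                           seed = 200 + s)
    fits <- timing_trend_models(tg, params = "NZdep")
    fits$p[1]
  })
  expect_gt(mean(ps > 0.05), 0.7)   # ~95% expected; loose bound
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
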