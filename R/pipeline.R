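# End-to-end orchestration: simulate -> analyze -> report, with a single
# flat configuration object holding every tunable threshold, stage toggles
# and seeds. Rerunning with the same config and seed is byte-identical.

#' Build a run configuration
#'
#' All numeric thresholds used anywhere in the pipeline live here, each
#' defaulting to the value the analyses were designed around: the 3-year
#' panel filter, 3-day minimum flight, 4-13 h incubation bouts within
#' 6-25 d of arrival, the light threshold of 2 units, the 64 N regional
#' split, the 1/3 snow-free and 15%-amplitude green-up thresholds, and the
#' 15 km / 4 km SD NDVI neighbourhood.
#'
#' @param out_dir output directory.
#' @param seed master seed; stage seeds derive from it deterministically.
#' @param stages character subset of
#'   `c("simulate", "departures", "tracks", "phenology", "report")`.
#' @param panel_file,grid_file,traces_dir optional existing inputs used when
#'   the simulate stage is disabled.
#' @param ... overrides for any default listed below.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("migrapheno_run_"), seed = 1L,
                       stages = c("simulate", "departures", "tracks",
                                  "phenology", "report"),
                       panel_file = NULL, grid_file = NULL, traces_dir = NULL,
                       ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), stages = stages,
    panel_file = panel_file, grid_file = grid_file, traces_dir = traces_dir,
    # panel generation (kept small so a default run is quick)
    n_individuals = 40, years_first = 2008, years_last = 2020,
    beta_within = -0.428, beta_between = -0.463,
    sd_individual_intercept = 8, sd_residual = 4.2,
    mean_date_year0 = 80, presence_prob = 0.5,
    # trace generation
    n_tracks = 4, sampling_interval = 10,
    # departures thresholds
    min_years = 3, n_draws = 1000,
    # tracks thresholds
    flight_min_duration_days = 3, flight_purity = 0.95, bridge_hours = 2,
    bout_lo = 4, bout_hi = 13, inc_min_consecutive_days = 3,
    inc_window_lo = 6, inc_window_hi = 25,
    light_threshold = 2, split_lat = 64,
    # phenology thresholds
    n_cells = 12, snow_threshold = 1 / 3, greenup_frac = 0.15,
    radius_km = 15, neighbor_sd_km = 4)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as a flat key=value file
#'
#' @param cfg a [run_config()].
#' @param path file path.
#' @return `read_run_config` returns the reconstructed `run_config`; the
#'   round trip is lossless.
#' @export
write_run_config <- function(cfg, path) {
  ser <- function(v) {
    if (is.null(v)) "" else paste(v, collapse = ",")
  }
  lines <- vapply(names(cfg), function(k) paste0(k, "=", ser(cfg[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  defaults <- run_config()
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  cfg <- defaults
  for (pair in kv) {
    k <- pair[1]; v <- pair[2]
    if (!k %in% names(defaults)) stop("unknown config key: ", k)
    proto <- defaults[[k]]
    if (!nzchar(v)) { cfg[k] <- list(NULL); next }
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    cfg[[k]] <- if (is.numeric(proto)) as.numeric(parts)
                else if (is.integer(proto)) as.integer(parts)
                else parts
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

.stage_seed <- function(cfg, stage) {
  # deterministic per-stage seed, kept well below 2^31
  offsets <- c(simulate = 101L, departures = 211L, tracks = 307L,
               phenology = 401L, report = 503L)
  (cfg$seed * 1000L + offsets[[stage]]) %% 2147483647L
}

.write_results_csv <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order
#' (simulate, departures, tracks, phenology, report), writing tidy CSV
#' outputs per stage plus a manifest with seeds, versions and row counts.
#' A stage failure aborts the run but leaves earlier outputs intact.
#' Identical config and seed give byte-identical outputs.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list of output file paths by stage.
#' @export
run_all <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  manifest <- list(package_version = as.character(utils::packageVersion("migrapheno")),
                   seed = cfg$seed, stages = cfg$stages, files = list())
  note_file <- function(stage, path, n) {
    manifest$files[[basename(path)]] <<- list(stage = stage, rows = n)
  }

  if ("simulate" %in% cfg$stages) {
    sseed <- .stage_seed(cfg, "simulate")
    panel <- generate_departure_panel(
      panel_spec(n_individuals = cfg$n_individuals,
                 years = cfg$years_first:cfg$years_last,
                 beta_within = cfg$beta_within, beta_between = cfg$beta_between,
                 sd_individual_intercept = cfg$sd_individual_intercept,
                 sd_residual = cfg$sd_residual,
                 mean_date_year0 = cfg$mean_date_year0,
                 presence_prob = cfg$presence_prob, seed = sseed))
    cfg$panel_file <- file.path(cfg$out_dir, "panel.csv")
    write_departure_panel(panel, cfg$panel_file)
    note_file("simulate", cfg$panel_file, nrow(panel))

    cfg$traces_dir <- file.path(cfg$out_dir, "traces")
    dir.create(cfg$traces_dir, showWarnings = FALSE)
    track_years <- rep(c(2008, 2009, 2013, 2014), length.out = cfg$n_tracks)
    for (i in seq_len(cfg$n_tracks)) {
      tr <- generate_trace(trace_spec(
        year = track_years[i], sampling_interval = cfg$sampling_interval,
        flight1_start = 75 + (i %% 5), site_lat = 60 + 2 * (i %% 4),
        seed = sseed + i))
      write_trace(tr$trace, file.path(cfg$traces_dir, sprintf("track_%02d.csv", i)))
    }
    note_file("simulate", file.path(cfg$traces_dir, "tracks"), cfg$n_tracks)

    gr <- generate_phenology_grid(grid_spec(n_cells = cfg$n_cells,
                                            years = 2008:2014, seed = sseed))
    cfg$grid_file <- file.path(cfg$out_dir, "grid.csv")
    write_phenology_grid(gr$grid, cfg$grid_file)
    note_file("simulate", cfg$grid_file, nrow(gr$grid))
    outputs$simulate <- c(cfg$panel_file, cfg$grid_file, cfg$traces_dir)
  }

  if ("departures" %in% cfg$stages) {
    if (is.null(cfg$panel_file) || !file.exists(cfg$panel_file)) {
      stop("departures stage needs a panel file: ",
           if (is.null(cfg$panel_file)) "none configured and simulation disabled"
           else cfg$panel_file)
    }
    panel <- read_departure_panel(cfg$panel_file)
    pt <- population_trend(panel)
    dec <- decompose_trend(panel, min_years = cfg$min_years)
    rep_ <- repeatability(panel, min_years = cfg$min_years)
    sl <- simulate_individual_slopes(panel, min_years = cfg$min_years,
                                     n_draws = cfg$n_draws,
                                     seed = .stage_seed(cfg, "departures"))
    rr <- return_rate_glm(panel)
    res <- rbind(
      data.frame(analysis = "population_trend", statistic = "slope",
                 value = pt$slope, se = pt$se, p = pt$p),
      data.frame(analysis = "population_trend", statistic = "r_squared",
                 value = pt$r_squared, se = NA, p = NA),
      data.frame(analysis = "decomposition", statistic = "beta_within",
                 value = dec$beta_within, se = dec$se_within, p = NA),
      data.frame(analysis = "decomposition", statistic = "beta_between",
                 value = dec$beta_between, se = dec$se_between,
                 p = dec$p_difference),
      data.frame(analysis = "repeatability", statistic = "r",
                 value = rep_$r, se = rep_$se, p = rep_$p),
      data.frame(analysis = "repeatability", statistic = "F",
                 value = rep_$F, se = NA, p = rep_$p),
      data.frame(analysis = "individual_slopes", statistic = "pct_negative",
                 value = sl$summary$pct_negative, se = NA, p = NA),
      data.frame(analysis = "return_rate", statistic = "slope",
                 value = rr$slope, se = rr$se, p = rr$p))
    outputs$departures <- .write_results_csv(res, cfg$out_dir, "departures_results")
    note_file("departures", outputs$departures, nrow(res))
  }

  if ("tracks" %in% cfg$stages) {
    if (is.null(cfg$traces_dir) || !dir.exists(cfg$traces_dir)) {
      stop("tracks stage needs a traces directory: ",
           if (is.null(cfg$traces_dir)) "none configured and simulation disabled"
           else cfg$traces_dir)
    }
    files <- sort(list.files(cfg$traces_dir, pattern = "\\.csv$",
                             full.names = TRUE))
    rows <- list()
    for (f in files) {
      tr <- read_trace(f)
      fl <- detect_flights(tr, min_duration_days = cfg$flight_min_duration_days,
                           purity = cfg$flight_purity,
                           bridge_hours = cfg$bridge_hours)
      tm <- derive_timing(fl)
      inc <- if (!is.na(tm$AKarr)) {
        detect_incubation(tr, tm$AKarr, bout_range = c(cfg$bout_lo, cfg$bout_hi),
                          min_consecutive_days = cfg$inc_min_consecutive_days,
                          search_window = c(cfg$inc_window_lo, cfg$inc_window_hi),
                          light_threshold = cfg$light_threshold)
      } else list(IncSt = NA_real_, status = "undetermined")
      yr <- as.integer(format(tr$timestamp[1], "%Y", tz = "UTC"))
      rows[[f]] <- data.frame(
        id = sub("\\.csv$", "", basename(f)), year = yr,
        NZdep = tm$NZdep, YSarr = tm$YSarr, YSdep = tm$YSdep,
        AKarr = tm$AKarr, YSdur = tm$YSdur, IncSt = inc$IncSt,
        inc_status = inc$status, stringsAsFactors = FALSE)
    }
    timings <- do.call(rbind, rows); rownames(timings) <- NULL
    outputs$tracks <- .write_results_csv(timings, cfg$out_dir, "track_timings")
    note_file("tracks", outputs$tracks, nrow(timings))
  }

  if ("phenology" %in% cfg$stages) {
    if (is.null(cfg$grid_file) || !file.exists(cfg$grid_file)) {
      stop("phenology stage needs a grid file: ",
           if (is.null(cfg$grid_file)) "none configured and simulation disabled"
           else cfg$grid_file)
    }
    grid <- read_phenology_grid(cfg$grid_file)
    snow <- grid[grid$channel == "snow", ]
    ndvi <- grid[grid$channel == "ndvi", ]
    cells <- unique(grid[c("cell_id", "lat", "lon")])
    res <- list()
    for (ci in seq_len(nrow(cells))) {
      for (yr in unique(grid$year)) {
        s <- snow[snow$cell_id == cells$cell_id[ci] & snow$year == yr, ]
        v <- ndvi[ndvi$cell_id == cells$cell_id[ci] & ndvi$year == yr, ]
        if (nrow(s) == 0 && nrow(v) == 0) next
        melt <- if (nrow(s)) fit_snowmelt(s$doy, s$value,
                                          threshold = cfg$snow_threshold)$snowmelt_doy
                else NA_real_
        green <- if (nrow(v)) {
          tryCatch(fit_greenup(list(lat = cells$lat[ci], lon = cells$lon[ci],
                                    doy = v$doy, value = v$value),
                               radius_km = cfg$radius_km,
                               sd_km = cfg$neighbor_sd_km,
                               threshold_frac = cfg$greenup_frac)$greenup_doy,
                   error = function(e) NA_real_)
        } else NA_real_
        res[[length(res) + 1]] <- data.frame(
          cell_id = cells$cell_id[ci], lat = cells$lat[ci], year = yr,
          snowmelt = melt, greenup = green, stringsAsFactors = FALSE)
      }
    }
    dates <- do.call(rbind, res)
    outputs$phenology <- .write_results_csv(dates, cfg$out_dir, "cell_dates")
    note_file("phenology", outputs$phenology, nrow(dates))
    for (chan in c("snowmelt", "greenup")) {
      d <- data.frame(cell_id = dates$cell_id, lat = dates$lat,
                      year = dates$year, date = dates[[chan]])
      rs <- suppressWarnings(regional_summary(d, split_lat = cfg$split_lat))
      p1 <- .write_results_csv(rs$per_year, cfg$out_dir,
                               paste0(chan, "_regional"))
      p2 <- .write_results_csv(rs$trend, cfg$out_dir, paste0(chan, "_trend"))
      note_file("phenology", p1, nrow(rs$per_year))
      note_file("phenology", p2, nrow(rs$trend))
      outputs$phenology <- c(outputs$phenology, p1, p2)
    }
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  if ("report" %in% cfg$stages) {
    outputs$report <- make_report(cfg$out_dir)
  }
  invisible(outputs)
}

#' Assemble the run report
#'
#' Collects every stage output CSV in `out_dir` into one machine-readable
#' JSON plus a human-readable text summary; every reported number is read
#' back from a stage output file, never recomputed. Missing stages appear
#' as explicit gaps.
#'
#' @param out_dir a [run_all()] output directory.
#' @return invisibly, paths of `report.json` and `report.txt`.
#' @export
make_report <- function(out_dir) {
  report <- list()
  txt <- c("migrapheno run report", strrep("=", 21))
  grab <- function(name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    if (file.exists(path)) utils::read.csv(path, stringsAsFactors = FALSE) else NULL
  }
  dep <- grab("departures_results")
  if (is.null(dep)) {
    txt <- c(txt, "", "[departures] MISSING")
  } else {
    report$departures <- dep
    fmt <- function(a, s) {
      r <- dep[dep$analysis == a & dep$statistic == s, ]
      if (nrow(r)) sprintf("%s %s = %.4g (SE %.4g)", a, s, r$value[1], r$se[1])
      else NULL
    }
    txt <- c(txt, "", "[departures]",
             unlist(lapply(list(c("population_trend", "slope"),
                                c("decomposition", "beta_within"),
                                c("decomposition", "beta_between"),
                                c("repeatability", "r")),
                           function(x) fmt(x[1], x[2]))))
  }
  tmg <- grab("track_timings")
  if (is.null(tmg)) {
    txt <- c(txt, "", "[tracks] MISSING")
  } else {
    report$track_timings <- tmg
    txt <- c(txt, "", "[tracks]", sprintf("%d tracks annotated", nrow(tmg)))
  }
  for (chan in c("snowmelt", "greenup")) {
    tr <- grab(paste0(chan, "_trend"))
    if (is.null(tr)) {
      txt <- c(txt, "", sprintf("[phenology %s] MISSING", chan))
    } else {
      report[[paste0(chan, "_trend")]] <- tr
      txt <- c(txt, "", sprintf("[phenology %s]", chan),
               sprintf("  %s: %.3f d/yr (SE %.3f)", tr$region, tr$slope, tr$se))
    }
  }
  jpath <- file.path(out_dir, "report.json")
  tpath <- file.path(out_dir, "report.txt")
  jsonlite::write_json(report, jpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  writeLines(txt, tpath)
  if (length(report) == 0) warning("no stage outputs found in ", out_dir)
  invisible(c(jpath, tpath))
}
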