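# Year trends of the six timing parameters across tracked bird-years:
# linear mixed models with individual as a random effect and breeding
# region as a fixed factor; the year x region interaction is screened and
# dropped when non-significant.

.TIMING_PARAMS <- c("NZdep", "YSarr", "YSdep", "AKarr", "YSdur", "IncSt")

#' Mixed-model year trends of migration timing parameters
#'
#' For each timing parameter, fits
#' `value ~ year_c * region + (1 | id)` (year centred on `center_year` so
#' the intercept is interpretable); if the interaction's Wald p is at least
#' `alpha_interaction` the model is refit without it and the additive year
#' slope is reported. With a single region in the data the region term is
#' dropped. Fixed-effect tests are Wald z. Falls back to OLS when the mixed
#' fit is degenerate.
#'
#' @param timings data.frame with columns `id`, `year`, `region`, and the
#'   timing parameters (any of `NZdep`, `YSarr`, `YSdep`, `AKarr`, `YSdur`,
#'   `IncSt`), one row per track.
#' @param params parameters to fit.
#' @param center_year year subtracted from `year`.
#' @param alpha_interaction screening level for the year x region
#'   interaction.
#' @param min_n parameters with fewer non-missing values are skipped with a
#'   warning.
#' @return data.frame with one row per fitted parameter: `parameter`,
#'   `slope` (d/yr), `se`, `p`, `region_effect`, `region_se`,
#'   `interaction_p`, `interaction_dropped`, `n_tracks`, `n_individuals`.
#' @export
timing_trend_models <- function(timings, params = .TIMING_PARAMS,
                                center_year = 2008, alpha_interaction = 0.05,
                                min_n = 5) {
  if (length(unique(timings$year)) < 2) stop("need >= 2 years")
  if (length(unique(timings$id)) < 2) stop("need >= 2 individuals")
  rows <- list()
  for (p in intersect(params, names(timings))) {
    d <- timings[!is.na(timings[[p]]), , drop = FALSE]
    if (nrow(d) < min_n) {
      warning("parameter ", p, " has < ", min_n, " non-missing values; skipped")
      next
    }
    d$value <- d[[p]]
    d$year_c <- d$year - center_year
    multi_region <- length(unique(d$region)) > 1
    int_p <- NA_real_; dropped <- NA
    if (multi_region) {
      m_int <- .lmm_or_ols(value ~ year_c * region + (1 | id),
                           value ~ year_c * region, d)
      ti <- .fixef_table(m_int$fit)
      int_row <- grep(":", rownames(ti))
      int_p <- .wald_p(ti[int_row, "est"], ti[int_row, "se"])
      dropped <- int_p >= alpha_interaction
      if (dropped) {
        m <- .lmm_or_ols(value ~ year_c + region + (1 | id),
                         value ~ year_c + region, d)
      } else {
        m <- m_int
      }
    } else {
      m <- .lmm_or_ols(value ~ year_c + (1 | id), value ~ year_c, d)
    }
    tab <- .fixef_table(m$fit)
    reg_row <- grep("^region", rownames(tab))
    rows[[p]] <- data.frame(
      parameter = p,
      slope = unname(tab["year_c", "est"]),
      se = unname(tab["year_c", "se"]),
      p = .wald_p(tab["year_c", "est"], tab["year_c", "se"]),
      region_effect = if (length(reg_row)) unname(tab[reg_row[1], "est"]) else NA_real_,
      region_se = if (length(reg_row)) unname(tab[reg_row[1], "se"]) else NA_real_,
      interaction_p = int_p, interaction_dropped = dropped,
      n_tracks = nrow(d), n_individuals = length(unique(d$id)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate synthetic migration timings
#'
#' Convenience generator for testing [timing_trend_models()]: per-track
#' timing parameters with specified year slopes, a region offset,
#' individual random intercepts and residual noise, at the scale of the
#' published tracking data (50 tracks of 36 individuals over 2008, 2009,
#' 2013, 2014 by default).
#'
#' @param n_individuals number of individuals.
#' @param years tracking years (individuals assigned 1-2 random years).
#' @param n_tracks total tracks to emit.
#' @param slopes named vector of true year slopes (d/yr) per parameter.
#' @param region_offset days added to every parameter for northern birds.
#' @param prop_north proportion of individuals breeding north of 64 N.
#' @param sd_individual,sd_residual random intercept and residual SDs, days.
#' @param means named vector of parameter means in the first year (southern
#'   birds).
#' @param seed integer seed.
#' @return data.frame `id`, `year`, `region`, and the six parameters, plus
#'   attribute `"truth"`.
#' @export
generate_timings <- function(n_individuals = 36, years = c(2008, 2009, 2013, 2014),
                             n_tracks = 50,
                             slopes = c(NZdep = -0.8, YSarr = -0.8, YSdep = -0.3,
                                        AKarr = -0.2, YSdur = 0.7, IncSt = 0),
                             region_offset = 5, prop_north = 0.45,
                             sd_individual = 3, sd_residual = 2,
                             means = c(NZdep = 79, YSarr = 87, YSdep = 127,
                                       AKarr = 134, YSdur = 40, IncSt = 154),
                             seed = 1L) {
  withr::with_seed(seed, {
    region <- ifelse(stats::runif(n_individuals) < prop_north, "North", "South")
    u <- stats::rnorm(n_individuals, 0, sd_individual)
    # distribute tracks: each individual at least one year, extras at random
    picks <- c(seq_len(n_individuals),
               sample(n_individuals, max(0, n_tracks - n_individuals),
                      replace = TRUE))
    rows <- list()
    for (t in seq_along(picks)) {
      i <- picks[t]
      yr <- sample(years, 1)
      vals <- vapply(names(means), function(pn) {
        means[[pn]] + slopes[[pn]] * (yr - years[1]) +
          (region[i] == "North") * region_offset + u[i] +
          stats::rnorm(1, 0, sd_residual)
      }, numeric(1))
      rows[[t]] <- data.frame(id = sprintf("T%03d", i), year = yr,
                              region = region[i], t(vals),
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    # one track per id-year
    out <- out[!duplicated(out[c("id", "year")]), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "truth") <- list(slopes = slopes, region_offset = region_offset)
    out
  })
}
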