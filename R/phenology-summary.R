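# Regional summaries of per-cell phenology dates: median and 95% quantile
# range per region-year, and the pooled-cell OLS year trend.

#' Regional phenology summary and trend
#'
#' Splits cells at `split_lat` into North/South (plus an overall "All"
#' summary), computes the median and 2.5/97.5% quantiles of cell dates per
#' region-year, and the year trend from OLS of cell-level dates on year with
#' all cells pooled (no per-cell random effects; with realistic cell counts
#' this yields the very small SEs characteristic of continental-scale
#' remote-sensing trends).
#'
#' @param dates data.frame with columns `cell_id`, `lat`, `year`, `date`
#'   (day-of-year; `NA` rows are dropped).
#' @param split_lat North/South boundary latitude.
#' @param regions which regional summaries to compute.
#' @return list with `per_year` (region, year, median, q2.5, q97.5,
#'   n_cells) and `trend` (region, slope, se, p, n).
#' @export
regional_summary <- function(dates, split_lat = 64,
                             regions = c("All", "North", "South")) {
  stopifnot(all(c("cell_id", "lat", "year", "date") %in% names(dates)))
  dates <- dates[!is.na(dates$date), , drop = FALSE]
  dates$region <- ifelse(dates$lat > split_lat, "North", "South")
  per_year <- list(); trend <- list()
  for (reg in regions) {
    d <- if (reg == "All") dates else dates[dates$region == reg, , drop = FALSE]
    if (nrow(d) == 0) { warning("region ", reg, " has no valid cells"); next }
    if (length(unique(d$year)) < 2) {
      warning("region ", reg, " has < 2 years; trend skipped")
      slope <- se <- p <- NA_real_
    } else {
      fit <- stats::lm(date ~ year, data = d)
      s <- summary(fit)$coefficients
      slope <- unname(s["year", "Estimate"]); se <- unname(s["year", "Std. Error"])
      p <- unname(s["year", "Pr(>|t|)"])
    }
    for (yr in sort(unique(d$year))) {
      x <- d$date[d$year == yr]
      q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
      per_year[[length(per_year) + 1]] <- data.frame(
        region = reg, year = yr, median = q[2], `q2.5` = q[1], `q97.5` = q[3],
        n_cells = length(x), check.names = FALSE, stringsAsFactors = FALSE)
    }
    trend[[length(trend) + 1]] <- data.frame(
      region = reg, slope = slope, se = se, p = p, n = nrow(d),
      stringsAsFactors = FALSE)
  }
  list(per_year = do.call(rbind, per_year), trend = do.call(rbind, trend))
}

#' Correlation between snowmelt and green-up dates
#'
#' OLS of green-up on snowmelt over all complete cell-years.
#'
#' @param pairs data.frame with columns `snowmelt`, `greenup` (incomplete
#'   pairs dropped).
#' @return list with `r_squared`, `t` (on the slope), `df`, `p`, `slope`,
#'   `n`.
#' @export
snow_ndvi_correlation <- function(pairs) {
  stopifnot(all(c("snowmelt", "greenup") %in% names(pairs)))
  d <- pairs[stats::complete.cases(pairs[c("snowmelt", "greenup")]), , drop = FALSE]
  if (nrow(d) < 3) stop("need >= 3 complete snowmelt/greenup pairs")
  if (stats::var(d$snowmelt) < 1e-12) stop("constant snowmelt predictor")
  fit <- stats::lm(greenup ~ snowmelt, data = d)
  s <- summary(fit)
  list(r_squared = s$r.squared,
       t = unname(s$coefficients["snowmelt", "t value"]),
       df = fit$df.residual,
       p = unname(s$coefficients["snowmelt", "Pr(>|t|)"]),
       slope = unname(s$coefficients["snowmelt", "Estimate"]),
       n = nrow(d))
}
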