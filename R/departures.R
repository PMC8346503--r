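# Statistics on the directly observed departure panel: population trend,
# within/between decomposition by within-subject centering, ANOVA
# repeatability, per-individual posterior slope simulation, and
# composition-change checks.

.check_panel <- function(panel, window = c(32, 120), validate_window = FALSE) {
  need <- c("id", "year", "depart_doy")
  if (!all(need %in% names(panel))) {
    stop("panel needs columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(panel[c("id", "year")])) stop("one row per id-year required")
  if (validate_window && !is.null(window) &&
      any(panel$depart_doy < window[1] | panel$depart_doy > window[2])) {
    stop("departure dates outside plausible window [", window[1], ", ",
         window[2], "]")
  }
  invisible(panel)
}

#' Population-level departure trend
#'
#' Ordinary least squares of departure day-of-year on calendar year over all
#' rows (marked and unmarked birds alike; repeated individuals are
#' deliberately pooled, matching the population-level analysis this
#' reproduces).
#'
#' @param panel data.frame with columns `id`, `year`, `depart_doy`.
#' @return list with `slope` (d/yr), `se`, `r_squared`, `F`, `df1`, `df2`,
#'   `p`, `n`.
#' @export
population_trend <- function(panel) {
  .check_panel(panel)
  if (length(unique(panel$year)) < 2) stop("need >= 2 distinct years")
  if (stats::var(panel$depart_doy) < 1e-12) {
    # constant response: a flat line fits exactly; R^2 is 0 by convention
    return(list(slope = 0, se = 0, r_squared = 0, F = 0,
                df1 = 1, df2 = nrow(panel) - 2, p = 1, n = nrow(panel)))
  }
  fit <- stats::lm(depart_doy ~ year, data = panel)
  s <- summary(fit)
  fstat <- s$fstatistic
  list(slope = unname(stats::coef(fit)["year"]),
       se = unname(s$coefficients["year", "Std. Error"]),
       r_squared = s$r.squared,
       F = unname(fstat["value"]), df1 = unname(fstat["numdf"]),
       df2 = unname(fstat["dendf"]),
       p = unname(s$coefficients["year", "Pr(>|t|)"]),
       n = nrow(panel))
}

# fit lmer, falling back to OLS when the mixed fit is degenerate (e.g. the
# noise-free constructions used in tests have zero residual variance)
.lmm_or_ols <- function(formula_mm, formula_ols, data) {
  msgs <- character()
  fit <- withCallingHandlers(
    tryCatch(lme4::lmer(formula_mm, data = data, REML = TRUE),
             error = function(e) e),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  if (inherits(fit, "error")) {
    fit <- stats::lm(formula_ols, data = data)
    msgs <- c(msgs, "mixed model failed; ordinary least squares fallback")
  }
  list(fit = fit, notes = msgs)
}

.fixef_table <- function(fit) {
  if (inherits(fit, "merMod")) {
    cf <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  } else {
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
  }
  cbind(est = cf, se = se)
}

.wald_p <- function(est, se, tol = 1e-8) {
  # estimates at numerical-noise scale (exactly collinear noise-free data)
  # are a null result, not an infinitely significant one
  if (abs(est) < tol) return(1)
  if (!is.finite(se) || se == 0) return(0)
  2 * stats::pnorm(-abs(est / se))
}

#' Within/between decomposition of the departure trend
#'
#' Within-subject centering: for individuals observed in at least
#' `min_years` years, fits the REML linear mixed model
#' `depart_doy ~ mean_year + dev_year + (1 | id)` where `mean_year` is the
#' individual's mean observed year and `dev_year = year - mean_year`. The
#' `dev_year` coefficient is the within-individual slope, `mean_year` the
#' between-individual slope. The test of equal slopes comes from the
#' reparameterised model `depart_doy ~ year + mean_year + (1 | id)`, whose
#' `mean_year` coefficient equals beta_between - beta_within (Wald z).
#'
#' @param panel data.frame with columns `id`, `year`, `depart_doy`.
#' @param min_years minimum observed years per included individual.
#' @param random_slopes also include a random year slope per individual
#'   (sensitivity option; default `FALSE`, random intercept only).
#' @return list of class `trend_decomposition`: `beta_within`, `se_within`,
#'   `beta_between`, `se_between`, `p_difference`, `n_individuals`,
#'   `n_observations`, `var_individual`, `var_residual`, `notes`.
#' @export
decompose_trend <- function(panel, min_years = 3, random_slopes = FALSE) {
  .check_panel(panel)
  counts <- table(panel$id)
  keep <- names(counts)[counts >= min_years]
  d <- panel[panel$id %in% keep, , drop = FALSE]
  if (length(keep) < 2) stop("need >= 2 individuals with >= min_years observations")
  d$mean_year <- stats::ave(d$year, d$id)
  d$dev_year <- d$year - d$mean_year
  id_means <- tapply(d$mean_year, d$id, `[`, 1)
  if (stats::var(id_means) < 1e-12) {
    stop("between-individual covariate is constant (identical year sets); ",
         "between slope inestimable")
  }
  f1 <- if (random_slopes) depart_doy ~ mean_year + dev_year + (dev_year | id)
        else depart_doy ~ mean_year + dev_year + (1 | id)
  m1 <- .lmm_or_ols(f1, depart_doy ~ mean_year + dev_year, d)
  tab <- .fixef_table(m1$fit)
  f2 <- if (random_slopes) depart_doy ~ year + mean_year + (dev_year | id)
        else depart_doy ~ year + mean_year + (1 | id)
  m2 <- .lmm_or_ols(f2, depart_doy ~ year + mean_year, d)
  tab2 <- .fixef_table(m2$fit)
  if (inherits(m1$fit, "merMod")) {
    vc <- as.data.frame(lme4::VarCorr(m1$fit))
    var_ind <- vc$vcov[vc$grp == "id" & vc$var1 == "(Intercept)" & is.na(vc$var2)]
    var_res <- vc$vcov[vc$grp == "Residual"]
  } else {
    var_ind <- NA_real_
    var_res <- summary(m1$fit)$sigma^2
  }
  structure(list(
    beta_within = unname(tab["dev_year", "est"]),
    se_within = unname(tab["dev_year", "se"]),
    beta_between = unname(tab["mean_year", "est"]),
    se_between = unname(tab["mean_year", "se"]),
    p_difference = .wald_p(tab2["mean_year", "est"], tab2["mean_year", "se"]),
    n_individuals = length(keep), n_observations = nrow(d),
    var_individual = var_ind, var_residual = var_res,
    notes = unique(c(m1$notes, m2$notes))),
    class = "trend_decomposition")
}

#' Repeatability (intraclass correlation) of departure date
#'
#' One-way ANOVA ICC with the Lessells & Boag effective group size
#' \eqn{n_0 = (N - \sum n_i^2 / N) / (k - 1)}:
#' \eqn{r = (MS_A - MS_W) / (MS_A + (n_0 - 1) MS_W)}. The SE is the standard
#' large-sample ICC formula; F = MS_A/MS_W on (k-1, N-k) df.
#'
#' @param panel data.frame with columns `id`, `year`, `depart_doy`.
#' @param min_years minimum observations per included individual (groups of
#'   size 1 are always excluded, with a warning).
#' @return list with `r`, `se`, `F`, `df_among`, `df_within`, `p`, `n0`,
#'   `n_individuals`, `n_observations`.
#' @export
repeatability <- function(panel, min_years = 3) {
  .check_panel(panel)
  counts <- table(panel$id)
  if (any(counts < min_years)) {
    drop_n <- sum(counts < min_years)
    if (any(counts == 1)) {
      warning(sum(counts == 1), " individual(s) with a single observation excluded")
    }
    counts <- counts[counts >= min_years]
  }
  keep <- names(counts)
  if (length(keep) < 2) stop("need >= 2 individuals after filtering")
  d <- panel[panel$id %in% keep, , drop = FALSE]
  x <- d$depart_doy
  g <- factor(d$id)
  ni <- as.numeric(table(g))
  k <- length(ni); N <- sum(ni)
  gm <- mean(x)
  means <- tapply(x, g, mean)
  ss_a <- sum(ni * (means - gm)^2)
  ss_w <- sum((x - means[g])^2)
  ms_a <- ss_a / (k - 1)
  ms_w <- ss_w / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  r <- (ms_a - ms_w) / (ms_a + (n0 - 1) * ms_w)
  se <- sqrt(2 * (1 - r)^2 * (1 + (n0 - 1) * r)^2 / (n0 * (n0 - 1) * (k - 1)))
  F <- ms_a / ms_w
  list(r = r, se = se, F = F, df_among = as.integer(k - 1),
       df_within = as.integer(N - k),
       p = stats::pf(F, k - 1, N - k, lower.tail = FALSE), n0 = n0,
       n_individuals = as.integer(k), n_observations = as.integer(N))
}

#' Per-individual posterior slope simulation
#'
#' For each individual with at least `min_years` observations, fits the OLS
#' regression of departure date on year and draws `n_draws` values from the
#' standard noninformative joint posterior of the linear-model parameters:
#' \eqn{\sigma^2} from a scaled inverse chi-square on the residual df, the
#' slope conditionally normal given \eqn{\sigma}. Summaries report (a) the
#' percentage of individuals with negative point slopes, (b) the 2.5% and
#' 97.5% quantiles of the pooled simulated slopes across individuals, and
#' (c) the mean per-individual posterior probability of a negative slope.
#'
#' Individuals with exactly zero residual variance have a degenerate
#' posterior at the point slope (flagged; `prob_negative` is then 0 or 1).
#'
#' @param panel data.frame with columns `id`, `year`, `depart_doy`.
#' @param min_years minimum observations per included individual (>= 3).
#' @param n_draws posterior draws per individual.
#' @param seed optional integer seed.
#' @return list with `individuals` (data.frame `id`, `n`, `point_slope`,
#'   `prob_negative`, `q2.5`, `q97.5`, `degenerate`), `draws` (matrix,
#'   n_draws x individuals) and `summary` (list `pct_negative`,
#'   `n_negative`, `n_individuals`, `q2.5`, `q97.5`, `mean_prob_negative`).
#' @export
simulate_individual_slopes <- function(panel, min_years = 3, n_draws = 1000,
                                       seed = NULL) {
  .check_panel(panel)
  if (min_years < 3) stop("min_years must be >= 3 (need residual df)")
  counts <- table(panel$id)
  ids <- names(counts)[counts >= min_years]
  if (length(ids) == 0) stop("no individual has >= min_years observations")
  run <- function() {
    draws <- matrix(NA_real_, n_draws, length(ids),
                    dimnames = list(NULL, ids))
    res <- vector("list", length(ids))
    for (j in seq_along(ids)) {
      d <- panel[panel$id == ids[j], ]
      X <- cbind(1, d$year)
      fit <- stats::lm.fit(X, d$depart_doy)
      bhat <- fit$coefficients[2]
      df <- nrow(d) - 2
      rss <- sum(fit$residuals^2)
      c22 <- chol2inv(chol(crossprod(X)))[2, 2]
      degen <- rss < 1e-10
      if (degen) {
        sl <- rep(bhat, n_draws)
      } else {
        sigma2 <- (rss / df) * df / stats::rchisq(n_draws, df)
        sl <- stats::rnorm(n_draws, bhat, sqrt(sigma2 * c22))
      }
      draws[, j] <- sl
      res[[j]] <- data.frame(id = ids[j], n = nrow(d), point_slope = bhat,
                             prob_negative = mean(sl < 0),
                             `q2.5` = unname(stats::quantile(sl, 0.025)),
                             `q97.5` = unname(stats::quantile(sl, 0.975)),
                             degenerate = degen, check.names = FALSE,
                             stringsAsFactors = FALSE)
    }
    ind <- do.call(rbind, res); rownames(ind) <- NULL
    qs <- stats::quantile(draws, c(0.025, 0.975))
    list(individuals = ind, draws = draws,
         summary = list(
           pct_negative = 100 * mean(ind$point_slope < 0),
           n_negative = sum(ind$point_slope < 0),
           n_individuals = nrow(ind),
           `q2.5` = unname(qs[1]), `q97.5` = unname(qs[2]),
           mean_prob_negative = mean(ind$prob_negative)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Return-rate logistic regression
#'
#' Tests whether the probability that a marked bird is seen again the next
#' year depends on its departure date (a composition-change check). The
#' response is constructed from the panel itself: `returned = 1` if the same
#' id appears in year + 1; rows from the last panel year are excluded.
#'
#' @param panel data.frame with columns `id`, `year`, `depart_doy`.
#' @return list with `slope`, `se`, `z`, `p`, `df` (residual df), `n`, and
#'   `separation` flag (all returned or none returned).
#' @export
return_rate_glm <- function(panel) {
  .check_panel(panel)
  last <- max(panel$year)
  d <- panel[panel$year < last, , drop = FALSE]
  key <- paste(panel$id, panel$year)
  d$returned <- as.integer(paste(d$id, d$year + 1) %in% key)
  sep <- length(unique(d$returned)) < 2
  if (sep) {
    warning("complete separation: all birds ",
            if (all(d$returned == 1)) "returned" else "failed to return")
    return(list(slope = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                df = nrow(d) - 2, n = nrow(d), separation = TRUE))
  }
  fit <- stats::glm(returned ~ depart_doy, family = stats::binomial(), data = d)
  s <- summary(fit)$coefficients
  list(slope = unname(s["depart_doy", "Estimate"]),
       se = unname(s["depart_doy", "Std. Error"]),
       z = unname(s["depart_doy", "z value"]),
       p = unname(s["depart_doy", "Pr(>|z|)"]),
       df = fit$df.residual, n = nrow(d), separation = FALSE)
}

#' Per-region trend decomposition
#'
#' Runs [decompose_trend()] separately for each breeding region over the
#' individuals assigned in the map (e.g. North/South Alaska at the 64 N
#' split); unmapped individuals are ignored.
#'
#' @param panel data.frame with columns `id`, `year`, `depart_doy`.
#' @param region_map data.frame with columns `id`, `region`.
#' @param min_years passed to [decompose_trend()].
#' @return named list of `trend_decomposition` objects, one per region.
#' @export
subgroup_decomposition <- function(panel, region_map, min_years = 3) {
  if (!all(c("id", "region") %in% names(region_map)) || nrow(region_map) == 0) {
    stop("region_map must be a non-empty data.frame with columns id, region")
  }
  out <- list()
  for (reg in unique(region_map$region)) {
    ids <- region_map$id[region_map$region == reg]
    sub <- panel[panel$id %in% ids, , drop = FALSE]
    if (length(unique(sub$id)) < 2) {
      stop("region ", reg, " has < 2 mapped individuals in the panel")
    }
    out[[reg]] <- decompose_trend(sub, min_years = min_years)
  }
  out
}
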