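# Snowmelt date from daily binary snow status: maximum-likelihood fit of an
# asymmetric Gaussian snow-free probability curve with Bernoulli error
# (binomial with trial size 1: the gridded product is binary per cell-day),
# then the date the fitted curve first reaches 1/3 snow-free.

#' Fit the asymmetric-Gaussian snowmelt model to one cell-season
#'
#' Maximises the Bernoulli log-likelihood of daily snow-free status under
#' \deqn{s(t) = p_{max} \exp(-\tfrac12 ((t-\mu)/\sigma_L)^2), t < \mu}
#' (\eqn{\sigma_R} for \eqn{t \ge \mu}) over a grid of starting values with
#' bounded quasi-Newton refinement (the likelihood is multimodal on short
#' seasons). The snowmelt date is the analytic first 1/3-crossing
#' \eqn{\mu - \sigma_L \sqrt{2\ln(3 p_{max})}} when \eqn{p_{max} > 1/3}
#' (missing otherwise, fit retained), clamped to the first observed day for
#' degenerate always-snow-free series.
#'
#' @param doy days-of-year of the observations.
#' @param snow_free binary snow-free indicator (1 = snow-free).
#' @param threshold snow-free fraction defining the melt date.
#' @return list of class `snowmelt_fit`: `p_max`, `mu`, `sigma_left`,
#'   `sigma_right`, `loglik`, `snowmelt_doy`, `converged`.
#' @export
fit_snowmelt <- function(doy, snow_free, threshold = 1 / 3) {
  stopifnot(length(doy) == length(snow_free))
  if (is.unsorted(doy, strictly = TRUE)) stop("doys must be strictly increasing")
  if (!all(snow_free %in% c(0, 1))) stop("snow_free must be binary")
  y <- as.numeric(snow_free)
  nll <- function(par) {
    p <- stats::plogis(min(par[1], 30))
    mu <- par[2]; sL <- exp(par[3]); sR <- exp(par[4])
    s <- .asym_gauss(doy, p, mu, sL, sR)
    s <- pmin(1 - 1e-9, pmax(1e-9, s))
    -sum(y * log(s) + (1 - y) * log(1 - s))
  }
  free_days <- doy[y == 1]
  mu_starts <- if (length(free_days) >= 2) {
    unique(stats::quantile(free_days, c(0.25, 0.5, 0.75), names = FALSE))
  } else stats::median(doy)
  best <- NULL
  for (mu0 in mu_starts) for (s0 in c(15, 40)) {
    fit <- tryCatch(
      stats::optim(c(stats::qlogis(0.9), mu0, log(s0), log(s0 * 1.5)), nll,
                   method = "L-BFGS-B",
                   lower = c(-10, min(doy) - 100, log(1), log(1)),
                   upper = c(30, max(doy) + 100, log(200), log(200)),
                   control = list(factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(p_max = NA_real_, mu = NA_real_,
                          sigma_left = NA_real_, sigma_right = NA_real_,
                          loglik = NA_real_, snowmelt_doy = NA_real_,
                          converged = FALSE), class = "snowmelt_fit"))
  }
  p_max <- stats::plogis(min(best$par[1], 30))
  mu <- best$par[2]; sL <- exp(best$par[3]); sR <- exp(best$par[4])
  melt <- .snow_crossing(p_max, mu, sL, threshold)
  if (!is.na(melt)) melt <- max(melt, min(doy))
  structure(list(p_max = p_max, mu = mu, sigma_left = sL, sigma_right = sR,
                 loglik = -best$value, snowmelt_doy = melt,
                 converged = best$convergence == 0),
            class = "snowmelt_fit")
}

#' Evaluate a fitted snow-free probability curve
#'
#' @param fit a `snowmelt_fit`.
#' @param doy days to evaluate.
#' @return snow-free probabilities.
#' @export
predict_snow_curve <- function(fit, doy) {
  .asym_gauss(doy, fit$p_max, fit$mu, fit$sigma_left, fit$sigma_right)
}
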