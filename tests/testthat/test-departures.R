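# Departure-panel statistics: OLS/ICC oracles, decomposition behaviour,
# posterior slope simulation, composition checks.

test_that("population_trend matches the closed-form OLS oracle", {
  panel <- data.frame(id = c("a", "a", "b", "b", "c", "c"),
                      year = c(2008, 2010, 2009, 2012, 2011, 2013),
                      depart_doy = c(84, 81, 90, 85, 78, 80), observed = 1L)
  pt <- population_trend(panel)
  expect_equal(pt$slope, oracle_ols_slope(panel$year, panel$depart_doy),
               tolerance = 1e-12)
  expect_equal(pt$n, 6)

  flat <- transform(panel, depart_doy = 100)
  pf <- population_trend(flat)
  expect_equal(pf$slope, 0)
  expect_equal(pf$r_squared, 0)

  single <- data.frame(id = letters[1:4], year = 2010,
                       depart_doy = c(80, 85, 90, 95), observed = 1L)
  expect_error(population_trend(single), "2 distinct years")
})

test_that("population_trend recovers the slope of a noise-free panel exactly", {
  p <- generate_departure_panel(panel_spec(n_individuals = 30, seed = 8,
                                           beta_within = -0.5, beta_between = -0.5,
                                           sd_individual_intercept = 0,
                                           sd_residual = 0), round = FALSE)
  expect_equal(suppressWarnings(population_trend(p))$slope, -0.5,
               tolerance = 1e-10)
})

test_that("decompose_trend: noise-free equality of slopes, filtering, errors", {
  p <- generate_departure_panel(panel_spec(n_individuals = 30, seed = 8,
                                           beta_within = -0.5, beta_between = -0.5,
                                           sd_individual_intercept = 0,
                                           sd_residual = 0), round = FALSE)
  dec <- decompose_trend(p)
  expect_equal(dec$beta_within, -0.5, tolerance = 1e-6)
  expect_equal(dec$beta_between, -0.5, tolerance = 1e-6)
  expect_gt(dec$p_difference, 0.99)

  # uses exactly the rows of qualifying individuals
  counts <- table(p$id)
  expect_identical(dec$n_observations,
                   as.integer(sum(counts[counts >= 3])))
  expect_identical(dec$n_individuals, as.integer(sum(counts >= 3)))

  # identical year sets make the between covariate constant
  bal <- expand.grid(id = c("a", "b", "c"), year = 2010:2014)
  bal$depart_doy <- 80 + rnorm(nrow(bal))
  bal$observed <- 1L
  expect_error(decompose_trend(bal), "inestimable")
})

test_that("decompose_trend recovers generator truth within 2 SEs", {
  spec <- panel_spec(n_individuals = 124, years = 2008:2020,
                     beta_within = -0.43, beta_between = -0.46,
                     sd_individual_intercept = 8, sd_residual = 3, seed = 31)
  dec <- decompose_trend(generate_departure_panel(spec, min_years = 3))
  expect_lt(abs(dec$beta_within - -0.43), 2 * dec$se_within)
  expect_lt(abs(dec$beta_between - -0.46), 2 * dec$se_between)
})

test_that("pooled OLS agrees with both slopes when the generator sets them equal", {
  # near-fully observed panel (full observation would make the between
  # covariate constant, which is flagged inestimable), beta_W = beta_B:
  # population trend, beta_within and beta_between must coincide up to noise
  spec <- panel_spec(n_individuals = 60, years = 2008:2020, presence_prob = 0.85,
                     beta_within = -0.4, beta_between = -0.4,
                     sd_individual_intercept = 4, sd_residual = 2, seed = 13)
  p <- generate_departure_panel(spec, round = FALSE)
  pt <- population_trend(p)
  dec <- decompose_trend(p)
  expect_lt(abs(pt$slope - dec$beta_within), 2 * dec$se_within)
  expect_lt(abs(dec$beta_between - dec$beta_within), 2 * dec$se_between)

  # in the noise-free limit all three coincide exactly
  spec0 <- panel_spec(n_individuals = 40, presence_prob = 0.85,
                      beta_within = -0.4, beta_between = -0.4,
                      sd_individual_intercept = 0, sd_residual = 0, seed = 13)
  p0 <- generate_departure_panel(spec0, round = FALSE)
  pt0 <- suppressWarnings(population_trend(p0))
  dec0 <- decompose_trend(p0)
  expect_equal(pt0$slope, -0.4, tolerance = 1e-8)
  expect_equal(dec0$beta_within, -0.4, tolerance = 1e-6)
  expect_equal(dec0$beta_between, -0.4, tolerance = 1e-6)
})

test_that("repeatability equals the brute-force ANOVA oracle", {
  set.seed(21)
  for (rep in 1:10) {
    panel <- random_small_panel()
    panel <- panel[panel$id %in% names(which(table(panel$id) >= 2)), ]
    got <- repeatability(panel, min_years = 2)
    want <- oracle_icc(panel)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$n0, want$n0, tolerance = 1e-10)
    expect_identical(got$df_among, got$n_individuals - 1L)
  }
})

test_that("repeatability limits: r -> 1 and r -> 0 in degenerate constructions", {
  ident <- data.frame(id = rep(c("a", "b", "c"), each = 3),
                      year = rep(2010:2012, 3),
                      depart_doy = rep(c(70, 85, 100), each = 3), observed = 1L)
  expect_equal(repeatability(ident)$r, 1)

  set.seed(2)
  noise <- data.frame(id = rep(sprintf("i%02d", 1:40), each = 5),
                      year = rep(2010:2014, 40),
                      depart_doy = rnorm(200, 80, 5), observed = 1L)
  expect_lt(abs(repeatability(noise)$r), 0.15)

  singleton <- rbind(ident, data.frame(id = "z", year = 2010, depart_doy = 80,
                                       observed = 1L))
  expect_warning(repeatability(singleton, min_years = 2), "single observation")
})

test_that("posterior slope simulation: degenerate, convergence, quantile order", {
  exact <- data.frame(id = "a", year = 2010:2014,
                      depart_doy = seq(90, 82, by = -2), observed = 1L)
  sim <- simulate_individual_slopes(exact, seed = 1)
  expect_true(sim$individuals$degenerate)
  expect_equal(sim$individuals$prob_negative, 1)
  expect_equal(sim$individuals$point_slope, -2)

  # draw mean converges to the OLS slope (3 Monte-Carlo SEs at 1e5 draws)
  set.seed(3)
  noisy <- data.frame(id = "b", year = 2008:2017,
                      depart_doy = 85 - 0.5 * (0:9) + rnorm(10, 0, 3),
                      observed = 1L)
  big <- simulate_individual_slopes(noisy, n_draws = 1e5, seed = 2)
  bhat <- oracle_ols_slope(noisy$year, noisy$depart_doy)
  mc_se <- sd(big$draws) / sqrt(length(big$draws))
  expect_lt(abs(mean(big$draws) - bhat), 3 * mc_se)
  expect_lte(big$individuals$`q2.5`, big$individuals$point_slope)
  expect_lte(big$individuals$point_slope, big$individuals$`q97.5`)
})

test_that("posterior intervals cover a zero true slope at ~95%", {
  spec <- panel_spec(n_individuals = 80, years = 2008:2020,
                     beta_within = 0, beta_between = 0,
                     sd_individual_intercept = 6, sd_residual = 3,
                     presence_prob = 0.7, seed = 17)
  p <- generate_departure_panel(spec, min_years = 4)
  sim <- simulate_individual_slopes(p, min_years = 4, seed = 5)
  cover <- mean(sim$individuals$`q2.5` <= 0 & sim$individuals$`q97.5` >= 0)
  expect_gt(cover, 0.85)
  expect_gt(mean(sim$individuals$prob_negative), 0.25)
  expect_lt(mean(sim$individuals$prob_negative), 0.75)
})

test_that("return_rate_glm: null behaviour and power against the survival knob", {
  # null: return independent of date; Z rarely large across repetitions
  zs <- sapply(1:25, function(s) {
    p <- generate_departure_panel(panel_spec(n_individuals = 60, seed = 100 + s,
                                             presence_prob = 0.6))
    return_rate_glm(p)$z
  })
  expect_lt(mean(abs(zs) > 1.96), 0.25)

  # alternative: late birds half as likely to return at large n
  p_alt <- generate_departure_panel(panel_spec(
    n_individuals = 400, seed = 23, presence_prob = 0.7,
    return_logit_slope = -0.08, sd_individual_intercept = 8))
  rr <- return_rate_glm(p_alt)
  expect_lt(rr$slope, 0)
  expect_lt(rr$p, 0.01)
  expect_identical(rr$df, rr$n - 2L)
})

test_that("return_rate_glm flags separation", {
  p <- data.frame(id = rep(c("a", "b"), each = 3), year = rep(2010:2012, 2),
                  depart_doy = c(80, 81, 82, 90, 91, 92), observed = 1L)
  # both ids present every year -> everyone returns
  expect_warning(rr <- return_rate_glm(p), "separation")
  expect_true(rr$separation)
})

test_that("subgroup_decomposition recovers a shared within slope per region", {
  mk <- function(seed) generate_departure_panel(
    panel_spec(n_individuals = 40, beta_within = -0.5, beta_between = -0.5,
               sd_individual_intercept = 5, sd_residual = 2,
               presence_prob = 0.8, seed = seed), min_years = 3)
  north <- mk(41); north$id <- paste0("N", north$id)
  south <- mk(42); south$id <- paste0("S", south$id)
  panel <- rbind(north, south)
  map <- data.frame(id = unique(panel$id),
                    region = ifelse(startsWith(unique(panel$id), "N"),
                                    "North", "South"))
  res <- subgroup_decomposition(panel, map)
  for (reg in c("North", "South")) {
    expect_lt(abs(res[[reg]]$beta_within - -0.5), 2 * res[[reg]]$se_within)
  }
  expect_error(subgroup_decomposition(panel, map[0, ]), "non-empty")
})
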