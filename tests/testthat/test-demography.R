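# Gompertz-Makeham hazard/survival identities, interval-censored MLE,
# Kaplan-Meier restricted means, log-rank, and cross-genotype models.

test_that("the hazard function evaluates the closed form exactly", {
  f <- gm_fit(exp(-11.5), 0.115)
  expect_equal(gm_hazard(f, 0), exp(-11.5))
  g <- gm_fit(exp(-15.9), 0.188)
  expect_equal(gm_hazard(g, 45), exp(-15.9 + 0.188 * 45))
  h <- gm_fit(0.01, 0, makeham = 0.005)
  expect_equal(gm_hazard(h, c(0, 10, 200)), rep(0.015, 3))
  expect_error(gm_hazard(f, -1), ">= 0")
})

test_that("survival matches quadrature of the hazard and its limits", {
  expect_equal(gm_survival(gm_fit(exp(-11.5), 0.115), 0), 1)
  expect_equal(gm_survival(gm_fit(0.02, 0, makeham = 0.01), 30),
               exp(-0.03 * 30))
  f <- gm_fit(exp(-11.5), 0.115)
  expect_equal(gm_survival(f, 80),
               exp(-(exp(-11.5) / 0.115) * (exp(0.115 * 80) - 1)),
               tolerance = 1e-12)
  set.seed(81)
  for (i in 1:25) {
    la <- runif(1, -16, -8); b <- runif(1, 0.05, 0.3); m <- runif(1, 0, 0.01)
    fit <- gm_fit(exp(la), b, m)
    x <- runif(1, 1, 90)
    quad <- integrate(function(u) gm_hazard(fit, u), 0, x,
                      rel.tol = 1e-11)$value
    expect_equal(gm_survival(fit, x), exp(-quad), tolerance = 1e-8)
  }
})

test_that("the interval-censored MLE recovers generating parameters", {
  la <- -11.5; b <- 0.115
  spec <- genotype_spec("G", exp(la), b, n_vials = 40, flies_per_vial = 25)
  err_la <- err_b <- numeric(5)
  for (s in 1:5) {
    d <- simulate_gm_deaths(spec, seed = 100 + s)
    fit <- fit_gm(d, include_makeham = FALSE)
    err_la[s] <- log(fit$alpha) - la
    err_b[s] <- (fit$beta - b) / b
    # MLE dominance: truth never beats the optimum
    ints <- metaboclock:::collapse_intervals(d)
    expect_gte(fit$log_likelihood + 1e-6,
               metaboclock:::gm_interval_loglik(exp(la), b, 0, ints))
  }
  expect_lt(median(abs(err_la)), 0.5)
  expect_lt(median(abs(err_b)), 0.10)
})

test_that("no coarse lattice point beats the optimizer", {
  spec <- genotype_spec("G", exp(-12), 0.13, n_vials = 8)
  d <- simulate_gm_deaths(spec, seed = 7)
  fit <- fit_gm(d, include_makeham = FALSE)
  ints <- metaboclock:::collapse_intervals(d)
  grid <- expand.grid(la = seq(-15, -9, by = 0.25),
                      b = seq(0.05, 0.25, by = 0.01))
  ll <- mapply(function(la, b)
    metaboclock:::gm_interval_loglik(exp(la), b, 0, ints), grid$la, grid$b)
  expect_gte(fit$log_likelihood + 1e-3, max(ll))
})

test_that("exponential-mortality data drive the aging rate to zero", {
  spec <- genotype_spec("G", 0.03, 0, n_vials = 20)
  d <- simulate_gm_deaths(spec, seed = 13)
  fit <- fit_gm(d, include_makeham = FALSE)
  # beta collapses toward the boundary; hazard stays near constant
  expect_lt(fit$beta, 0.01)
  expect_equal(gm_hazard(fit, 60) / gm_hazard(fit, 5), 1, tolerance = 0.6)
})

test_that("MLE bias shrinks with cohort size", {
  la <- -12.5; b <- 0.14
  err <- function(n_vials, seeds) {
    spec <- genotype_spec("G", exp(la), b, n_vials = n_vials)
    vapply(seeds, function(s) {
      abs(fit_gm(simulate_gm_deaths(spec, seed = s),
                 include_makeham = FALSE)$beta - b)
    }, numeric(1))
  }
  small <- median(err(8, 1:9))     # ~200 flies
  large <- median(err(80, 1:9))    # ~2000 flies
  expect_lt(large, small)
})

test_that("degenerate death tables are rejected", {
  one <- toy_death_table(starts = 10, ends = 12, n_dead = 25)
  expect_error(fit_gm(one), "single interval")
  few <- toy_death_table(n_dead = c(2, 2, 1))
  expect_warning(fit_gm(few, include_makeham = FALSE), "unreliable")
})

test_that("restricted mean reduces to the sample mean without censoring", {
  pm <- toy_death_table(starts = 10, ends = 12, n_dead = 10)
  km <- km_restricted_mean(pm)
  expect_equal(km$mean, 12)
  d <- simulate_gm_deaths(genotype_spec("G", exp(-11), 0.12), seed = 3)
  km2 <- km_restricted_mean(d)
  expect_equal(km2$mean,
               sum(d$interval_end * d$n_dead) / sum(d$n_dead),
               tolerance = 1e-10)
  expect_error(km_restricted_mean(d, tau = 1), "precedes")
})

test_that("restricted mean with censoring matches the enumerated step function", {
  d <- toy_death_table(starts = c(10, 14, 18), ends = c(12, 16, 20),
                       n_dead = c(2, 2, 1), n_censored = c(1, 0, 0))
  km <- km_restricted_mean(d, tau = 20)
  time <- c(12, 12, 12, 16, 16, 20)
  status <- c(1, 1, 0, 1, 1, 1)
  expect_equal(km$mean, km_area_oracle(time, status, 20), tolerance = 1e-10)
  # hand arithmetic: 12*1 + 4*(2/3) + 4*(2/9)
  expect_equal(km$mean, 12 + 4 * 2/3 + 4 * 2/9, tolerance = 1e-10)
  expect_gt(km$se, 0)
})

test_that("log-rank equals a from-scratch observed-minus-expected oracle", {
  g1 <- toy_death_table("A", starts = c(2, 6, 10), ends = c(4, 8, 12),
                        n_dead = c(3, 4, 3))
  g2 <- toy_death_table("B", starts = c(6, 10, 14), ends = c(8, 12, 16),
                        n_dead = c(2, 5, 3))
  g3 <- toy_death_table("C", starts = c(2, 10, 18), ends = c(4, 12, 20),
                        n_dead = c(1, 4, 5))
  res <- log_rank(list(A = g1, B = g2, C = g3))
  ev <- do.call(rbind, lapply(list(A = g1, B = g2, C = g3), function(d)
    data.frame(time = rep(d$interval_end, d$n_dead), status = 1)))
  ev$group <- rep(c("A", "B", "C"), times = c(10, 10, 10))
  expect_equal(res$chi2, logrank_oracle(ev$time, ev$status, ev$group),
               tolerance = 1e-10)
  expect_equal(res$df, 2)
})

test_that("log-rank is null on identical groups and vial-invariant", {
  d <- toy_death_table()
  res <- log_rank(list(d, d))
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  # merging vials within genotype leaves the statistic unchanged
  pop <- simulate_population(n_genotypes = 4, seed = 19)
  merged <- pop$deaths
  merged$vial <- "V1"
  class(merged) <- c("death_table", "data.frame")
  expect_equal(log_rank(pop$deaths)$chi2, log_rank(merged)$chi2,
               tolerance = 1e-12)
})

test_that("lifespan variance model finds exact and null structure", {
  set.seed(23)
  df <- data.frame(ln_alpha = rnorm(20, -12, 2), beta = runif(20, 0.08, 0.2))
  df$mean_lifespan <- 100 + 3 * df$ln_alpha - 200 * df$beta
  fit <- suppressWarnings(lifespan_variance_model(df))
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)
  expect_lt(fit$p_alpha, 1e-10)
  # permuted response carries no signal on average
  r2 <- replicate(20, {
    df$mean_lifespan <- sample(df$mean_lifespan)
    lifespan_variance_model(df)$adj_r2
  })
  expect_lt(abs(mean(r2)), 0.15)
  expect_error(lifespan_variance_model(df[1:4, ]), ">= 5")
})

test_that("mortality-parameter correlation recovers rank structure", {
  fits <- list(gm_fit(exp(-10), 0.10), gm_fit(exp(-12), 0.15),
               gm_fit(exp(-14), 0.20))
  sm <- strehler_mildvan(fits)
  expect_equal(sm$rho, -1)
  pop <- simulate_population(n_genotypes = 100, sm_coupling = -0.8, seed = 29)
  demog <- data.frame(
    ln_alpha = vapply(pop$specs, function(s) log(s$alpha), numeric(1)),
    beta = vapply(pop$specs, function(s) s$beta, numeric(1)))
  expect_lt(strehler_mildvan(demog)$rho, -0.6)
})
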