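test_that("log posterior truncates at the hard bounds", {
  w <- study_weather(seed = 1)
  pri <- prior_spec(hybrid_defaults())
  obs <- lai_observations(study_stage_dates, c(3, 4.5, 3.5))
  th <- pri$means
  expect_true(is.finite(log_posterior(th, pri, obs, w, study_sowing)))
  th_out <- th; th_out["TSUM1"] <- pri$upper["TSUM1"] * 1.01
  expect_identical(log_posterior(th_out, pri, obs, w, study_sowing), -Inf)
})

test_that("log posterior peaks at the generating parameters on a grid", {
  w <- study_weather(seed = 1)
  truth <- inbred_optimized()
  lt <- stage_lai(crop_parameters(truth), w)
  obs <- lai_observations(study_stage_dates, lt, sd = 0.01)
  pri <- prior_spec(truth)   # prior centred at truth so only the peak moves
  grid <- seq(0.9, 1.1, by = 0.05)
  lp <- sapply(grid, function(f) {
    th <- truth; th["TSUM1"] <- truth["TSUM1"] * f
    log_posterior(th, pri, obs, w, study_sowing)
  })
  expect_equal(which.max(lp), which(grid == 1))
})

test_that("with an uninformative likelihood the posterior is the prior", {
  w <- study_weather(seed = 1)
  pri <- prior_spec(hybrid_defaults())
  obs <- lai_observations(study_stage_dates, c(3, 4.5, 3.5), sd = 1e9)
  th1 <- pri$means
  th2 <- pri$means * 1.05
  d_post <- log_posterior(th1, pri, obs, w, study_sowing) -
    log_posterior(th2, pri, obs, w, study_sowing)
  d_prior <- sum(dnorm(th1, pri$means, pri$sd, log = TRUE)) -
    sum(dnorm(th2, pri$means, pri$sd, log = TRUE))
  expect_equal(d_post, d_prior, tolerance = 1e-6)
})

test_that("a one-iteration chain with no burn-in is the initial point", {
  lp <- function(m) -0.5 * rowSums(m^2)
  r <- maizecast:::metropolis(lp, init = c(x = 0.3), prop_sd = 0.1,
                              n_iter = 1, n_burn = 0, seed = 1)
  expect_equal(as.numeric(r$chains[1, 1, 1]), 0.3)
})

test_that("Metropolis sampling matches an analytic normal posterior", {
  # 1-parameter quadratic log-posterior ~ N(2, 0.5^2)
  lp <- function(m) -(m[, 1] - 2)^2 / (2 * 0.5^2)
  r <- maizecast:::metropolis(lp, init = c(x = 2), prop_sd = 0.5,
                              n_iter = 50000, n_burn = 1000, seed = 4)
  x <- r$chains[, 1, 1]
  ks <- suppressWarnings(stats::ks.test(x, "pnorm", 2, 0.5))
  expect_lt(unname(ks$statistic), 0.05)
  expect_equal(mean(x), 2, tolerance = 0.02)
  expect_equal(sd(x), 0.5, tolerance = 0.02)
})

test_that("chains never leave the hard bounds and acceptance is tuned", {
  w <- study_weather(seed = 1)
  truth <- inbred_optimized()
  lt <- stage_lai(crop_parameters(truth), w)
  pri <- prior_spec(hybrid_defaults())
  obs <- lai_observations(study_stage_dates, lt)
  cal <- mcmc_calibrate(pri, obs, w, study_sowing, n_iter = 800,
                        n_burn = 400, seed = 2)
  for (j in seq_along(pri$means)) {
    expect_gte(min(cal$chains[, j, 1]), pri$lower[j])
    expect_lte(max(cal$chains[, j, 1]), pri$upper[j])
  }
  expect_gt(cal$acceptance_rate, 0.05)
  expect_lt(cal$acceptance_rate, 0.7)
  # ci95 within hard bounds by construction
  expect_true(all(cal$ci95[1, , 1] >= pri$lower - 1e-9))
  expect_true(all(cal$ci95[2, , 1] <= pri$upper + 1e-9))
})

test_that("posterior concentrates as the observation error shrinks", {
  w <- study_weather(seed = 1)
  truth <- inbred_optimized()
  lt <- stage_lai(crop_parameters(truth), w)
  pri <- prior_spec(hybrid_defaults())
  run <- function(sd_obs) {
    cal <- mcmc_calibrate(pri, lai_observations(study_stage_dates, lt,
                                                sd = sd_obs),
                          w, study_sowing, n_iter = 2000, n_burn = 800,
                          seed = 3)
    sd(cal$chains[, "TSUM1", 1])
  }
  expect_lte(run(0.05), 0.5 * run(0.25))
})

test_that("independent seeds agree on the posterior mean", {
  w <- study_weather(seed = 1)
  truth <- inbred_optimized()
  lt <- stage_lai(crop_parameters(truth), w)
  pri <- prior_spec(hybrid_defaults())
  obs <- lai_observations(study_stage_dates, lt)
  c1 <- mcmc_calibrate(pri, obs, w, study_sowing, n_iter = 20000,
                       n_burn = 1000, seed = 11)
  c2 <- mcmc_calibrate(pri, obs, w, study_sowing, n_iter = 20000,
                       n_burn = 1000, seed = 12)
  psd <- apply(c1$chains[, , 1], 2, sd)
  diff <- abs(c1$posterior_mean[, 1] - c2$posterior_mean[, 1])
  expect_true(all(diff < 0.5 * psd))
})

test_that("multi-chain runs expose a Gelman-Rubin diagnostic", {
  lp <- function(m) -(m[, 1])^2 / 2
  r <- maizecast:::metropolis(lp, init = c(x = 0), prop_sd = 1,
                              n_iter = 4000, n_burn = 500, seed = 5,
                              n_chains = 3)
  expect_lt(gelman_rubin(r$chains)[["x"]], 1.1)
})

test_that("constructors validate their invariants", {
  expect_error(prior_spec(sd_fraction = 0), "positive")
  expect_error(lai_observations(Sys.Date(), -1), "non-negative")
  expect_error(lai_observations(Sys.Date(), 1, sd = 0), "positive")
  pri <- prior_spec(hybrid_defaults())
  expect_equal(pri$lower, hybrid_defaults() * 0.7)
  expect_equal(pri$upper, hybrid_defaults() * 1.3)
})
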