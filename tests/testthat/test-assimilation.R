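test_that("ensemble construction respects mode, spread and truncation", {
  p_inb <- crop_parameters(inbred_optimized())
  # degenerate spread: all members identical
  set.seed(1)
  e0 <- build_ensemble(p_inb, ensemble_config(parameter_sd_fraction = 0))
  expect_equal(max(apply(e0$par_mat, 2, sd)), 0)
  # CLT bound on the sample mean of TSUM1 draws
  set.seed(2)
  e1 <- build_ensemble(p_inb, ensemble_config(n_members = 1000))
  expect_lt(abs(mean(e1$par_mat[, "TSUM1"]) - 735),
            2 * 0.05 * 735 / sqrt(1000))
  # parameter-set draws clipped to the +/-30% bounds
  expect_true(all(e1$par_mat[, "TSUM1"] >= 735 * 0.7 &
                    e1$par_mat[, "TSUM1"] <= 735 * 1.3))
  # single-parameter mode: only GWF varies, truncated to [0.3, 0.8]
  set.seed(3)
  es <- build_ensemble(crop_parameters(),
                       ensemble_config(n_members = 2000,
                                       parameter_sd_fraction = 0.3,
                                       mode = "single_parameter"))
  expect_true(all(es$par_mat[, "GWF"] >= 0.3 & es$par_mat[, "GWF"] <= 0.8))
  expect_equal(sd(es$par_mat[, "TSUM1"]), 0)
  expect_error(build_ensemble(p_inb, ensemble_config(n_members = 1)),
               "at least 2")
})

test_that("EnKF analysis matches the closed-form Kalman filter", {
  # forecast N(2, 0.2^2) (spread injected by the model-error perturbation),
  # obs 3.0, R = 0.25^2 -> analysis mean 2 + 0.04/(0.04+0.0625)
  oracle <- 2 + 0.04 / (0.04 + 0.0625)
  cfg <- ensemble_config(n_members = 10000, model_lai_sd = 0.2,
                         obs_lai_sd = 0.25)
  set.seed(10)
  a <- enkf_update(rep(2, 10000), 3.0, cfg)
  expect_lt(abs(mean(a) - oracle), 0.02)
})

test_that("EnKF error decays with ensemble size at a root-M rate", {
  oracle <- 2 + 0.04 / (0.04 + 0.0625)
  cfg_for <- function(M) ensemble_config(n_members = M, model_lai_sd = 0.2,
                                         obs_lai_sd = 0.25)
  err <- sapply(c(100, 1000, 10000), function(M) {
    mean(sapply(1:40, function(r) {
      set.seed(1000 * M + r)
      abs(mean(enkf_update(rep(2, M), 3.0, cfg_for(M))) - oracle)
    }))
  })
  expect_true(all(diff(err) < 0))
  slope <- coef(lm(log(err) ~ log(c(100, 1000, 10000))))[2]
  expect_gt(slope, -0.8)
  expect_lt(slope, -0.2)
})

test_that("EnKF limits: infinite R keeps the forecast, zero R matches obs", {
  set.seed(4)
  A <- rnorm(5000, 2, 0.3)
  big_r <- ensemble_config(n_members = 5000, model_lai_sd = 0,
                           obs_lai_sd = 1e9)
  expect_equal(enkf_update(A, 3, big_r), A, tolerance = 1e-4)
  tiny_r <- ensemble_config(n_members = 5000, model_lai_sd = 0,
                            obs_lai_sd = 1e-6)
  expect_equal(mean(enkf_update(A, 3, tiny_r)), 3, tolerance = 1e-3)
})

test_that("analysis variance does not exceed forecast variance", {
  cfg <- ensemble_config(n_members = 1000, model_lai_sd = 0,
                         obs_lai_sd = 0.25)
  for (r in 1:20) {
    set.seed(300 + r)
    A <- rnorm(1000, 2.5, 0.4)
    a <- enkf_update(A, 2.0, cfg)
    expect_lt(var(a), var(A) * 1.05)
  }
})

test_that("state augmentation updates a correlated parameter", {
  # GWF positively correlated with LAI: a high observation must raise it
  set.seed(5)
  gwf <- rnorm(4000, 0.55, 0.05)
  lai <- 2 + 4 * (gwf - 0.55) + rnorm(4000, 0, 0.05)
  cfg <- ensemble_config(n_members = 4000, model_lai_sd = 0.05,
                         obs_lai_sd = 0.25)
  a <- enkf_update(rbind(lai, gwf), 3.0, cfg)
  expect_gt(mean(a[2, ]), mean(gwf) + 0.01)
  expect_gt(mean(a[1, ]), mean(lai))
})

test_that("point assimilation is consistent and respects identities", {
  w <- study_weather(seed = 6)
  p <- crop_parameters(inbred_optimized())
  cfg <- ensemble_config(n_members = 40, seed = 9)
  ol <- open_loop(p, w, cfg, study_sowing)
  # observations equal to the model's own trajectory leave yield within 1 sd
  lt <- stage_lai(p, w)
  obs <- lai_observations(study_stage_dates, lt)
  as1 <- assimilate_point(p, w, obs, cfg, study_sowing)
  expect_lt(abs(as1$yield - ol$yield), ol$yield_sd)
  # zero observations reproduce the open loop exactly
  none <- lai_observations(as.Date(character()), numeric())
  expect_equal(assimilate_point(p, w, none, cfg, study_sowing)$yield,
               ol$yield)
  # all observations outside the season error out
  far <- lai_observations(as.Date("2035-06-01"), 3)
  expect_error(assimilate_point(p, w, far, cfg, study_sowing),
               "outside the simulated season")
})

test_that("twin experiment: assimilation corrects a biased phenology prior", {
  # weather long enough for the late-phenology truth to fill its grain
  w <- study_weather(seed = 6, n_days = 190)
  truth_p <- crop_parameters(c(TSUM1 = 735))
  truth <- suppressWarnings(simulate_crop(truth_p, w, study_sowing))
  lt <- truth$trajectory$LAI[match(study_stage_dates, truth$trajectory$date)]
  prior <- crop_parameters(c(TSUM1 = 695))
  wins <- 0
  for (r in 1:50) {
    set.seed(700 + r)
    obs <- lai_observations(study_stage_dates, pmax(0, lt + rnorm(3, 0, 0.25)))
    cfg <- ensemble_config(n_members = 40, seed = 700 + r)
    ol <- open_loop(prior, w, cfg, study_sowing)
    as1 <- assimilate_point(prior, w, obs, cfg, study_sowing)
    wins <- wins + (abs(as1$yield - truth$yield) < abs(ol$yield - truth$yield))
  }
  expect_gte(wins, 40)   # >= 80% of repeats
})

test_that("regional assimilation is deterministic and propagates no-data", {
  w <- study_weather(seed = 6)
  p <- crop_parameters(inbred_optimized())
  cfg <- ensemble_config(n_members = 20, seed = 13)
  # 2x2 grid of identical pixels -> 4 identical yields
  maps <- lapply(c(3, 4.5, 3.2), function(v) matrix(v, 2, 2))
  ym <- assimilate_region(maps, w, p, cfg, study_sowing, study_stage_dates)
  expect_equal(max(ym$yield) - min(ym$yield), 0)
  # identical config + seed -> bit-identical map
  ym2 <- assimilate_region(maps, w, p, cfg, study_sowing, study_stage_dates)
  expect_identical(ym$yield, ym2$yield)
  # all-stage no-data pixel -> no-data yield; partial no-data is kept
  maps[[1]][1, 1] <- NA; maps[[2]][1, 1] <- NA; maps[[3]][1, 1] <- NA
  maps[[2]][2, 1] <- NA
  ym3 <- assimilate_region(maps, w, p, cfg, study_sowing, study_stage_dates)
  expect_true(is.na(ym3$yield[1, 1]))
  expect_false(is.na(ym3$yield[2, 1]))
  # member parameters unchanged by updates in parameter_set mode: yields of
  # the no-update pixel equal the open-loop ensemble
  expect_error(assimilate_region(maps[1:2], w, p, cfg, study_sowing,
                                 study_stage_dates), "3")
  bad <- list(matrix(3, 2, 2), matrix(3, 3, 2), matrix(3, 2, 2))
  expect_error(assimilate_region(bad, w, p, cfg, study_sowing,
                                 study_stage_dates), "mismatch")
})

test_that("plot-level validation statistics", {
  v <- validate_yield(c(6100, 6900, 7500), c(6000, 7000, 7600))
  expect_equal(v$rmse, 100, tolerance = 1e-9)
  ve <- validate_yield(c(6000, 7000, 7600), c(6000, 7000, 7600))
  expect_equal(ve$r_squared, 1)
  expect_equal(ve$rmse, 0)
  expect_error(validate_yield(c(1, 2), c(1, 2)), "3")
  expect_warning(vz <- validate_yield(c(1, 2, 3), c(5, 5, 5)),
                 "zero variance")
  expect_true(is.na(vz$r_squared))
  # pixel-to-plot aggregation
  ymap <- matrix(c(6000, 6200, 7000, 7200, 8000, 8400), 2, 3)
  pid <- matrix(c(1, 1, 2, 2, 3, 3), 2, 3)
  va <- validate_yield(ymap, c(6100, 7100, 8200), plot_id = pid)
  expect_equal(va$rmse, 0, tolerance = 1e-9)
})
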