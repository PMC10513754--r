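test_that("vegetation indices match their defining formulas", {
  b <- list(nir = 0.5, red = 0.1, blue = 0.04, green = 0.2)
  expect_equal(compute_vi(b, "NDVI"), 0.4 / 0.6, tolerance = 1e-6)
  expect_equal(compute_vi(b, "kNDVI"), tanh((0.4 / 0.6)^2), tolerance = 1e-6)
  expect_equal(compute_vi(b, "EVI"), 2.5 * 0.4 / (0.5 + 0.6 - 0.3 + 1),
               tolerance = 1e-6)
  expect_equal(compute_vi(b, "NDGI"), 0.1 / 0.3, tolerance = 1e-6)
  # symmetry zeros
  expect_equal(compute_vi(list(nir = 0.3, red = 0.3), "NDVI"), 0)
  expect_equal(compute_vi(list(nir = 0.3, red = 0.3), "kNDVI"), 0)
  expect_equal(compute_vi(list(green = 0.2, red = 0.2), "NDGI"), 0)
})

test_that("index ranges and kNDVI shape hold over reflectance space", {
  set.seed(1)
  b <- list(nir = runif(500), red = runif(500), green = runif(500))
  ndvi <- compute_vi(b, "NDVI")
  ndgi <- compute_vi(b, "NDGI")
  kndvi <- compute_vi(b, "kNDVI")
  expect_true(all(abs(ndvi) <= 1 & abs(ndgi) <= 1))
  expect_true(all(kndvi >= 0 & kndvi <= tanh(1)))
  expect_equal(kndvi, tanh(ndvi^2))
  # even in NDVI, strictly increasing in |NDVI|
  o <- order(abs(ndvi))
  expect_true(all(diff(kndvi[o]) > 0))
})

test_that("zero denominators give NaN sentinels, missing bands error", {
  expect_warning(v <- compute_vi(list(nir = 0, red = 0), "NDVI"),
                 "zero denominator")
  expect_true(is.nan(v))
  expect_error(compute_vi(list(nir = 0.5), "NDVI"), "missing band")
  expect_error(compute_vi(list(nir = 1.5, red = 0.2), "NDVI"), "outside")
})

test_that("noiseless linear data is fitted exactly", {
  set.seed(2)
  vi <- runif(40, 0.1, 0.7)
  # suppress lm's essentially-perfect-fit note: the fit is meant to be exact
  m <- suppressWarnings(fit_lai_model(vi, 10.8 * vi + 1.3,
                                      stage = "jointing",
                                      vi_name = "NDGI", seed = 1))
  expect_equal(m$slope, 10.8, tolerance = 1e-9)
  expect_equal(m$intercept, 1.3, tolerance = 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
  expect_equal(m$rmse, 0, tolerance = 1e-7)
  expect_equal(m$n_train + m$n_valid, 40)
})

test_that("uncorrelated data gives near-zero validation R2", {
  set.seed(3)
  m <- fit_lai_model(runif(200), rnorm(200, 3, 1), seed = 1)
  expect_lt(m$r_squared, 0.15)
})

test_that("fit_lai_model enforces its preconditions", {
  expect_error(fit_lai_model(runif(5), runif(5)), "10")
  expect_error(fit_lai_model(rep(0.5, 20), runif(20)), "zero variance")
})

test_that("fitting recovers generating coefficients within 2 SE", {
  # seeded repeats; per-coefficient 2-SE coverage should be ~95%
  hits_slope <- hits_int <- 0
  for (r in 1:100) {
    set.seed(1000 + r)
    vi <- runif(60, 0.2, 0.8)
    lai <- 10.8 * vi + 1.3 + rnorm(60, 0, 0.4)
    m <- fit_lai_model(vi, lai, seed = r)
    hits_slope <- hits_slope + (abs(m$slope - 10.8) <= 2 * m$slope_se)
    hits_int <- hits_int + (abs(m$intercept - 1.3) <= 2 * m$intercept_se)
  }
  expect_gte(hits_slope, 93)
  expect_gte(hits_int, 93)
})

test_that("model selection ranks by validation R2 with stated tie-breaks", {
  mk <- function(vi, r2, rmse)
    empirical_lai_model("jointing", vi, 1, 0, r_squared = r2, rmse = rmse)
  cands <- list(mk("NDVI", 0.60, 2.5), mk("EVI", 0.58, 2.2),
                mk("NDGI", 0.72, 2.4), mk("kNDVI", 0.65, 2.0))
  expect_equal(select_best_model(cands)$vi_name, "NDGI")
  expect_equal(select_best_model(cands[1])$vi_name, "NDVI")
  # exact R2 tie broken by lower rmse, then fixed index order
  tie <- list(mk("kNDVI", 0.6, 2.0), mk("NDVI", 0.6, 2.4))
  expect_equal(select_best_model(tie)$vi_name, "kNDVI")
  tie2 <- list(mk("kNDVI", 0.6, 2.0), mk("NDVI", 0.6, 2.0))
  expect_equal(select_best_model(tie2)$vi_name, "NDVI")
  expect_error(select_best_model(list()), "empty")
})

test_that("LAI maps apply the linear model with flooring and NA passthrough", {
  m <- default_lai_models()$jointing
  vi <- matrix(c(0.5, 0.5, -0.5, NA), 2, 2)
  lai <- estimate_lai_map(vi, m)
  expect_equal(lai[1, 1], 6.7, tolerance = 1e-9)
  expect_equal(lai[1, 2], 0)       # negative prediction floored
  expect_true(is.na(lai[2, 2]))    # no-data propagates
  expect_true(is.na(estimate_lai_map(matrix(NA_real_, 1, 1), m)[1, 1]))
  # uniform raster gives uniform map
  u <- estimate_lai_map(matrix(0.4, 3, 3), m)
  expect_equal(max(u) - min(u), 0)
})
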