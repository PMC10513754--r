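#' Generate a synthetic daily weather series
#'
#' Emulates a temperate continental growing-season climate: a sinusoidal
#' annual temperature cycle plus AR(1) day-to-day anomalies, a fixed diurnal
#' range, beta-distributed relative sunshine duration, occasional
#' precipitation, and global radiation derived from sunshine hours through
#' the Angstrom-Prescott relation. Deterministic given `seed`.
#'
#' @param latitude Site latitude, decimal degrees.
#' @param start First date of the series.
#' @param n_days Series length (>= 150).
#' @param seed Integer RNG seed.
#' @param annual_mean Annual mean temperature, degC.
#' @param amplitude Amplitude of the annual cycle, degC (warmest day =
#'   `annual_mean + amplitude`).
#' @param peak_doy Day of year of the temperature maximum.
#' @param diurnal_range Tmax - Tmin, degC.
#' @param ar_rho,ar_sd AR(1) autocorrelation and innovation sd of the daily
#'   temperature anomaly, degC.
#' @param sunshine_shape1,sunshine_shape2 Beta parameters of relative
#'   sunshine duration n/N (defaults give mean ~0.71, matching 3000-3600
#'   annual sunshine hours).
#' @return A `weather_series` data frame with columns `date, tmax, tmin,
#'   sunshine_hours, precipitation, wind_speed, pressure, radiation`.
#' @examples
#' w <- generate_weather(38.9, as.Date("2021-04-20"), 170, seed = 1)
#' @export
generate_weather <- function(latitude, start, n_days, seed,
                             annual_mean = 7, amplitude = 15,
                             peak_doy = 200, diurnal_range = 13.4,
                             ar_rho = 0.7, ar_sd = 1.5,
                             sunshine_shape1 = 5, sunshine_shape2 = 2) {
  if (n_days < 150) stop("n_days must be at least 150")
  set.seed(seed)
  dates <- as.Date(start) + seq_len(n_days) - 1
  doy <- as.integer(strftime(dates, "%j"))
  t_mean <- annual_mean + amplitude * cos(2 * pi * (doy - peak_doy) / 365)
  anom <- as.numeric(
    stats::filter(stats::rnorm(n_days, 0, ar_sd), ar_rho, "recursive"))
  t_mean <- t_mean + anom
  geom <- solar_geometry(deg2rad(latitude), doy)
  frac <- stats::rbeta(n_days, sunshine_shape1, sunshine_shape2)
  n_sun <- frac * geom$daylength
  wet <- stats::runif(n_days) < 0.25
  precip <- ifelse(wet, stats::rgamma(n_days, shape = 1.2, scale = 4), 0)
  w <- data.frame(
    date = dates,
    tmax = t_mean + diurnal_range / 2,
    tmin = t_mean - diurnal_range / 2,
    sunshine_hours = n_sun,
    precipitation = precip,
    wind_speed = pmax(0.2, stats::rnorm(n_days, 2, 0.8)),
    pressure = stats::rnorm(n_days, 880, 3))  # ~1500 m elevation
  w$radiation <- radiation_from_sunshine(n_sun, geom)
  w$radiation_derived <- TRUE
  class(w) <- c("weather_series", "data.frame")
  w
}

# smoothed-white-noise Gaussian random field, unit sd, zero mean
gaussian_field <- function(nx, ny, kernel_sd = 3) {
  half <- ceiling(3 * kernel_sd)
  g <- stats::dnorm(-half:half, sd = kernel_sd)
  smooth_mat <- function(n) {
    s <- matrix(0, n, n)
    for (j in seq_len(n)) {
      lo <- max(1, j - half); hi <- min(n, j + half)
      kk <- g[(lo - j + half + 1):(hi - j + half + 1)]
      s[lo:hi, j] <- kk / sum(kk)
    }
    s
  }
  z <- matrix(stats::rnorm(nx * ny), ny, nx)
  f <- smooth_mat(ny) %*% z %*% t(smooth_mat(nx))
  (f - mean(f)) / stats::sd(f)
}

#' Default stage-wise VI-to-LAI models
#'
#' The three stage-specific empirical retrieval models used as the
#' synthetic-scene default: NDGI at jointing (LAI = 10.8 VI + 1.3) and
#' kNDVI at tasseling (18.3 VI - 6.3) and milky stage (5.8 VI + 1.3).
#'
#' @return A list of three [empirical_lai_model()] objects named
#'   `jointing`, `tasseling`, `milky`.
#' @export
default_lai_models <- function() {
  list(
    jointing = empirical_lai_model("jointing", "NDGI", 10.8, 1.3),
    tasseling = empirical_lai_model("tasseling", "kNDVI", 18.3, -6.3),
    milky = empirical_lai_model("milky", "kNDVI", 5.8, 1.3))
}

#' Generate a synthetic maize scene for twin experiments
#'
#' Builds a complete, internally consistent synthetic study area: a shared
#' weather series; per-pixel "true" variety parameters obtained by applying
#' smooth Gaussian-random-field multipliers (coefficient of variation
#' `spatial_cv`) to `TSUM1`, `CVO` and `TDWI`; true LAI grids at the three
#' observation stages (jointing, tasseling, milky) and true yields from the
#' simulator; noisy LAI observations (`obs = truth + N(0, obs_sd^2)`);
#' vegetation-index grids obtained by inverting the stage retrieval models
#' plus index noise; and rectangular plots whose "measured" yields are the
#' plot-mean true yield plus measurement noise.
#'
#' @param nx,ny Grid dimensions (nx*ny <= 10000).
#' @param base_params `crop_parameters` of the true variety (defaults to the
#'   calibrated inbred set).
#' @param spatial_cv Coefficient of variation of the per-pixel parameter
#'   multipliers (>= 0).
#' @param obs_sd LAI observation noise sd, m2 m-2.
#' @param seed Integer RNG seed.
#' @param stage_doys Day-of-year of the jointing, tasseling and milky
#'   observations.
#' @param sowing_date Sowing date; the weather series starts 5 days before.
#' @param latitude Site latitude, decimal degrees.
#' @param n_days Weather series length.
#' @param vi_models Stage retrieval models ([default_lai_models()]).
#' @param vi_noise_sd Additive index noise sd.
#' @param plot_size Side length of the square validation plots, pixels.
#' @param plot_noise_sd Plot yield measurement noise, kg ha-1.
#' @return A list of class `synthetic_scene` with elements `weather`,
#'   `truth_params` (per-pixel multipliers), `truth_yield`, `lai_truth`,
#'   `lai_obs`, `vi_obs` (lists of 3 grids), `stage_dates`, `plots`
#'   (data frame id, yield_measured, yield_true) and `plot_id` grid.
#' @export
generate_scene <- function(nx, ny, base_params = crop_parameters(inbred_optimized()),
                           spatial_cv = 0.1, obs_sd = 0.25, seed = 1,
                           stage_doys = c(173, 218, 246),
                           sowing_date = as.Date("2021-04-25"),
                           latitude = 38.9, n_days = 170,
                           vi_models = default_lai_models(),
                           vi_noise_sd = 0.02,
                           plot_size = 4, plot_noise_sd = 200) {
  if (spatial_cv < 0) stop("spatial_cv must be non-negative")
  if (nx * ny > 1e4) stop("scene larger than 10000 pixels")
  weather <- generate_weather(latitude, as.Date(sowing_date) - 5, n_days,
                              seed = seed)
  set.seed(seed + 1L)
  np <- nx * ny
  mult <- list(TSUM1 = 1 + spatial_cv * gaussian_field(nx, ny),
               CVO = 1 + spatial_cv * gaussian_field(nx, ny),
               TDWI = 1 + spatial_cv * gaussian_field(nx, ny))
  base <- par_row(base_params)
  pm <- base[rep(1, np), , drop = FALSE]
  for (nm in names(mult)) pm[, nm] <- pmax(0.05, as.vector(mult[[nm]])) * base[1, nm]
  pm[, "CVO"] <- pmin(pm[, "CVO"], 1)

  year <- as.integer(strftime(as.Date(sowing_date), "%Y"))
  stage_dates <- as.Date(stage_doys - 1, origin = paste0(year, "-01-01"))
  res <- sim_engine(pm, base_params, weather, as.Date(sowing_date),
                    record_dates = stage_dates)
  truth_yield <- matrix(res$yield, ny, nx)
  lai_truth <- lapply(1:3, function(k) matrix(res$lai_record[k, ], ny, nx))
  lai_obs <- lapply(lai_truth, function(m)
    m + matrix(stats::rnorm(np, 0, obs_sd), ny, nx))
  vi_obs <- lapply(1:3, function(k) {
    md <- vi_models[[k]]
    (lai_truth[[k]] - md$intercept) / md$slope +
      matrix(stats::rnorm(np, 0, vi_noise_sd), ny, nx)
  })
  names(lai_truth) <- names(lai_obs) <- names(vi_obs) <- names(vi_models)

  # rectangular validation plots
  pid <- outer(ceiling(seq_len(ny) / plot_size) - 1,
               ceiling(seq_len(nx) / plot_size),
               function(r, c) r * max(ceiling(nx / plot_size)) + c)
  ids <- sort(unique(as.vector(pid)))
  yt <- vapply(ids, function(id) mean(truth_yield[pid == id]), 0)
  plots <- data.frame(id = ids, yield_true = yt,
                      yield_measured = yt + stats::rnorm(length(ids), 0,
                                                         plot_noise_sd))
  structure(
    list(weather = weather, truth_params = mult, param_matrix = pm,
         base_params = base_params, sowing_date = as.Date(sowing_date),
         stage_dates = stage_dates, truth_yield = truth_yield,
         lai_truth = lai_truth, lai_obs = lai_obs, vi_obs = vi_obs,
         plot_id = pid, plots = plots, obs_sd = obs_sd,
         spatial_cv = spatial_cv, seed = seed),
    class = "synthetic_scene")
}
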