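#' Ensemble configuration for EnKF assimilation
#'
#' @param n_members Ensemble size M (>= 2, default 50).
#' @param model_lai_sd Sd of the additive model-error perturbation applied
#'   to each member's LAI immediately before an update (default 0.20,
#'   the customary simulated-LAI error level).
#' @param obs_lai_sd Sd of the LAI observation error (default 0.25);
#'   `R = obs_lai_sd^2` in the Kalman gain.
#' @param parameter_sd_fraction Sd of the member parameter draws as a
#'   fraction of the parameter mean (default 0.05).
#' @param mode `"parameter_set"`: every calibrated parameter is drawn per
#'   member and the assimilated state is LAI alone. `"single_parameter"`:
#'   members share the default parameters and draw only the
#'   growth-weakness factor, which is appended to the assimilated state so
#'   the filter estimates it jointly with LAI.
#' @param seed Integer RNG seed.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_members = 50, model_lai_sd = 0.20,
                            obs_lai_sd = 0.25, parameter_sd_fraction = 0.05,
                            mode = c("parameter_set", "single_parameter"),
                            seed = 1) {
  mode <- match.arg(mode)
  if (n_members < 2) stop("at least 2 ensemble members are required")
  if (model_lai_sd < 0 || obs_lai_sd <= 0)
    stop("sds must be positive (model_lai_sd may be 0)")
  if (parameter_sd_fraction < 0) stop("parameter_sd_fraction must be >= 0")
  structure(list(n_members = n_members, model_lai_sd = model_lai_sd,
                 obs_lai_sd = obs_lai_sd,
                 parameter_sd_fraction = parameter_sd_fraction,
                 mode = mode, seed = seed),
            class = "ensemble_config")
}

# inverse-CDF truncated normal draws
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(upper, pmax(lower, mean)), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Build a forecast ensemble of simulator instances
#'
#' In `parameter_set` mode every calibrated parameter of every member is
#' drawn from `Normal(mean, parameter_sd_fraction * mean)` and clipped to
#' the +/-30 percent bounds around the mean; the growth-weakness factor is
#' kept at the mean's value. In `single_parameter` mode members share the
#' mean parameters and draw only the growth-weakness factor from
#' `Normal(GWF_init, parameter_sd_fraction * GWF_init)` truncated to
#' \[0.3, 0.8\].
#'
#' @param params_mean `crop_parameters` giving the member means (use the
#'   calibrated set in `parameter_set` mode, hybrid defaults in
#'   `single_parameter` mode).
#' @param cfg An [ensemble_config()].
#' @param gwf_init Initial growth-weakness factor for `single_parameter`
#'   mode (default 0.7).
#' @return A list of class `ensemble` with `par_mat`
#'   (`n_members x 9` matrix), `params_mean`, `cfg`.
#' @export
build_ensemble <- function(params_mean, cfg, gwf_init = 0.7) {
  stopifnot(inherits(params_mean, "crop_parameters"),
            inherits(cfg, "ensemble_config"))
  M <- cfg$n_members
  base <- par_row(params_mean)
  pm <- base[rep(1, M), , drop = FALSE]
  if (cfg$mode == "parameter_set") {
    for (nm in PAR_NAMES) {
      mu <- base[1, nm]
      draw <- stats::rnorm(M, mu, cfg$parameter_sd_fraction * mu)
      pm[, nm] <- pmin(mu * 1.3, pmax(mu * 0.7, draw))
    }
  } else {
    pm[, "GWF"] <- rtruncnorm(M, gwf_init,
                              cfg$parameter_sd_fraction * gwf_init, 0.3, 0.8)
  }
  structure(list(par_mat = pm, params_mean = params_mean, cfg = cfg),
            class = "ensemble")
}

#' One ensemble Kalman filter analysis step
#'
#' Perturbed-observation EnKF update of the state ensemble
#' `A_a = A_f + P H' (H P H' + R)^-1 (D - H A_f)`. Each member's LAI is
#' first jittered by `Normal(0, model_lai_sd^2)` (the model-error
#' perturbation); `P` is the sample covariance of the jittered forecast
#' ensemble; each member assimilates its own perturbed observation
#' `d + Normal(0, obs_lai_sd^2)`; `H` selects the LAI component. Analysed
#' LAI is floored at 0.01.
#'
#' @param A_f Forecast ensemble: numeric vector of member LAIs, or a
#'   `n_state x M` matrix whose first row is LAI (further rows, e.g. an
#'   augmented growth-weakness factor, are updated through their ensemble
#'   covariance with LAI).
#' @param d Observed LAI (scalar, >= 0).
#' @param cfg An [ensemble_config()].
#' @return Analysis ensemble in the shape of `A_f`.
#' @export
enkf_update <- function(A_f, d, cfg) {
  stopifnot(inherits(cfg, "ensemble_config"))
  vec <- is.null(dim(A_f))
  A <- if (vec) matrix(A_f, 1) else A_f
  if (any(!is.finite(A))) stop("non-finite forecast state")
  if (!is.finite(d) || d < 0) stop("observed LAI must be finite and >= 0")
  M <- ncol(A)
  A[1, ] <- A[1, ] + stats::rnorm(M, 0, cfg$model_lai_sd)
  R <- cfg$obs_lai_sd^2
  v <- stats::var(A[1, ])
  if (v == 0) {
    message("zero ensemble LAI variance after perturbation; ",
            "analysis equals forecast")
    K <- numeric(nrow(A))
  } else {
    # P H' for H = (1, 0, ...): covariance of each state row with LAI
    PHt <- apply(A, 1, function(row) stats::cov(row, A[1, ]))
    K <- PHt / (v + R)
  }
  D <- d + stats::rnorm(M, 0, cfg$obs_lai_sd)
  A_a <- A + K %o% (D - A[1, ])
  A_a[1, ] <- pmax(0.01, A_a[1, ])
  if (vec) A_a[1, ] else A_a
}

#' Sequential point-scale assimilation of staged LAI observations
#'
#' Propagates the ensemble through the season and applies
#' [enkf_update()] at each observation date, writing each member's
#' analysed LAI back into its crop state (leaf cohorts rescaled
#' proportionally; in `single_parameter` mode the growth-weakness factor
#' is updated jointly and clipped to \[0.3, 0.8\]). Observation rows with
#' missing LAI are skipped.
#'
#' @param params_mean `crop_parameters` of the ensemble mean.
#' @param weather A `weather_series`.
#' @param obs A [lai_observations()] set (typically jointing, tasseling
#'   and milky stages, ascending dates).
#' @param cfg An [ensemble_config()].
#' @param sowing_date Sowing date.
#' @return List with `yield` (ensemble-mean yield, kg ha-1), `yield_sd`,
#'   `member_yields`, `lai_max` (ensemble mean), `gwf_final` (mean, for
#'   `single_parameter` mode), `ensemble`.
#' @export
assimilate_point <- function(params_mean, weather, obs, cfg, sowing_date) {
  stopifnot(inherits(cfg, "ensemble_config"))
  obs <- obs[!is.na(obs$lai), , drop = FALSE]
  keep <- obs$date %in% weather$date
  if (nrow(obs) > 0 && !any(keep))
    stop("all observation dates fall outside the simulated season")
  obs <- obs[keep, , drop = FALSE]
  set.seed(cfg$seed)
  ens <- build_ensemble(params_mean, cfg)
  single <- cfg$mode == "single_parameter"
  upd <- function(lai, gwf, k) {
    A_f <- if (single) rbind(lai, gwf) else matrix(lai, 1)
    A_a <- enkf_update(A_f, obs$lai[k], cfg)
    list(lai = A_a[1, ],
         gwf = if (single) pmin(0.8, pmax(0.3, A_a[2, ])) else gwf)
  }
  r <- sim_engine(ens$par_mat, params_mean, weather, as.Date(sowing_date),
                  update_dates = if (nrow(obs)) obs$date else NULL,
                  update_fn = if (nrow(obs)) upd else NULL)
  list(yield = mean(r$yield), yield_sd = stats::sd(r$yield),
       member_yields = r$yield, lai_max = mean(r$lai_max),
       gwf_final = mean(r$gwf_final), ensemble = ens)
}

#' Open-loop ensemble run (no assimilation)
#'
#' @inheritParams assimilate_point
#' @return As [assimilate_point()] without observations.
#' @export
open_loop <- function(params_mean, weather, cfg, sowing_date) {
  assimilate_point(params_mean, weather,
                   lai_observations(as.Date(character()), numeric()),
                   cfg, sowing_date)
}

#' Pixel-wise regional assimilation to a yield map
#'
#' Runs the sequential EnKF for every valid pixel of three co-registered
#' stage LAI grids. All pixels share one parameter-draw and one
#' perturbation stream (common random numbers), so identical pixels give
#' identical yields, results do not depend on pixel order, and the whole
#' map is reproducible from the seed; the pixels are propagated in a
#' single vectorised simulator run.
#'
#' @param lai_maps List of three numeric matrices (jointing, tasseling,
#'   milky LAI, m2 m-2), identical dimensions; `NA` marks no-data.
#' @param weather A `weather_series`.
#' @param params_mean `crop_parameters` of the ensemble mean.
#' @param cfg An [ensemble_config()].
#' @param sowing_date Sowing date.
#' @param stage_dates The three observation dates (`Date`, ascending).
#' @return A list of class `yield_map`: `yield` (matrix, kg ha-1,
#'   ensemble mean; `NA` where all three stages are no-data), `yield_sd`
#'   (ensemble sd), `gwf` (mean analysed growth-weakness factor,
#'   `single_parameter` mode), `cfg`.
#' @export
assimilate_region <- function(lai_maps, weather, params_mean, cfg,
                              sowing_date, stage_dates) {
  stopifnot(length(lai_maps) == 3, length(stage_dates) == 3)
  dm <- dim(lai_maps[[1]])
  if (!all(vapply(lai_maps, function(m) identical(dim(m), dm), TRUE)))
    stop("stage LAI grids have mismatching dimensions")
  ny <- dm[1]; nx <- dm[2]; npix <- nx * ny
  M <- cfg$n_members
  set.seed(cfg$seed)
  ens <- build_ensemble(params_mean, cfg)
  # perturbation streams shared across pixels, drawn up-front
  eps_model <- matrix(stats::rnorm(3 * M, 0, cfg$model_lai_sd), M, 3)
  eps_obs <- matrix(stats::rnorm(3 * M, 0, cfg$obs_lai_sd), M, 3)
  # columns: pixel-major blocks of M members
  pm <- ens$par_mat[rep(seq_len(M), npix), , drop = FALSE]
  single <- cfg$mode == "single_parameter"
  R <- cfg$obs_lai_sd^2
  upd <- function(lai, gwf, k) {
    d <- as.vector(lai_maps[[k]])
    Lf <- matrix(lai, M, npix) + eps_model[, k]
    P <- .colMeans(Lf^2, M, npix) - .colMeans(Lf, M, npix)^2
    P <- P * M / (M - 1)
    gain_ok <- !is.na(d) & d >= 0 & P > 0
    K <- ifelse(gain_ok, P / (P + R), 0)
    innov <- sweep(-Lf, 2, d, "+") + eps_obs[, k]   # D - H A_f
    innov[, !gain_ok] <- 0
    La <- Lf + sweep(innov, 2, K, "*")
    La[La < 0.01] <- 0.01
    out_gwf <- gwf
    if (single) {
      G <- matrix(gwf, M, npix)
      C <- .colMeans(Lf * G, M, npix) - .colMeans(Lf, M, npix) * .colMeans(G, M, npix)
      C <- C * M / (M - 1)
      Kg <- ifelse(gain_ok, C / (P + R), 0)
      Ga <- G + sweep(innov, 2, Kg, "*")
      Ga[Ga < 0.3] <- 0.3; Ga[Ga > 0.8] <- 0.8
      out_gwf <- as.vector(Ga)
    }
    list(lai = as.vector(La), gwf = out_gwf)
  }
  r <- sim_engine(pm, params_mean, weather, as.Date(sowing_date),
                  update_dates = stage_dates, update_fn = upd)
  ym <- matrix(.colMeans(matrix(r$yield, M, npix), M, npix), ny, nx)
  ysd <- matrix(apply(matrix(r$yield, M, npix), 2, stats::sd), ny, nx)
  gwf_map <- matrix(.colMeans(matrix(r$gwf_final, M, npix), M, npix), ny, nx)
  nodata <- Reduce(`&`, lapply(lai_maps, is.na))
  ym[nodata] <- NA; ysd[nodata] <- NA; gwf_map[nodata] <- NA
  structure(list(yield = ym, yield_sd = ysd, gwf = gwf_map, cfg = cfg),
            class = "yield_map")
}

#' Plot-level validation of yield estimates
#'
#' @param estimates Estimated plot yields, kg ha-1 (or a yield matrix plus
#'   `plot_id` to aggregate pixel yields to plot means first).
#' @param measured Measured plot yields, kg ha-1 (paired, >= 3 plots).
#' @param plot_id Optional integer matrix assigning pixels to plots.
#' @return List with `r_squared` (squared Pearson correlation; `NA` with a
#'   warning when the measured yields have zero variance) and `rmse`
#'   (kg ha-1).
#' @examples
#' validate_yield(c(6100, 6900, 7500), c(6000, 7000, 7600))
#' @export
validate_yield <- function(estimates, measured, plot_id = NULL) {
  if (!is.null(plot_id)) {
    ids <- sort(unique(as.vector(plot_id[!is.na(plot_id)])))
    estimates <- vapply(ids, function(id)
      mean(estimates[plot_id == id], na.rm = TRUE), 0)
  }
  ok <- is.finite(estimates) & is.finite(measured)
  estimates <- estimates[ok]; measured <- measured[ok]
  if (length(estimates) < 3) stop("at least 3 paired plots are required")
  r2 <- if (stats::var(measured) == 0) {
    warning("measured yields have zero variance; R squared undefined")
    NA_real_
  } else stats::cor(estimates, measured)^2
  list(r_squared = r2, rmse = sqrt(mean((estimates - measured)^2)))
}
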