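#' Truncated-normal prior specification for calibration
#'
#' Independent truncated-normal priors: mean at the default parameter
#' value, standard deviation a fraction of the mean, and hard bounds at a
#' +/-30 percent float of the default (the customary float used when
#' calibrating crop variety parameters).
#'
#' @param means Named numeric vector of default parameter values.
#' @param sd_fraction Prior sd as a fraction of the mean (default 0.10).
#' @param float Fractional float defining the hard bounds (default 0.30).
#' @return A list of class `prior_spec` with `means`, `sd`, `lower`,
#'   `upper`.
#' @export
prior_spec <- function(means = hybrid_defaults(), sd_fraction = 0.10,
                       float = 0.30) {
  if (sd_fraction <= 0) stop("sd_fraction must be positive")
  structure(list(means = means, sd = sd_fraction * abs(means),
                 lower = means * (1 - float), upper = means * (1 + float)),
            class = "prior_spec")
}

#' LAI observation set
#'
#' @param dates Observation dates (within the simulated season).
#' @param lai Observed LAI values, m2 m-2 (non-negative).
#' @param sd Observation standard deviation(s), m2 m-2 (default 0.25,
#'   recycled).
#' @return A data frame of class `lai_observations`.
#' @export
lai_observations <- function(dates, lai, sd = 0.25) {
  if (any(lai < 0)) stop("LAI observations must be non-negative")
  if (any(sd <= 0)) stop("observation sd must be positive")
  o <- data.frame(date = as.Date(dates), lai = lai,
                  sd = rep(sd, length.out = length(lai)))
  o <- o[order(o$date), ]
  class(o) <- c("lai_observations", "data.frame")
  o
}

# simulate LAI at the observation dates for a chains x d theta matrix
sim_lai_at <- function(theta, obs, weather, sowing_date, aux) {
  pm <- par_row(aux)[rep(1, nrow(theta)), , drop = FALSE]
  pm[, colnames(theta)] <- theta
  r <- sim_engine(pm, aux, weather, as.Date(sowing_date),
                  record_dates = obs$date)
  r$lai_record   # n_obs x chains
}

#' Log posterior density of crop parameters given LAI observations
#'
#' Gaussian log-likelihood of the simulated LAI at the observation dates
#' plus independent truncated-normal log-priors; `-Inf` outside the hard
#' bounds. Rows of a matrix `theta` are evaluated in one vectorised
#' simulator call.
#'
#' @param theta Named parameter vector, or matrix with one row per
#'   evaluation point (columns named after prior parameters).
#' @param priors A [prior_spec()].
#' @param obs A [lai_observations()] set.
#' @param weather A `weather_series`.
#' @param sowing_date Sowing date.
#' @param aux `crop_parameters` supplying auxiliaries and non-calibrated
#'   values.
#' @return Numeric vector of log-posterior values (one per row of
#'   `theta`).
#' @export
log_posterior <- function(theta, priors, obs, weather, sowing_date,
                          aux = crop_parameters()) {
  if (is.null(dim(theta)))
    theta <- matrix(theta, 1, dimnames = list(NULL, names(theta)))
  stopifnot(identical(colnames(theta), names(priors$means)))
  inb <- rep(TRUE, nrow(theta))
  for (j in seq_along(priors$means))
    inb <- inb & theta[, j] >= priors$lower[j] & theta[, j] <= priors$upper[j]
  lp <- rep(-Inf, nrow(theta))
  if (!any(inb)) return(lp)
  th <- theta[inb, , drop = FALSE]
  sim <- sim_lai_at(th, obs, weather, sowing_date, aux)
  ll <- -colSums((sim - obs$lai)^2 / (2 * obs$sd^2))
  pr <- rowSums(stats::dnorm(th, rep(priors$means, each = nrow(th)),
                             rep(priors$sd, each = nrow(th)), log = TRUE))
  ll[!is.finite(ll)] <- -Inf
  lp[inb] <- ll + pr
  lp
}

#' Random-walk Metropolis sampler (vectorised over independent chains)
#'
#' Joint Gaussian proposals for all parameters; the proposal scale is
#' adapted during burn-in toward a 20-40 percent acceptance rate and frozen
#' afterwards (preserving the stationary distribution of the retained
#' samples). Chains are independent replicates run in lock-step so a
#' vectorised log-posterior evaluates all of them per iteration.
#'
#' @param logpost `function(theta_matrix) -> numeric` (one value per row).
#' @param init Initial point (named vector) or `n_chains x d` matrix.
#' @param prop_sd Initial per-parameter proposal sd.
#' @param n_iter,n_burn Post-burn-in iterations and burn-in length.
#' @param seed Integer RNG seed.
#' @param n_chains Number of independent chains.
#' @return List with `chains` (`n_iter x d x n_chains` array),
#'   `acceptance_rate` (per chain), `map_estimate`, `prop_sd` (final).
#' @keywords internal
metropolis <- function(logpost, init, prop_sd, n_iter, n_burn = 0,
                       seed = 1, n_chains = 1) {
  if (n_iter <= 0) stop("n_iter must be positive")
  if (n_burn < 0) stop("n_burn must be non-negative")
  set.seed(seed)
  if (is.null(dim(init)))
    init <- matrix(init, n_chains, length(init), byrow = TRUE,
                   dimnames = list(NULL, names(init)))
  d <- ncol(init)
  cur <- init
  lp_cur <- logpost(cur)
  if (any(!is.finite(lp_cur))) stop("initial point has zero posterior density")
  scale <- rep(1, n_chains)
  total <- n_burn + n_iter
  out <- array(NA_real_, c(n_iter, d, n_chains),
               dimnames = list(NULL, colnames(init), NULL))
  acc <- numeric(n_chains)
  acc_win <- numeric(n_chains)
  map_lp <- lp_cur; map_theta <- cur
  for (it in seq_len(total)) {
    # record the state entering the iteration (the chain includes init)
    if (it > n_burn) out[it - n_burn, , ] <- t(cur)
    prop <- cur + matrix(stats::rnorm(n_chains * d), n_chains, d) *
      (scale %o% prop_sd)
    colnames(prop) <- colnames(init)
    lp_prop <- logpost(prop)
    u <- stats::runif(n_chains)
    take <- log(u) < lp_prop - lp_cur
    cur[take, ] <- prop[take, , drop = FALSE]
    lp_cur[take] <- lp_prop[take]
    better <- lp_cur > map_lp
    map_lp[better] <- lp_cur[better]
    map_theta[better, ] <- cur[better, , drop = FALSE]
    acc_win <- acc_win + take
    if (it <= n_burn && it %% 50 == 0) {
      rate <- acc_win / 50
      scale <- scale * ifelse(rate < 0.20, 0.8, ifelse(rate > 0.40, 1.25, 1))
      acc_win[] <- 0
    }
    if (it > n_burn) acc <- acc + take
  }
  list(chains = out, acceptance_rate = acc / n_iter,
       map_estimate = map_theta, map_lp = map_lp,
       prop_sd = scale %o% prop_sd)
}

#' MCMC calibration of crop parameters against LAI observations
#'
#' Random-walk Metropolis sampling of the posterior defined by
#' [log_posterior()]: truncated-normal priors around the default parameter
#' values and a Gaussian LAI likelihood. Several independent chains can be
#' run in lock-step (vectorised through the simulator); summaries are
#' reported per chain.
#'
#' @param priors A [prior_spec()].
#' @param obs A [lai_observations()] set shared by all chains, or a list
#'   of `n_chains` observation sets with identical dates (one per chain,
#'   e.g. independent noise realisations in a repeated recovery
#'   experiment).
#' @param weather A `weather_series`.
#' @param sowing_date Sowing date.
#' @param n_iter Post-burn-in iterations.
#' @param n_burn Burn-in iterations (with proposal adaptation).
#' @param seed Integer RNG seed.
#' @param n_chains Independent chains (default 1).
#' @param aux Auxiliary `crop_parameters`.
#' @return A list of class `calibration_result`: `chains`
#'   (`n_iter x d x n_chains`), `acceptance_rate`, `posterior_mean`,
#'   `posterior_median` (`d x n_chains` matrices), `ci95`
#'   (`2 x d x n_chains`), `map_estimate`.
#' @export
mcmc_calibrate <- function(priors, obs, weather, sowing_date,
                           n_iter = 5000, n_burn = 1000, seed = 1,
                           n_chains = 1, aux = crop_parameters()) {
  stopifnot(inherits(priors, "prior_spec"))
  if (n_iter <= 0) stop("n_iter must be positive")
  if (n_burn < 0) stop("n_burn must be non-negative")
  if (is.data.frame(obs)) {
    lpfun <- function(m) log_posterior(m, priors, obs, weather, sowing_date,
                                       aux = aux)
  } else {
    # one observation set per chain, evaluated in one simulator call
    stopifnot(length(obs) == n_chains)
    dates <- obs[[1]]$date
    if (!all(vapply(obs, function(o) identical(o$date, dates), TRUE)))
      stop("per-chain observation sets must share the same dates")
    lai_mat <- vapply(obs, function(o) o$lai, numeric(length(dates)))
    sd_mat <- vapply(obs, function(o) o$sd, numeric(length(dates)))
    obs1 <- obs[[1]]
    lpfun <- function(m) {
      # rows of m are the chains, in order
      inb <- rep(TRUE, nrow(m))
      for (j in seq_along(priors$means))
        inb <- inb & m[, j] >= priors$lower[j] & m[, j] <= priors$upper[j]
      lp <- rep(-Inf, nrow(m))
      if (!any(inb)) return(lp)
      th <- m[inb, , drop = FALSE]
      sim <- sim_lai_at(th, obs1, weather, sowing_date, aux)
      ll <- -colSums((sim - lai_mat[, inb, drop = FALSE])^2 /
                       (2 * sd_mat[, inb, drop = FALSE]^2))
      pr <- rowSums(stats::dnorm(th, rep(priors$means, each = nrow(th)),
                                 rep(priors$sd, each = nrow(th)),
                                 log = TRUE))
      ll[!is.finite(ll)] <- -Inf
      lp[inb] <- ll + pr
      lp
    }
  }
  res <- metropolis(lpfun, init = priors$means, prop_sd = 0.5 * priors$sd,
                    n_iter = n_iter, n_burn = n_burn, seed = seed,
                    n_chains = n_chains)
  if (any(res$acceptance_rate < 0.01))
    stop("Metropolis acceptance rate below 1% after tuning; ",
         "check the observation set and priors")
  d <- length(priors$means)
  pm <- apply(res$chains, c(2, 3), mean)
  pmed <- apply(res$chains, c(2, 3), stats::median)
  ci <- apply(res$chains, c(2, 3), stats::quantile, c(0.025, 0.975))
  structure(list(chains = res$chains,
                 acceptance_rate = res$acceptance_rate,
                 posterior_mean = pm, posterior_median = pmed,
                 ci95 = ci, map_estimate = res$map_estimate,
                 priors = priors),
            class = "calibration_result")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Split-free multi-chain PSRF, a convergence diagnostic for
#' [mcmc_calibrate()] runs with `n_chains > 1`.
#'
#' @param chains `n_iter x d x n_chains` array.
#' @return Named vector of PSRF values (one per parameter).
#' @export
gelman_rubin <- function(chains) {
  stopifnot(length(dim(chains)) == 3, dim(chains)[3] >= 2)
  n <- dim(chains)[1]; m <- dim(chains)[3]
  vapply(seq_len(dim(chains)[2]), function(j) {
    x <- chains[, j, ]
    W <- mean(apply(x, 2, stats::var))
    B <- n * stats::var(colMeans(x))
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0) -> r
  stats::setNames(r, dimnames(chains)[[2]])
}
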