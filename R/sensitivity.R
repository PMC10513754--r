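#' Parameter space for sensitivity analysis
#'
#' @param names Parameter names.
#' @param lower,upper Elementwise bounds (`lower < upper`).
#' @param defaults Nominal values, within bounds (defaults to the midpoint).
#' @return A list of class `parameter_space`.
#' @export
parameter_space <- function(names, lower, upper,
                            defaults = (lower + upper) / 2) {
  stopifnot(length(names) == length(lower), length(lower) == length(upper))
  if (any(lower >= upper)) stop("lower bounds must be below upper bounds")
  if (any(defaults < lower | defaults > upper))
    stop("defaults must lie within bounds")
  structure(list(names = names, lower = lower, upper = upper,
                 defaults = defaults),
            class = "parameter_space")
}

#' Parameter space spanning +/-30 percent of a nominal parameter set
#'
#' Convenience constructor: bounds at `default * (1 -/+ float)` around each
#' of the eight calibrated crop parameters.
#'
#' @param values Named nominal values (default [inbred_optimized()]).
#' @param float Fractional float (default 0.30).
#' @return A [parameter_space()].
#' @export
crop_parameter_space <- function(values = inbred_optimized(), float = 0.30) {
  parameter_space(names(values), values * (1 - float), values * (1 + float),
                  defaults = values)
}

#' Sobol variance-based sensitivity analysis
#'
#' Saltelli-scheme radial sampling of `(d + 2) * base_samples` model
#' evaluations with uniform priors over the bounds; the two base matrices
#' are Latin-hypercube stratified for variance reduction and both the
#' first-order and the total-order indices use the low-variance Jansen
#' estimators.
#'
#' @param model_fn Function mapping an `n x d` parameter matrix (columns in
#'   `space$names` order) to a numeric vector of length `n`, or a matrix
#'   with one column per analysis target.
#' @param space A [parameter_space()].
#' @param base_samples Base sample count `N`, a power of two >= 64.
#' @param seed Integer RNG seed.
#' @param targets Optional names for the model output columns.
#' @return A list of class `sensitivity_result` (one per target, invisibly
#'   wrapped in a list when the model is multi-target) with elements
#'   `target`, `first_order`, `total_order`, `sample_count` and `conf`
#'   (bootstrap-free large-sample half-widths).
#' @examples
#' sp <- parameter_space(c("x1", "x2"), c(0, 0), c(1, 1))
#' f <- function(m) m[, 1] + 2 * m[, 2]
#' sobol_analyze(f, sp, 1024, seed = 1)[[1]]$first_order
#' @export
sobol_analyze <- function(model_fn, space, base_samples, seed = 1,
                          targets = NULL) {
  stopifnot(inherits(space, "parameter_space"))
  N <- base_samples
  if (N < 64 || bitwAnd(N, N - 1L) != 0)
    stop("base_samples must be a power of 2 and at least 64")
  d <- length(space$names)
  set.seed(seed)
  scale <- function(u) sweep(sweep(u, 2, space$upper - space$lower, "*"),
                             2, space$lower, "+")
  A <- scale(lhs::randomLHS(N, d))
  B <- scale(lhs::randomLHS(N, d))
  colnames(A) <- colnames(B) <- space$names
  X <- rbind(A, B)
  for (i in seq_len(d)) {
    ABi <- A
    ABi[, i] <- B[, i]
    X <- rbind(X, ABi)
  }
  Y <- model_fn(X)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  if (anyNA(Y) || any(!is.finite(Y))) {
    bad <- which(!is.finite(Y[, 1]))[1]
    stop("model_fn returned a non-finite value (first at design row ", bad,
         "); check the parameterisation")
  }
  if (is.null(targets))
    targets <- colnames(Y) %||% paste0("y", seq_len(ncol(Y)))
  out <- lapply(seq_len(ncol(Y)), function(t) {
    y <- Y[, t]
    yA <- y[1:N]; yB <- y[(N + 1):(2 * N)]
    V <- stats::var(c(yA, yB))
    Si <- Ti <- ci_s <- ci_t <- numeric(d)
    for (i in seq_len(d)) {
      yABi <- y[(2 * N + (i - 1) * N + 1):(2 * N + i * N)]
      e1 <- V - (yB - yABi)^2 / 2       # Jansen first-order
      e2 <- (yA - yABi)^2 / 2           # Jansen total-order
      Si[i] <- mean(e1) / V
      Ti[i] <- mean(e2) / V
      ci_s[i] <- 1.96 * stats::sd(e1) / sqrt(N) / V
      ci_t[i] <- 1.96 * stats::sd(e2) / sqrt(N) / V
    }
    structure(list(target = targets[t],
                   first_order = stats::setNames(Si, space$names),
                   total_order = stats::setNames(Ti, space$names),
                   conf_first = stats::setNames(ci_s, space$names),
                   conf_total = stats::setNames(ci_t, space$names),
                   sample_count = N),
              class = "sensitivity_result")
  })
  names(out) <- targets
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen sensitive parameters across analysis targets
#'
#' A parameter is sensitive for a target when its first-order OR
#' total-order index exceeds `threshold`; the returned set is the union
#' across targets, ordered by decreasing maximum index.
#'
#' @param results List of `sensitivity_result` objects (e.g. the return of
#'   [sobol_analyze()] on a multi-target model).
#' @param threshold Sensitivity threshold (default 0.05).
#' @return Character vector of sensitive parameter names.
#' @export
screen_sensitive <- function(results, threshold = 0.05) {
  if (inherits(results, "sensitivity_result")) results <- list(results)
  if (!length(results)) stop("at least one sensitivity result is required")
  score <- NULL
  for (r in results) {
    s <- pmax(r$first_order, r$total_order)
    score <- if (is.null(score)) s else pmax(score, s)
  }
  names(sort(score[score > threshold], decreasing = TRUE))
}

#' Sobol analysis of the crop simulator
#'
#' Runs [sobol_analyze()] with the reduced-order simulator as the model,
#' returning per-parameter indices for the two standard targets `LAIMAX`
#' (seasonal maximum leaf area index) and `TWSO` (storage-organ dry weight
#' at maturity).
#'
#' @param space A [parameter_space()] over (a subset of) the eight
#'   calibrated parameters.
#' @param weather A `weather_series`.
#' @param sowing_date Sowing date.
#' @param base_samples,seed Passed to [sobol_analyze()].
#' @param aux `crop_parameters` supplying auxiliaries and the values of
#'   parameters not in `space`.
#' @return Named list of two `sensitivity_result`s (`LAIMAX`, `TWSO`).
#' @export
sobol_crop <- function(space, weather, sowing_date, base_samples = 256,
                       seed = 1, aux = crop_parameters()) {
  model <- function(m) {
    pm <- par_row(aux)[rep(1, nrow(m)), , drop = FALSE]
    pm[, colnames(m)] <- m
    r <- sim_engine(pm, aux, weather, as.Date(sowing_date))
    cbind(LAIMAX = r$lai_max, TWSO = r$twso)
  }
  sobol_analyze(model, space, base_samples, seed = seed,
                targets = c("LAIMAX", "TWSO"))
}
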