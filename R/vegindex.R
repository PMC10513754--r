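VI_NAMES <- c("NDVI", "EVI", "NDGI", "kNDVI")

#' Compute a vegetation index from band reflectances
#'
#' Supported indices (surface reflectances in \[0, 1\]):
#' \describe{
#'   \item{NDVI}{`(R_nir - R_red) / (R_nir + R_red)`}
#'   \item{EVI}{`2.5 (R_nir - R_red) / (R_nir + 6 R_red - 7.5 R_blue + 1)`}
#'   \item{NDGI}{`(R_green - R_red) / (R_green + R_red)`}
#'   \item{kNDVI}{`tanh(NDVI^2)`}
#' }
#' A zero denominator yields `NaN` with a warning (undefined-value
#' sentinel) rather than an error, so raster workflows can proceed.
#'
#' @param bands Named list or data frame with elements among `blue`,
#'   `green`, `red`, `nir` (vectors allowed).
#' @param which One of `"NDVI"`, `"EVI"`, `"NDGI"`, `"kNDVI"`.
#' @return Index value(s), dimensionless.
#' @examples
#' compute_vi(list(nir = 0.5, red = 0.1, blue = 0.04), "EVI")
#' @export
compute_vi <- function(bands, which = c("NDVI", "EVI", "NDGI", "kNDVI")) {
  which <- match.arg(which)
  need <- switch(which, NDVI = c("nir", "red"), kNDVI = c("nir", "red"),
                 EVI = c("nir", "red", "blue"), NDGI = c("green", "red"))
  miss <- setdiff(need, names(bands))
  if (length(miss)) stop("missing band(s): ", paste(miss, collapse = ", "))
  for (b in need)
    if (any(bands[[b]] < 0 | bands[[b]] > 1, na.rm = TRUE))
      stop("reflectance outside [0, 1] in band ", b)
  safe_ratio <- function(num, den) {
    bad <- den == 0
    if (any(bad, na.rm = TRUE))
      warning("zero denominator in vegetation index; returning NaN")
    ifelse(bad, NaN, num / den)
  }
  switch(which,
    NDVI = safe_ratio(bands$nir - bands$red, bands$nir + bands$red),
    NDGI = safe_ratio(bands$green - bands$red, bands$green + bands$red),
    EVI = safe_ratio(2.5 * (bands$nir - bands$red),
                     bands$nir + 6 * bands$red - 7.5 * bands$blue + 1),
    kNDVI = tanh(safe_ratio(bands$nir - bands$red,
                            bands$nir + bands$red)^2))
}

#' Stage-specific empirical VI-to-LAI model
#'
#' A one-dimensional linear retrieval model `LAI = slope * VI + intercept`
#' for one phenological stage, with held-out validation diagnostics.
#'
#' @param stage One of `"jointing"`, `"tasseling"`, `"milky"`.
#' @param vi_name Index name (`"NDVI"`, `"EVI"`, `"NDGI"`, `"kNDVI"`).
#' @param slope,intercept Model coefficients.
#' @param r_squared Validation coefficient of determination (squared
#'   Pearson correlation on the held-out split).
#' @param rmse Validation RMSE, m2 m-2.
#' @param n_train,n_valid Split sizes.
#' @param slope_se,intercept_se Coefficient standard errors from the fit.
#' @return A list of class `empirical_lai_model`.
#' @export
empirical_lai_model <- function(stage, vi_name, slope, intercept,
                                r_squared = NA_real_, rmse = NA_real_,
                                n_train = NA_integer_, n_valid = NA_integer_,
                                slope_se = NA_real_, intercept_se = NA_real_) {
  stage <- match.arg(stage, c("jointing", "tasseling", "milky"))
  vi_name <- match.arg(vi_name, VI_NAMES)
  structure(list(stage = stage, vi_name = vi_name, slope = slope,
                 intercept = intercept, r_squared = r_squared, rmse = rmse,
                 n_train = n_train, n_valid = n_valid,
                 slope_se = slope_se, intercept_se = intercept_se),
            class = "empirical_lai_model")
}

#' @export
print.empirical_lai_model <- function(x, ...) {
  cat(sprintf("%s-stage %s model: LAI = %.4g VI %+.4g  (R2 = %.3g, RMSE = %.3g, n = %d/%d)\n",
              x$stage, x$vi_name, x$slope, x$intercept,
              x$r_squared, x$rmse,
              if (is.na(x$n_train)) 0L else x$n_train,
              if (is.na(x$n_valid)) 0L else x$n_valid))
  invisible(x)
}

#' Fit a stage-specific linear VI-to-LAI model
#'
#' Ordinary-least-squares fit of `LAI ~ VI` on a seeded random 70 percent
#' of the samples; `r_squared` (squared Pearson correlation) and `rmse` are
#' computed on the held-out 30 percent.
#'
#' @param vi_values Vegetation-index values.
#' @param lai_values Paired LAI measurements, m2 m-2 (>= 10 pairs).
#' @param stage,vi_name Labels stored in the model.
#' @param train_fraction Fraction of samples used for fitting.
#' @param seed Integer seed for the random split.
#' @return An [empirical_lai_model()].
#' @export
fit_lai_model <- function(vi_values, lai_values,
                          stage = "jointing", vi_name = "NDVI",
                          train_fraction = 0.7, seed = 1) {
  stopifnot(length(vi_values) == length(lai_values))
  ok <- is.finite(vi_values) & is.finite(lai_values)
  vi_values <- vi_values[ok]; lai_values <- lai_values[ok]
  n <- length(vi_values)
  if (n < 10) stop("at least 10 paired samples are required")
  if (stats::var(vi_values) == 0)
    stop("degenerate fit: vegetation index has zero variance")
  set.seed(seed)
  n_train <- round(train_fraction * n)
  tr <- sample.int(n, n_train)
  fit <- stats::lm(lai ~ vi,
                   data = data.frame(vi = vi_values[tr], lai = lai_values[tr]))
  co <- summary(fit)$coefficients
  va <- setdiff(seq_len(n), tr)
  pred <- co["vi", "Estimate"] * vi_values[va] + co["(Intercept)", "Estimate"]
  resid <- lai_values[va] - pred
  r2 <- if (stats::var(lai_values[va]) == 0 || stats::var(pred) == 0)
    NA_real_ else stats::cor(pred, lai_values[va])^2
  empirical_lai_model(stage, vi_name,
                      slope = unname(co["vi", "Estimate"]),
                      intercept = unname(co["(Intercept)", "Estimate"]),
                      r_squared = r2,
                      rmse = sqrt(mean(resid^2)),
                      n_train = length(tr), n_valid = length(va),
                      slope_se = unname(co["vi", "Std. Error"]),
                      intercept_se = unname(co["(Intercept)", "Std. Error"]))
}

#' Select the best retrieval model among candidates
#'
#' Ranks candidate [empirical_lai_model()]s by validation `r_squared`
#' (descending); ties are broken by lower `rmse`, then by the fixed index
#' order NDVI, EVI, NDGI, kNDVI.
#'
#' @param candidates Non-empty list of `empirical_lai_model` objects.
#' @return The winning model.
#' @export
select_best_model <- function(candidates) {
  if (!length(candidates)) stop("empty candidate list")
  if (inherits(candidates, "empirical_lai_model")) return(candidates)
  r2 <- vapply(candidates, function(m) m$r_squared, 0)
  rmse <- vapply(candidates, function(m) m$rmse, 0)
  vio <- match(vapply(candidates, function(m) m$vi_name, ""), VI_NAMES)
  candidates[[order(-r2, rmse, vio)[1]]]
}

#' Apply a retrieval model to a vegetation-index grid
#'
#' Per-pixel `LAI = slope * VI + intercept`, floored at 0; `NA` (no-data)
#' pixels propagate.
#'
#' @param vi_raster Numeric matrix of index values.
#' @param model An [empirical_lai_model()].
#' @return LAI matrix, m2 m-2.
#' @examples
#' m <- default_lai_models()$jointing
#' estimate_lai_map(matrix(0.5, 2, 2), m)  # all 6.7
#' @export
estimate_lai_map <- function(vi_raster, model) {
  stopifnot(is.matrix(vi_raster), inherits(model, "empirical_lai_model"))
  pmax(model$slope * vi_raster + model$intercept, 0)
}
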