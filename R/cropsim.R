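#' @keywords internal
PAR_NAMES <- c("SLATB000", "SLATB078", "CVO", "TSUM1", "TDWI",
               "SPAN", "TBASE", "TMPFTB200")

#' Calibrated-parameter sets
#'
#' `hybrid_defaults()` returns the default variety parameter values of a
#' hybrid maize cultivar; `inbred_optimized()` returns the calibrated set for
#' a weaker-growing inbred seed-production line. The eight named parameters
#' (`SLATB000`, `SLATB078`, `CVO`, `TSUM1`, `TDWI`, `SPAN`, `TBASE`,
#' `TMPFTB200`) are the calibration targets of the pipeline; everything else
#' in a [crop_parameters()] object is a fixed auxiliary.
#'
#' @return A named numeric vector of the eight calibrated parameters.
#' @export
hybrid_defaults <- function() {
  c(SLATB000 = 0.0026, SLATB078 = 0.0012, CVO = 0.671, TSUM1 = 695,
    TDWI = 50, SPAN = 33, TBASE = 10, TMPFTB200 = 1)
}

#' @rdname hybrid_defaults
#' @export
inbred_optimized <- function() {
  c(SLATB000 = 0.002, SLATB078 = 0.0016, CVO = 0.63, TSUM1 = 735,
    TDWI = 35, SPAN = 39, TBASE = 10, TMPFTB200 = 0.8)
}

#' Crop variety parameters
#'
#' Container for the maize variety parameters of the reduced-order
#' potential-production simulator.
#'
#' @details The eight calibrated parameters carried in `values` are:
#'   `SLATB000` / `SLATB078`, specific leaf area (ha kg-1) at DVS 0 and
#'   0.78 (constant beyond 0.78); `CVO`, conversion efficiency of
#'   assimilate into storage organs (kg kg-1, in (0, 1\]); `TSUM1`,
#'   temperature sum emergence to anthesis (degC d); `TDWI`, initial total
#'   crop dry weight at emergence (kg ha-1); `SPAN`, life span of leaves
#'   growing at 35 degC (d); `TBASE`, lower threshold temperature for
#'   physiological leaf ageing (degC); `TMPFTB200`, correction factor on
#'   assimilation at 20 degC.
#'
#' @param values Named numeric vector of calibrated-parameter overrides
#'   (any subset of `SLATB000 ... TMPFTB200`), or an unnamed vector of all
#'   eight in canonical order; defaults to [hybrid_defaults()].
#' @param GWF Growth-weakness factor multiplying daily gross growth; 1 for a
#'   hybrid, 0.3-0.8 when emulating an inbred line with a single scalar.
#' @param TSUM2 Temperature sum anthesis to maturity, degC d (auxiliary).
#' @param TBASE_PHENO Base temperature for phenological thermal time, degC.
#' @param RUE Net radiation-use efficiency, g dry matter per MJ intercepted
#'   PAR. The model carries no explicit respiration term, so a net value
#'   (default 1.8, the conventional maize magnitude) is appropriate; a
#'   gross-assimilation value (~3) would inflate LAI and yield.
#' @param K_EXT Canopy light extinction coefficient.
#' @param moisture Standard grain moisture fraction used for the dry-matter
#'   to fresh-yield conversion.
#' @param emergence_lag Days from sowing to emergence.
#' @param t_resp_knots,t_resp_values Knots (degC) and values of the
#'   piecewise-linear temperature response of assimilation; the value at the
#'   20 degC knot is overridden by `TMPFTB200`.
#' @param partition_dvs,partition_leaf,partition_storage DVS knots and the
#'   fractions of daily growth routed to leaves and storage organs
#'   (linearly interpolated; the remainder goes to stems + roots).
#'
#' @return A list of class `crop_parameters`.
#' @examples
#' p <- crop_parameters()            # hybrid defaults
#' q <- crop_parameters(inbred_optimized())
#' @export
crop_parameters <- function(values = hybrid_defaults(),
                            GWF = 1,
                            TSUM2 = 800, TBASE_PHENO = 8,
                            RUE = 1.8, K_EXT = 0.6,
                            moisture = 0.14, emergence_lag = 7,
                            t_resp_knots = c(0, 12, 20, 28, 35, 40),
                            t_resp_values = c(0, 0.7, NA, 1, 1, 0.5),
                            partition_dvs = c(0, 0.78, 0.95, 1, 2),
                            partition_leaf = c(0.65, 0.30, 0.10, 0, 0),
                            partition_storage = c(0, 0, 0, 0.8, 1)) {
  v <- hybrid_defaults()
  if (!is.null(names(values))) {
    unknown <- setdiff(names(values), PAR_NAMES)
    if (length(unknown)) stop("unknown parameter(s): ",
                              paste(unknown, collapse = ", "))
    v[names(values)] <- values
  } else {
    stopifnot(length(values) == length(PAR_NAMES))
    v[] <- values
  }
  if (any(v <= 0)) stop("all calibrated parameters must be positive")
  if (v["CVO"] > 1) stop("CVO must lie in (0, 1]")
  if (GWF <= 0 || GWF > 1) stop("GWF must lie in (0, 1]")
  if (any(partition_leaf + partition_storage > 1 + 1e-12))
    stop("partition fractions exceed 1 at a DVS knot")
  structure(
    c(as.list(v),
      list(GWF = GWF, TSUM2 = TSUM2, TBASE_PHENO = TBASE_PHENO, RUE = RUE,
           K_EXT = K_EXT, moisture = moisture, emergence_lag = emergence_lag,
           t_resp_knots = t_resp_knots, t_resp_values = t_resp_values,
           partition_dvs = partition_dvs, partition_leaf = partition_leaf,
           partition_storage = partition_storage)),
    class = "crop_parameters")
}

#' Set the growth-weakness factor
#'
#' Returns a copy of `params` with the growth-weakness factor (GWF) set.
#' GWF scales daily gross growth to emulate the weaker growth of inbred
#' lines relative to hybrids; admissible values are 0.3-0.8 (an inbred
#' grows roughly 30-80 percent as much as a hybrid, about 70 percent for
#' gramineous crops, hence the customary initial value 0.7).
#'
#' @param params A [crop_parameters()] object.
#' @param gwf Growth-weakness factor in \[0.3, 0.8\].
#' @return A `crop_parameters` copy with `GWF = gwf`.
#' @export
set_growth_weakness <- function(params, gwf) {
  stopifnot(inherits(params, "crop_parameters"))
  if (gwf < 0.3 || gwf > 0.8)
    stop("growth-weakness factor must lie in [0.3, 0.8]")
  params$GWF <- gwf
  params
}

#' Yield at standard moisture from storage-organ dry weight
#'
#' @param twso Total dry weight of storage organs, kg ha-1.
#' @param moisture Standard grain moisture fraction in \[0, 1).
#' @return Fresh yield `twso / (1 - moisture)`, kg ha-1.
#' @examples
#' yield_from_twso(6000, 0.14)  # 6976.74
#' @export
yield_from_twso <- function(twso, moisture = 0.14) {
  if (any(moisture < 0 | moisture >= 1))
    stop("moisture must lie in [0, 1)")
  if (any(twso < 0)) stop("twso must be non-negative")
  twso / (1 - moisture)
}

# piecewise-linear interpolation with flat extrapolation; xk ascending
lin_interp <- function(xk, yk, x) {
  i <- findInterval(x, xk, all.inside = TRUE)
  x0 <- xk[i]; x1 <- xk[i + 1]
  w <- (x - x0) / (x1 - x0)
  w[w < 0] <- 0; w[w > 1] <- 1
  yk[i] * (1 - w) + yk[i + 1] * w
}

# temperature response of assimilation for a scalar temperature and a
# per-member TMPFTB200 vector; returns a vector aligned with tmpf
t_response <- function(t_avg, tmpf, knots, values) {
  i20 <- which(knots == 20)
  lo <- values; hi <- values
  # interpolate twice with the 20 degC knot at 0 and at 1, then blend:
  # response is linear in the knot value, so r = r0 + tmpf * (r1 - r0)
  lo[i20] <- 0; hi[i20] <- 1
  r0 <- lin_interp(knots, lo, t_avg)
  r1 <- lin_interp(knots, hi, t_avg)
  r0 + tmpf * (r1 - r0)
}

#' Run an ensemble of simulator instances (internal engine)
#'
#' All state is vectorised across the `M` columns of `par_mat`, so one call
#' can propagate an EnKF ensemble, a Saltelli design or a whole pixel grid.
#' At each date in `update_dates` the optional `update_fn` is called with
#' the current LAI and GWF vectors and may return adjusted ones; leaf
#' cohorts are then rescaled proportionally so that the canopy is consistent
#' with the analysed LAI.
#'
#' @param par_mat M x 9 matrix, columns `SLATB000 ... TMPFTB200, GWF`.
#' @param aux A `crop_parameters` object supplying the auxiliaries.
#' @param weather A `weather_series` data frame covering the season.
#' @param sowing_date Sowing date (`Date`).
#' @param record_dates Dates at which to record forecast LAI (matrix
#'   `length(record_dates)` x M in the result).
#' @param update_dates Dates at which `update_fn` is applied.
#' @param update_fn `function(lai, gwf, k)` returning
#'   `list(lai = ..., gwf = ...)`; `k` is the index of the update date.
#' @param trace Record the daily trajectory (only sensible for small M).
#' @return List with `lai_max`, `twso`, `yield`, `dvs_final`,
#'   `anthesis_day`, `maturity_day`, `lai_record`, `mature` and optionally
#'   `trace`.
#' @keywords internal
sim_engine <- function(par_mat, aux, weather, sowing_date,
                       record_dates = NULL, update_dates = NULL,
                       update_fn = NULL, trace = FALSE) {
  M <- nrow(par_mat)
  dates <- weather$date
  emerge <- as.Date(sowing_date) + aux$emergence_lag
  i0 <- match(emerge, dates)
  if (is.na(i0)) stop("weather series does not cover emergence (",
                      format(emerge), ")")
  n <- length(dates)
  tmax <- weather$tmax; tmin <- weather$tmin; rs <- weather$radiation

  SLA0 <- par_mat[, "SLATB000"]; SLA78 <- par_mat[, "SLATB078"]
  CVO <- par_mat[, "CVO"]; TSUM1 <- par_mat[, "TSUM1"]
  TDWI <- par_mat[, "TDWI"]; SPAN <- par_mat[, "SPAN"]
  TBASE <- par_mat[, "TBASE"]; TMPF <- par_mat[, "TMPFTB200"]
  gwf <- par_mat[, "GWF"]

  pk <- aux$partition_dvs
  pl <- aux$partition_leaf; ps <- aux$partition_storage
  po <- 1 - pl - ps

  # state
  fl0 <- pl[1]
  w_other <- (1 - fl0) * TDWI
  twso <- numeric(M)
  tsum <- numeric(M); dvs <- numeric(M)
  nmax <- n - i0 + 2
  cw <- matrix(0, nmax, M)   # cohort leaf dry weight
  cl <- matrix(0, nmax, M)   # cohort LAI at birth SLA
  ca <- matrix(0, nmax, M)   # cohort physiological age
  cw[1, ] <- fl0 * TDWI
  cl[1, ] <- SLA0 * cw[1, ]
  k <- 1L
  lai <- cl[1, ]
  lai_max <- lai
  anth <- rep(NA_integer_, M); matu <- rep(NA_integer_, M)

  rec <- if (!is.null(record_dates))
    matrix(NA_real_, length(record_dates), M) else NULL
  rd_idx <- if (!is.null(record_dates)) match(as.Date(record_dates), dates)
            else integer(0)
  ud_idx <- if (!is.null(update_dates)) match(as.Date(update_dates), dates)
            else integer(0)
  if (anyNA(rd_idx)) stop("record date outside weather series")
  if (length(ud_idx) && anyNA(ud_idx)) stop("update date outside weather series")
  rec_at <- integer(n); rec_at[rd_idx] <- seq_along(rd_idx)
  upd_at <- integer(n); upd_at[ud_idx] <- seq_along(ud_idx)

  # per-day scalars, hoisted out of the loop
  t_avg_d <- (tmax + tmin) / 2
  dts_d <- pmax(0, t_avg_d - aux$TBASE_PHENO)
  vals0 <- aux$t_resp_values; vals1 <- aux$t_resp_values
  i20 <- which(aux$t_resp_knots == 20)
  vals0[i20] <- 0; vals1[i20] <- 1
  tresp0_d <- lin_interp(aux$t_resp_knots, vals0, t_avg_d)
  tresp1_d <- lin_interp(aux$t_resp_knots, vals1, t_avg_d)
  grow_d <- aux$RUE * 0.5 * rs * 10   # kg ha-1 per unit (gwf*tresp*fint)
  kx <- aux$K_EXT
  slad <- (SLA78 - SLA0) / 0.78
  inv_tsum2 <- 1 / aux$TSUM2
  span35 <- 35 - TBASE

  tr <- if (trace) vector("list", n) else NULL

  for (i in i0:n) {
    active <- dvs < 2
    if (!any(active)) break
    # phenology
    tsum <- tsum + dts_d[i] * active
    pre <- tsum <= TSUM1
    dvs <- pre * (tsum / TSUM1) + (!pre) * (1 + (tsum - TSUM1) * inv_tsum2)
    dvs[dvs > 2] <- 2
    newly_anth <- is.na(anth) & dvs >= 1
    if (any(newly_anth)) anth[newly_anth] <- i
    newly_mat <- is.na(matu) & dvs >= 2
    if (any(newly_mat)) matu[newly_mat] <- i

    # daily growth, kg ha-1 (PAR = 0.5 R_S; RUE in g MJ-1 -> x10)
    fint <- 1 - exp(-kx * lai)
    tresp <- tresp0_d[i] + TMPF * (tresp1_d[i] - tresp0_d[i])
    dw <- gwf * tresp * fint * grow_d[i] * active

    # partitioning (one shared knot lookup)
    j <- findInterval(dvs, pk, all.inside = TRUE)
    wdv <- (dvs - pk[j]) / (pk[j + 1] - pk[j])
    wdv[wdv < 0] <- 0; wdv[wdv > 1] <- 1
    f_leaf <- pl[j] + wdv * (pl[j + 1] - pl[j])
    f_stor <- ps[j] + wdv * (ps[j + 1] - ps[j])
    f_oth <- po[j] + wdv * (po[j + 1] - po[j])
    twso <- twso + CVO * f_stor * dw
    w_other <- w_other + f_oth * dw
    dwl <- f_leaf * dw

    # new leaf cohort at the current SLA
    dvs78 <- dvs; dvs78[dvs78 > 0.78] <- 0.78
    sla <- SLA0 + slad * dvs78
    k <- k + 1L
    cw[k, ] <- dwl
    cl[k, ] <- sla * dwl

    # physiological ageing and senescence
    dage <- t_avg_d[i] - TBASE
    dage[dage < 0] <- 0
    inc <- dage / span35 * active
    idx <- seq_len(k)
    ca[idx, ] <- ca[idx, , drop = FALSE] + rep(inc, each = k)
    alive <- ca[idx, , drop = FALSE] <= rep(SPAN, each = k)
    lai <- .colSums(cl[idx, , drop = FALSE] * alive, k, M)

    # EnKF-style analysis hook
    if (upd_at[i] && !is.null(update_fn)) {
      upd <- update_fn(lai, gwf, upd_at[i])
      ratio <- ifelse(lai > 0, upd$lai / lai, 0)
      cl[idx, ] <- cl[idx, , drop = FALSE] * rep(ratio, each = k)
      cw[idx, ] <- cw[idx, , drop = FALSE] * rep(ratio, each = k)
      lai <- upd$lai
      gwf <- upd$gwf
    }
    if (rec_at[i]) rec[rec_at[i], ] <- lai

    gt <- lai > lai_max
    if (any(gt)) lai_max[gt] <- lai[gt]
    if (trace) {
      w_leaf <- .colSums(cw[idx, , drop = FALSE] * alive, k, M)
      tr[[i]] <- data.frame(date = dates[i], member = seq_len(M),
                            DVS = dvs, LAI = lai, W_leaf = w_leaf,
                            W_other = w_other, TWSO = twso)
    }
  }

  mature <- dvs >= 2
  lai_max <- unname(lai_max); twso <- unname(twso)
  out <- list(lai_max = lai_max, twso = twso,
              yield = twso / (1 - aux$moisture),
              dvs_final = dvs,
              anthesis_day = dates[anth], maturity_day = dates[matu],
              lai_record = rec, mature = mature, gwf_final = gwf)
  if (trace) out$trace <- do.call(rbind, tr[!vapply(tr, is.null, TRUE)])
  out
}

# flatten crop_parameters (+ optional overrides) into the engine's row matrix
par_row <- function(params) {
  stopifnot(inherits(params, "crop_parameters"))
  m <- matrix(unlist(params[PAR_NAMES]), 1,
              dimnames = list(NULL, PAR_NAMES))
  cbind(m, GWF = params$GWF)
}

#' Simulate one season of potential maize growth
#'
#' Daily-step reduced-order potential-production simulation: thermal-time
#' phenology (DVS 0 at emergence, 1 at anthesis, 2 at maturity),
#' light interception by an exponentially extinguishing canopy,
#' radiation-use-efficiency growth with a piecewise-linear temperature
#' response, DVS-dependent partitioning to leaves / stems+roots / storage
#' organs, cohort-based leaf senescence driven by physiological age, and
#' conversion of storage-organ dry weight to fresh yield at standard
#' moisture.
#'
#' @param params A [crop_parameters()] object.
#' @param weather A `weather_series` data frame (see [read_weather()],
#'   [generate_weather()]).
#' @param sowing_date Sowing date (`Date` or ISO string).
#' @return A list of class `simulation_result` with the daily `trajectory`
#'   (date, DVS, LAI, biomass pools, TWSO), `LAIMAX`, `TWSO_maturity`,
#'   `yield` (kg ha-1), `anthesis_day`, `maturity_day` and `mature`.
#' @examples
#' w <- generate_weather(38.9, as.Date("2021-04-20"), 170, seed = 1)
#' s <- simulate_crop(crop_parameters(), w, as.Date("2021-04-25"))
#' s$LAIMAX; s$yield
#' @export
simulate_crop <- function(params, weather, sowing_date) {
  res <- sim_engine(par_row(params), params, weather, as.Date(sowing_date),
                    trace = TRUE)
  if (!res$mature[1])
    warning("weather series ended before maturity; result flagged immature")
  traj <- res$trace[, c("date", "DVS", "LAI", "W_leaf", "W_other", "TWSO")]
  structure(
    list(trajectory = traj,
         LAIMAX = res$lai_max[1], TWSO_maturity = res$twso[1],
         yield = res$yield[1],
         anthesis_day = res$anthesis_day[1],
         maturity_day = res$maturity_day[1],
         mature = res$mature[1]),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Reduced-order maize simulation\n")
  cat(sprintf("  LAIMAX        %.2f m2/m2\n", x$LAIMAX))
  cat(sprintf("  TWSO maturity %.0f kg/ha\n", x$TWSO_maturity))
  cat(sprintf("  yield         %.0f kg/ha\n", x$yield))
  cat(sprintf("  anthesis      %s\n  maturity      %s\n",
              format(x$anthesis_day), format(x$maturity_day)))
  invisible(x)
}
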