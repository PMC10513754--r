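#' Solar geometry for a site and day of year
#'
#' Computes the FAO-56 daily solar geometry quantities used to derive global
#' radiation from sunshine duration: solar declination, inverse relative
#' earth-sun distance, sunset hour angle, extraterrestrial radiation and
#' astronomical daylength.
#'
#' @param latitude Site latitude in radians (use [deg2rad()] for degrees).
#' @param day_of_year Integer day of year, 1-366.
#'
#' @return A list of class `solar_geometry` with elements `latitude`,
#'   `day_of_year`, `solar_declination` (rad), `inverse_rel_distance`,
#'   `sunset_hour_angle` (rad), `extraterrestrial_radiation`
#'   (MJ m-2 d-1) and `daylength` (h).
#'
#' @details The solar constant is taken as 0.0820 MJ m-2 min-1. The argument
#'   of the arccos in the sunset hour angle is clipped to \[-1, 1\] so polar
#'   day/night do not produce NaN: in polar night the sunset hour angle, the
#'   daylength and the extraterrestrial radiation are all zero.
#'
#' @examples
#' g <- solar_geometry(deg2rad(38.9), 172)
#' g$extraterrestrial_radiation
#' @export
solar_geometry <- function(latitude, day_of_year) {
  if (any(abs(latitude) >= pi / 2))
    stop("latitude must lie strictly between -pi/2 and pi/2 radians")
  if (any(day_of_year < 1 | day_of_year > 366 | day_of_year != round(day_of_year)))
    stop("day_of_year must be an integer in 1..366")
  gsc <- 0.0820  # MJ m-2 min-1
  j <- 2 * pi * day_of_year / 365
  dr <- 1 + 0.033 * cos(j)
  delta <- 0.409 * sin(j - 1.39)
  x <- -tan(latitude) * tan(delta)
  ws <- acos(pmin(1, pmax(-1, x)))
  ra <- (24 * 60 / pi) * gsc * dr *
    (ws * sin(latitude) * sin(delta) + cos(latitude) * cos(delta) * sin(ws))
  ra <- pmax(0, ra)
  structure(
    list(latitude = latitude, day_of_year = day_of_year,
         solar_declination = delta, inverse_rel_distance = dr,
         sunset_hour_angle = ws,
         extraterrestrial_radiation = ra,
         daylength = 24 * ws / pi),
    class = "solar_geometry")
}

#' Angstrom coefficients
#'
#' Empirical coefficients of the Angstrom-Prescott relation between relative
#' sunshine duration and the fraction of extraterrestrial radiation reaching
#' the surface. The defaults (0.25, 0.50) are the standard values used when
#' no local calibration exists.
#'
#' @param a_s Intercept (fraction of extraterrestrial radiation on a fully
#'   overcast day). Must be positive.
#' @param b_s Slope; `a_s + b_s` (clear-sky fraction) must not exceed 1.
#' @return A list of class `angstrom_coefficients`.
#' @export
angstrom_coefficients <- function(a_s = 0.25, b_s = 0.5) {
  if (a_s <= 0) stop("a_s must be positive")
  if (a_s + b_s > 1) stop("a_s + b_s must not exceed 1")
  structure(list(a_s = a_s, b_s = b_s), class = "angstrom_coefficients")
}

#' Global radiation from sunshine duration
#'
#' Angstrom-Prescott estimate of daily global (shortwave) radiation:
#' `R_s = (a_s + b_s * n/N) * R_a`, where `n` is observed bright sunshine,
#' `N` the astronomical daylength and `R_a` the extraterrestrial radiation.
#'
#' @param n Bright sunshine duration, hours. Values above the daylength are
#'   clipped to the daylength with a warning; negative values are an error.
#' @param geometry A [solar_geometry()] object.
#' @param coeffs An [angstrom_coefficients()] object.
#' @return Daily global radiation, MJ m-2 d-1 (0 when daylength is 0).
#' @export
radiation_from_sunshine <- function(n, geometry,
                                    coeffs = angstrom_coefficients()) {
  stopifnot(inherits(geometry, "solar_geometry"))
  if (any(n < 0)) stop("sunshine duration n must be non-negative")
  N <- geometry$daylength
  if (any(n > N + 1e-9)) {
    warning("sunshine duration exceeds daylength; clipping to daylength")
    n <- pmin(n, N)
  }
  frac <- ifelse(N > 0, n / N, 0)
  ifelse(N > 0, (coeffs$a_s + coeffs$b_s * frac) *
           geometry$extraterrestrial_radiation, 0)
}

#' Convert degrees to radians
#' @param deg Angle in decimal degrees.
#' @return Angle in radians.
#' @export
deg2rad <- function(deg) deg * pi / 180

#' Read a daily weather series
#'
#' Reads a comma-separated daily weather file with ISO dates and a header
#' row. Required columns: `date`, `tmax`, `tmin`, `sunshine_hours`. Optional
#' columns: `radiation` (MJ m-2 d-1), `precipitation` (mm), `wind_speed`
#' (m/s), `pressure` (hPa). When `radiation` is absent it is derived from
#' sunshine hours via [radiation_from_sunshine()] and the rows are flagged
#' with `radiation_derived = TRUE`.
#'
#' @param path Path to the CSV file.
#' @param latitude Site latitude in decimal degrees (needed only when the
#'   radiation column is absent).
#' @param coeffs [angstrom_coefficients()] used for derivation.
#' @return A `data.frame` of class `weather_series`, one row per day,
#'   consecutive dates.
#' @seealso [generate_weather()] for a synthetic series.
#' @export
read_weather <- function(path, latitude = NULL,
                         coeffs = angstrom_coefficients()) {
  if (!file.exists(path)) stop("weather file not found: ", path)
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("date", "tmax", "tmin", "sunshine_hours")
  miss <- setdiff(req, names(w))
  if (length(miss)) stop("weather file missing columns: ",
                         paste(miss, collapse = ", "))
  w$date <- as.Date(w$date)
  if (anyNA(w$date)) stop("unparseable dates in weather file")
  validate_weather(w, latitude = latitude, coeffs = coeffs)
}

#' Validate (and complete) a daily weather data frame
#'
#' Checks date contiguity, the tmax/tmin ordering and the sunshine-hours
#' range, and derives missing radiation from sunshine duration.
#'
#' @inheritParams read_weather
#' @param w Data frame with at least `date`, `tmax`, `tmin`,
#'   `sunshine_hours`.
#' @return The completed `weather_series` data frame.
#' @export
validate_weather <- function(w, latitude = NULL,
                             coeffs = angstrom_coefficients()) {
  w <- w[order(w$date), , drop = FALSE]
  gaps <- diff(as.integer(w$date))
  if (any(gaps != 1)) {
    at <- w$date[which(gaps != 1)[1]] + 1
    stop("weather series has a gap: missing date ", format(at))
  }
  bad <- which(w$tmax < w$tmin)
  if (length(bad)) stop("tmax < tmin on ", format(w$date[bad[1]]))
  if (any(w$sunshine_hours < 0 | w$sunshine_hours > 24))
    stop("sunshine_hours outside [0, 24]")
  if (is.null(w$radiation) || anyNA(w$radiation)) {
    if (is.null(latitude))
      stop("latitude (decimal degrees) required to derive radiation")
    doy <- as.integer(strftime(w$date, "%j"))
    need <- if (is.null(w$radiation)) rep(TRUE, nrow(w)) else is.na(w$radiation)
    geom <- solar_geometry(deg2rad(latitude), doy)
    rs <- radiation_from_sunshine(pmin(w$sunshine_hours, geom$daylength),
                                  geom, coeffs)
    if (is.null(w$radiation)) w$radiation <- NA_real_
    w$radiation[need] <- rs[need]
    w$radiation_derived <- need
  } else {
    w$radiation_derived <- FALSE
  }
  if (any(w$radiation < 0)) stop("negative radiation in weather series")
  class(w) <- c("weather_series", "data.frame")
  w
}
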