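# Orbital elements and daily-mean insolation.
#
# The orbital solution is a truncated Berger-type trigonometric series whose
# amplitude/rate/phase tables ship as plain-text files under inst/extdata
# (see their provenance headers). Over the Holocene the truncation error is
# far below the precision of any covariate built from it.

.holoreef_cache <- new.env(parent = emptyenv())

.orbital_tables <- function() {
  tab <- get0("orbital_tables", envir = .holoreef_cache)
  if (!is.null(tab)) return(tab)
  rd <- function(f) {
    read.csv(system.file("extdata", f, package = "holoreef", mustWork = TRUE),
             comment.char = "#")
  }
  tab <- list(
    obliquity    = rd("orbital_obliquity_terms.csv"),
    eccentricity = rd("orbital_eccentricity_terms.csv"),
    precession   = rd("orbital_precession_terms.csv"),
    eps0   = 23.320556,   # deg
    psibar = 50.439273,   # arcsec/yr
    zeta   = 3.392506     # deg
  )
  assign("orbital_tables", tab, envir = .holoreef_cache)
  tab
}

SEC2RAD <- pi / (180 * 3600)
DEG2RAD <- pi / 180

# Fixed 365-day calendar used throughout (non-leap month lengths).
MONTH_LENGTHS <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
VERNAL_EQUINOX_DAY <- 80

#' Orbital elements at a Holocene (or deeper) age
#'
#' Evaluates a truncated Berger-type trigonometric series for Earth's orbital
#' eccentricity, axial obliquity, moving-equinox longitude of perihelion, and
#' the climatic precession index \eqn{e \sin(\varpi)}.
#'
#' @param age numeric vector of ages in calibrated years BP (1950 CE;
#'   negative values are years after 1950). Must satisfy `abs(age) <= 1e6`,
#'   the validity window of the bundled series.
#' @return A data frame with columns `age`, `eccentricity` (dimensionless),
#'   `obliquity` (degrees), `perihelion` (radians, moving equinox, in
#'   `[0, 2*pi)`; the true solar longitude of perigee), and
#'   `precession_index` (`eccentricity * sin(perihelion)`).
#' @export
#' @examples
#' orbital_elements(0)$obliquity        # ~23.45 degrees at present
#' orbital_elements(11000)$obliquity    # larger early-Holocene tilt
orbital_elements <- function(age) {
  if (!is.numeric(age) || any(!is.finite(age))) {
    stop_fmt("'age' must be finite numeric (years BP)")
  }
  if (any(abs(age) > 1e6)) {
    stop_fmt("age %g outside the +/-1 Myr validity window of the orbital series",
             age[which.max(abs(age))])
  }
  tab <- .orbital_tables()
  t <- -age  # years relative to 1950 CE, positive forward in time

  ob <- tab$obliquity
  eps <- tab$eps0 + vapply(t, function(ti) {
    sum(ob$amplitude_arcsec / 3600 *
          cos(ob$rate_arcsec_yr * ti * SEC2RAD + ob$phase_deg * DEG2RAD))
  }, numeric(1))

  ec <- tab$eccentricity
  esin <- vapply(t, function(ti) {
    sum(ec$amplitude * sin(ec$rate_arcsec_yr * ti * SEC2RAD + ec$phase_deg * DEG2RAD))
  }, numeric(1))
  ecos <- vapply(t, function(ti) {
    sum(ec$amplitude * cos(ec$rate_arcsec_yr * ti * SEC2RAD + ec$phase_deg * DEG2RAD))
  }, numeric(1))
  e <- sqrt(esin^2 + ecos^2)
  Pi_fixed <- atan2(esin, ecos)

  pr <- tab$precession
  psi <- vapply(t, function(ti) {
    tab$psibar * ti * SEC2RAD + tab$zeta * DEG2RAD +
      sum(pr$amplitude_arcsec * SEC2RAD *
            sin(pr$rate_arcsec_yr * ti * SEC2RAD + pr$phase_deg * DEG2RAD))
  }, numeric(1))
  varpi <- (Pi_fixed + psi + pi) %% (2 * pi)

  data.frame(age = age, eccentricity = e, obliquity = eps,
             perihelion = varpi, precession_index = e * sin(varpi))
}

# Mean solar longitude at the vernal equinox (true longitude zero), solved by
# fixed-point iteration of the equation-of-centre expansion.
.mean_long_at_equinox <- function(e, varpi) {
  lm <- 0
  for (i in 1:8) {
    m <- lm - varpi
    lm <- -((2 * e - e^3 / 4) * sin(m) + 1.25 * e^2 * sin(2 * m) +
              (13 / 12) * e^3 * sin(3 * m))
  }
  lm
}

#' True solar longitude of a calendar day
#'
#' Maps day-of-year in a fixed 365-day calendar to true solar longitude, with
#' the vernal equinox pinned at day 80. The mean longitude advances uniformly
#' and is converted to true longitude with the standard equation-of-centre
#' expansion in the eccentricity.
#'
#' @param day numeric day-of-year (1-365; fractional values allowed).
#' @param elements one row of [orbital_elements()] (or any list with
#'   `eccentricity` and `perihelion`).
#' @return True solar longitude in radians, in `[0, 2*pi)`.
#' @export
day_to_solar_longitude <- function(day, elements) {
  e <- elements$eccentricity
  w <- elements$perihelion
  lm0 <- .mean_long_at_equinox(e, w)
  lm <- lm0 + 2 * pi * (day - VERNAL_EQUINOX_DAY) / 365
  m <- lm - w
  (lm + (2 * e - e^3 / 4) * sin(m) + 1.25 * e^2 * sin(2 * m) +
      (13 / 12) * e^3 * sin(3 * m)) %% (2 * pi)
}

#' Daily-mean top-of-atmosphere insolation
#'
#' Standard geometric daily mean at a latitude for a given true solar
#' longitude: declination follows from obliquity, the sun-hour angle is
#' clamped for polar day and night, and the Earth-Sun distance factor follows
#' Kepler's relation from the eccentricity and longitude of perihelion. No
#' atmospheric attenuation is applied.
#'
#' @param latitude degrees north, in `[-90, 90]`. Vectorised (recycled
#'   against `solar_longitude`).
#' @param solar_longitude true solar longitude in radians (0 = vernal
#'   equinox).
#' @param tsi total solar irradiance in W/m^2 (absolute, > 0).
#' @param elements one row of [orbital_elements()].
#' @return Daily-mean insolation in W/m^2 (exactly 0 in polar night).
#' @export
#' @examples
#' el <- orbital_elements(0)
#' daily_mean_insolation(0, 0, 1365, el)  # equator at equinox, ~tsi/pi
daily_mean_insolation <- function(latitude, solar_longitude, tsi, elements) {
  if (any(latitude < -90 | latitude > 90)) stop_fmt("latitude outside [-90, 90]")
  if (any(tsi <= 0)) stop_fmt("tsi must be positive")
  e <- elements$eccentricity
  w <- elements$perihelion
  eps <- elements$obliquity * DEG2RAD
  phi <- latitude * DEG2RAD
  lam <- solar_longitude

  delta <- asin(sin(eps) * sin(lam))
  nu <- lam - w
  rho2 <- ((1 + e * cos(nu)) / (1 - e^2))^2
  cosH0 <- pmin(1, pmax(-1, -tan(phi) * tan(delta)))
  H0 <- acos(cosH0)
  val <- tsi / pi * rho2 *
    (H0 * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(H0))
  # polar night: H0 == 0 makes both terms vanish, but force exact zeros
  val[H0 == 0] <- 0
  pmax(val, 0)
}

#' Annual-mean insolation at a latitude and age
#'
#' Evaluates the daily mean at the midpoint of each of the 12 months of a
#' fixed 365-day calendar and averages with month-length weights.
#'
#' @param latitude degrees north.
#' @param age age in years BP (scalar or vector).
#' @param tsi total solar irradiance in W/m^2 (absolute); recycled against
#'   `age`.
#' @return Annual-mean insolation in W/m^2, one value per age.
#' @export
#' @examples
#' annual_mean_insolation(15, 6000, 1365.4)
annual_mean_insolation <- function(latitude, age, tsi) {
  stopifnot(length(latitude) == 1L)
  tsi <- rep_len(tsi, length(age))
  el <- orbital_elements(age)
  mid <- cumsum(c(0, MONTH_LENGTHS[-12])) + MONTH_LENGTHS / 2
  wts <- MONTH_LENGTHS / 365
  vapply(seq_along(age), function(i) {
    lam <- day_to_solar_longitude(mid, el[i, ])
    sum(wts * daily_mean_insolation(latitude, lam, tsi[i], el[i, ]))
  }, numeric(1))
}
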