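#' Solar geometry for a day of year and latitude
#'
#' Computes the astronomical quantities needed to estimate daily solar
#' radiation: the inverse-square Sun-Earth distance factor `dr`, the solar
#' declination, the sunset hour angle, extraterrestrial radiation `ra`
#' (MJ m^-2 d^-1) and the potential day length (hours).
#'
#' The formulas are the standard FAO-56-style set with day-angle constant
#' 0.0172 and declination amplitude 0.4209:
#' \deqn{D_r = 1 + 0.033\cos(0.0172\,\mathrm{DOY})}
#' \deqn{\delta = 0.4209\sin(0.0172\,\mathrm{DOY} - 1.39)}
#' \deqn{\omega_s = \arccos(-\tan\varphi\tan\delta)}
#' \deqn{R_a = 37.6\,D_r(\omega_s\sin\varphi\sin\delta +
#'   \cos\varphi\cos\delta\sin\omega_s)}
#' \deqn{N = \frac{24}{\pi}\omega_s}
#'
#' The arccos argument is clamped to \[-1, 1\] so that polar-latitude inputs
#' degrade gracefully to 0- or 24-hour day length instead of producing NaN.
#'
#' @param doy Integer day(s) of year in \[1, 366\].
#' @param latitude_deg Latitude in decimal degrees, strictly inside
#'   (-90, 90). Latitudes beyond the polar circles are accepted but clamped.
#' @return A tibble with one row per input day: `doy`, `dr`,
#'   `declination_rad`, `omega_s_rad`, `ra`, `daylength_hours`.
#' @export
#' @examples
#' solar_geometry(172, 27.7)
solar_geometry <- function(doy, latitude_deg) {
  if (!is.numeric(doy) || any(!is.finite(doy)) ||
      any(doy < 1) || any(doy > 366)) {
    abort("`doy` must be numeric in [1, 366].", class = "sistr_invalid_input")
  }
  if (!is.numeric(latitude_deg) || length(latitude_deg) != 1L ||
      !is.finite(latitude_deg) || abs(latitude_deg) >= 90) {
    abort("`latitude_deg` must be a single number in (-90, 90).",
          class = "sistr_invalid_input")
  }
  phi <- latitude_deg * pi / 180
  dr <- 1 + 0.033 * cos(0.0172 * doy)
  delta <- 0.4209 * sin(0.0172 * doy - 1.39)
  # clamp: only bites poleward of ~66.5 degrees
  arg <- pmin(1, pmax(-1, -tan(phi) * tan(delta)))
  omega_s <- acos(arg)
  ra <- 37.6 * dr *
    (omega_s * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(omega_s))
  ra <- pmax(ra, 0)
  tibble(
    doy = as.integer(doy),
    dr = dr,
    declination_rad = delta,
    omega_s_rad = omega_s,
    ra = ra,
    daylength_hours = 24 / pi * omega_s
  )
}

#' Angstrom-Prescott coefficients
#'
#' Empirical coefficients relating relative sunshine duration to the fraction
#' of extraterrestrial radiation reaching the surface. The defaults
#' (a_s = 0.18, b_s = 0.55) are the standard temperate-zone values.
#'
#' @param a_s Intercept: fraction of `ra` on a fully overcast day.
#' @param b_s Slope on relative sunshine `n/N`.
#' @return A named list with class `angstrom_coefficients`.
#' @export
angstrom_coefficients <- function(a_s = 0.18, b_s = 0.55) {
  if (!is.numeric(a_s) || !is.numeric(b_s) || a_s <= 0 || b_s <= 0 ||
      a_s + b_s > 1) {
    abort("Angstrom coefficients must be positive with a_s + b_s <= 1.",
          class = "sistr_invalid_input")
  }
  structure(list(a_s = a_s, b_s = b_s), class = "angstrom_coefficients")
}

#' Convert daily sunshine hours to solar radiation
#'
#' Applies the Angstrom-Prescott relation
#' \deqn{R_s = (a_s + b_s\, n/N)\, R_a}
#' to a daily meteorology table, where `n` is observed sunshine hours and `N`
#' the potential day length from [solar_geometry()].
#'
#' @param meteo A data frame with columns `doy`, `tmax`, `tmin`,
#'   `sunshine_hours` (one row per day).
#' @param latitude_deg Site latitude, decimal degrees.
#' @param coeffs An [angstrom_coefficients()] object.
#' @return The input as a tibble with columns `ra`, `daylength_hours` and
#'   `rs` (MJ m^-2 d^-1) appended.
#' @export
#' @examples
#' m <- tibble::tibble(doy = 160:165, tmax = 30, tmin = 22, sunshine_hours = 6)
#' sunshine_to_radiation(m, latitude_deg = 27.7)
sunshine_to_radiation <- function(meteo, latitude_deg,
                                  coeffs = angstrom_coefficients()) {
  meteo <- validate_meteo(meteo)
  if (!inherits(coeffs, "angstrom_coefficients")) {
    coeffs <- do.call(angstrom_coefficients, as.list(coeffs))
  }
  geom <- solar_geometry(meteo$doy, latitude_deg)
  if (any(geom$daylength_hours <= 0)) {
    abort("Zero day length (polar night): cannot form n/N.",
          class = "sistr_division_guard")
  }
  out <- as_tibble(meteo)
  out$ra <- geom$ra
  out$daylength_hours <- geom$daylength_hours
  out$rs <- (coeffs$a_s + coeffs$b_s * out$sunshine_hours /
               out$daylength_hours) * out$ra
  out
}

# internal: check a daily meteorology table
validate_meteo <- function(meteo) {
  need <- c("doy", "tmax", "tmin", "sunshine_hours")
  if (!is.data.frame(meteo) || !all(need %in% names(meteo))) {
    abort(paste0("`meteo` must be a data frame with columns ",
                 paste(need, collapse = ", "), "."),
          class = "sistr_invalid_input")
  }
  bad <- !is.finite(meteo$doy) | meteo$doy < 1 | meteo$doy > 366 |
    meteo$tmax < meteo$tmin |
    meteo$sunshine_hours < 0 | meteo$sunshine_hours > 24
  if (any(bad)) {
    abort(paste0("Invalid meteorology rows (doy range, tmax >= tmin, ",
                 "0 <= sunshine_hours <= 24): rows ",
                 paste(which(bad), collapse = ", ")),
          class = "sistr_invalid_input")
  }
  meteo
}

# internal: require complete daily forcing over the season
require_season_meteo <- function(meteo) {
  meteo <- validate_meteo(meteo)
  missing_doys <- setdiff(season_doys(), meteo$doy)
  if (length(missing_doys) > 0) {
    abort(paste0("Meteorology must cover every DOY in 160-255; missing: ",
                 paste(head(missing_doys, 10), collapse = ", "),
                 if (length(missing_doys) > 10) ", ..." else ""),
          class = "sistr_missing_forcing")
  }
  meteo[match(season_doys(), meteo$doy), , drop = FALSE]
}

#' Read a daily meteorology CSV
#'
#' Expects a header row and columns `doy,tmax,tmin,sunshine_hours`, one file
#' per year. Missing days inside the file's DOY span raise an error listing
#' the gaps.
#'
#' @param path Path to the CSV file.
#' @return A tibble with the four columns, ordered by `doy`.
#' @export
read_meteo_csv <- function(path) {
  df <- as_tibble(read.csv(path))
  df <- validate_meteo(df)
  df <- arrange(df, .data$doy)
  gaps <- setdiff(seq(min(df$doy), max(df$doy)), df$doy)
  if (length(gaps) > 0) {
    abort(paste0("Meteorology file has missing days: ",
                 paste(head(gaps, 20), collapse = ", "),
                 if (length(gaps) > 20) ", ..." else ""),
          class = "sistr_missing_forcing")
  }
  df
}

#' Generate a synthetic season of daily meteorology
#'
#' Produces plausible subtropical-paddy forcing for DOY 160-255: sinusoidal
#' temperatures peaking in late July plus day-to-day noise, and beta-like
#' sunshine-hour variability. Used by the synthetic-scene generator and in
#' examples; real applications read station records with [read_meteo_csv()].
#'
#' @param year Calendar year label carried through to outputs.
#' @param seed Integer seed; every draw is reproducible.
#' @param tmean_peak Seasonal peak of daily mean temperature, degrees C.
#' @param noise_sd Day-to-day temperature noise, degrees C.
#' @return A tibble with columns `year`, `doy`, `tmax`, `tmin`,
#'   `sunshine_hours`.
#' @export
synth_meteo <- function(year, seed, tmean_peak = 29, noise_sd = 1.5) {
  doys <- season_doys()
  withr_seed(seed, {
    tmean <- tmean_peak - 4 * cos(2 * pi * (doys - 205) / 365) +
      rnorm(length(doys), 0, noise_sd)
    trange <- 8 + rnorm(length(doys), 0, 1)
    trange <- pmax(trange, 2)
    sunshine <- pmin(pmax(7 + 3 * sin(2 * pi * doys / 40) +
                            rnorm(length(doys), 0, 2), 0), 12)
  })
  tibble(
    year = as.integer(year),
    doy = doys,
    tmax = tmean + trange / 2,
    tmin = tmean - trange / 2,
    sunshine_hours = sunshine
  )
}

# internal: evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
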