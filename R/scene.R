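# A "scene" in sistr is a long tibble of rice-pixel LAI samples with columns
#   row, col  — 1-based grid coordinates
#   year      — observation year
#   doy       — one of the 20 canonical DOYs
#   lai       — leaf area index, >= 0
# Non-rice pixels are simply absent (nodata); the rice mask is the set of
# (row, col) keys present. All raster-scale operators take and return
# tibbles keyed on (row, col).

# internal: check a scene tibble and return it with canonical ordering
validate_scene <- function(scene, years = NULL) {
  need <- c("row", "col", "year", "doy", "lai")
  if (!is.data.frame(scene) || !all(need %in% names(scene))) {
    abort(paste0("A scene needs columns ", paste(need, collapse = ", "), "."),
          class = "sistr_invalid_input")
  }
  if (!all(scene$doy %in% canonical_doys())) {
    abort("Scene DOYs must lie on the canonical 5-day grid (160-255).",
          class = "sistr_invalid_input")
  }
  if (!is.null(years) && !all(years %in% scene$year)) {
    abort("Scene does not contain the requested years.",
          class = "sistr_invalid_input")
  }
  arrange(as_tibble(scene), .data$year, .data$row, .data$col, .data$doy)
}

# internal: one year of a scene as an npix x 20 matrix plus its pixel key
scene_year_matrix <- function(scene, yr) {
  sub <- filter(scene, .data$year == yr)
  wide <- tidyr::pivot_wider(sub, id_cols = c("row", "col"),
                             names_from = "doy", values_from = "lai",
                             names_sort = TRUE)
  doy_cols <- as.character(canonical_doys())
  if (!all(doy_cols %in% names(wide)) ||
      anyNA(wide[doy_cols])) {
    abort(paste0("Year ", yr, ": every rice pixel needs all 20 canonical ",
                 "DOY samples."),
          class = "sistr_invalid_input")
  }
  list(pixels = select(wide, "row", "col"),
       lai = as.matrix(wide[doy_cols]))
}

#' Min-max normalisation over defined values
#'
#' Linearly maps values to \[0, 1\]: \eqn{(x - x_{min})/(x_{max} - x_{min})}.
#' `NA` values (nodata) are passed through and never contaminate the
#' extrema. When all defined values are equal the range is degenerate and
#' every value maps to `degenerate` (0 by default: no evidence of
#' differential signal).
#'
#' @param x Numeric vector; `NA` = nodata.
#' @param degenerate Value assigned when `max(x) == min(x)`.
#' @return A list with `values` (same length as `x`), `vmin`, `vmax`.
#' @export
#' @examples
#' normalize_minmax(c(2, 4, 6))$values  # 0, 0.5, 1
normalize_minmax <- function(x, degenerate = 0) {
  ok <- !is.na(x)
  if (!any(ok)) {
    abort("Need at least one defined value to normalise.",
          class = "sistr_invalid_input")
  }
  vmin <- min(x[ok])
  vmax <- max(x[ok])
  out <- rep(NA_real_, length(x))
  if (vmax > vmin) {
    out[ok] <- (x[ok] - vmin) / (vmax - vmin)
  } else {
    out[ok] <- degenerate
  }
  list(values = out, vmin = vmin, vmax = vmax)
}

#' Per-pixel stress level against a no-stress reference series
#'
#' The stress level of rice pixel i in a year is the DTW distance between
#' its LAI series and the year's unstressed reference series:
#' \eqn{S_i = dtw(LAI_{sample}, LAI_i)}. A larger distance from the healthy
#' reference means the pixel is under higher stress.
#'
#' @param scene A scene tibble (see package docs): columns `row`, `col`,
#'   `year`, `doy`, `lai`.
#' @param references A named list mapping year (as character) to a reference
#'   series tibble (`doy`, `lai`), e.g. from [reference_series()].
#' @param band_radius,local_distance DTW settings, see [dtw_distance()].
#' @return A tibble `row`, `col`, `year`, `s` with one row per rice pixel
#'   and year.
#' @export
stress_level <- function(scene, references, band_radius = 3,
                         local_distance = "absolute") {
  scene <- validate_scene(scene)
  years <- sort(unique(scene$year))
  purrr::map_dfr(years, function(yr) {
    ref <- references[[as.character(yr)]]
    if (is.null(ref)) {
      abort(paste0("No reference series supplied for year ", yr, "."),
            class = "sistr_invalid_input")
    }
    if (!identical(as.integer(ref$doy), canonical_doys())) {
      abort("Reference series must be on the canonical DOY grid.",
            class = "sistr_invalid_input")
    }
    ym <- scene_year_matrix(scene, yr)
    refmat <- matrix(ref$lai, nrow(ym$lai), length(ref$lai), byrow = TRUE)
    s <- dtw_distance_many(refmat, ym$lai, band_radius, local_distance)
    mutate(ym$pixels, year = yr, s = s)
  })
}

#' Unstressed reference LAI series for a year
#'
#' Simulates the season with the stress factor forced to 1 (healthy crop);
#' one reference per year, shared by all pixels of the scene.
#'
#' @inheritParams simulate_lai
#' @return A tibble `doy`, `lai` on the canonical grid.
#' @export
reference_series <- function(meteo, latitude_deg, params = crop_params()) {
  simulate_lai(meteo, latitude_deg, params, f = 1)
}

#' Average normalised stress levels across two years
#'
#' The final stress level of a pixel is the arithmetic mean of its per-year
#' normalised stress levels.
#'
#' @param s_norm A tibble `row`, `col`, `year`, `s_norm` covering exactly
#'   the years to combine (normally two).
#' @return A tibble `row`, `col`, `s_final`; pixels must be present in
#'   every year.
#' @export
combined_stress <- function(s_norm) {
  need <- c("row", "col", "year", "s_norm")
  if (!is.data.frame(s_norm) || !all(need %in% names(s_norm))) {
    abort("`s_norm` needs columns row, col, year, s_norm.",
          class = "sistr_invalid_input")
  }
  nyears <- length(unique(s_norm$year))
  out <- s_norm %>%
    group_by(.data$row, .data$col) %>%
    summarise(s_final = mean(.data$s_norm), n_years = n(), .groups = "drop")
  if (any(out$n_years != nyears)) {
    abort("Pixels must be co-registered: every pixel present in every year.",
          class = "sistr_invalid_input")
  }
  select(out, "row", "col", "s_final")
}

#' Inter-annual temporal dissimilarity
#'
#' For each rice pixel, the DTW distance between its LAI series in two
#' consecutive years: \eqn{TD_i = dtw(LAI_{i,y_1}, LAI_{i,y_2})}. Pixels
#' whose seasonal signal repeats (chronic stress, or health) get low TD;
#' pixels hit by a one-season stressor get high TD.
#'
#' @param scene A scene tibble holding exactly two years for each pixel.
#' @param years Length-2 vector selecting the year pair (default: the two
#'   years present).
#' @inheritParams stress_level
#' @return A tibble `row`, `col`, `td`.
#' @export
temporal_dissimilarity <- function(scene, years = NULL, band_radius = 3,
                                   local_distance = "absolute") {
  scene <- validate_scene(scene)
  if (is.null(years)) years <- sort(unique(scene$year))
  if (length(years) != 2) {
    abort("Temporal dissimilarity needs exactly two years.",
          class = "sistr_invalid_input")
  }
  y1 <- scene_year_matrix(scene, years[1])
  y2 <- scene_year_matrix(scene, years[2])
  if (!identical(y1$pixels, y2$pixels)) {
    abort("Rice masks differ between the two years.",
          class = "sistr_invalid_input")
  }
  td <- dtw_distance_many(y1$lai, y2$lai, band_radius, local_distance)
  mutate(y1$pixels, td = td)
}

#' Temporal stability from temporal dissimilarity
#'
#' The min-max complement of TD over the rice pixels of the scene:
#' \eqn{TS_i = 1 - (TD_i - TD_{min})/(TD_{max} - TD_{min})}, in \[0, 1\].
#' The pixel with the smallest TD gets TS = 1 (most stable). A degenerate
#' range (all TD equal) maps every pixel to TS = 1: maximal stability.
#'
#' @param td A tibble `row`, `col`, `td` from [temporal_dissimilarity()].
#' @return The input with a `ts` column appended; attributes are reported in
#'   the `extrema` element of the returned list.
#' @export
temporal_stability <- function(td) {
  if (!is.data.frame(td) || !all(c("row", "col", "td") %in% names(td))) {
    abort("`td` needs columns row, col, td.", class = "sistr_invalid_input")
  }
  nm <- normalize_minmax(td$td, degenerate = 0)
  out <- mutate(as_tibble(td), ts = 1 - nm$values)
  list(surfaces = out, td_min = nm$vmin, td_max = nm$vmax)
}
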