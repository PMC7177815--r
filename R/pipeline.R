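#' Run the full heavy-metal stress-discrimination pipeline
#'
#' Executes the whole chain on a two-year scene: per-year unstressed
#' reference simulation, per-pixel DTW stress level and its per-year min-max
#' normalisation, the two-year mean stress level, inter-annual temporal
#' dissimilarity and temporal stability, local Moran's I of temporal
#' stability on the rice mask, its normalisation, and the composite SIST
#' index. Deterministic given its inputs.
#'
#' @param scene A scene tibble (`row`, `col`, `year`, `doy`, `lai`), e.g.
#'   `generate_scene(...)$scene` or [read_scene_csv()].
#' @param meteo A named list (year -> daily meteorology tibble) or a single
#'   tibble with a `year` column covering both years.
#' @param latitude_deg Site latitude.
#' @param params [crop_params()] for the reference simulation.
#' @param band_radius,local_distance DTW settings ([dtw_distance()]).
#' @param scheme Spatial-weight scheme for [local_morans_i()].
#' @param references Optional named list (year -> reference series) to use
#'   instead of simulating from `meteo`.
#' @return An object of class `sist_result`: list with
#'   * `surfaces` — tibble `row`, `col`, `s_final`, `td`, `ts`, `i_raw`,
#'     `i_norm`, `n_neighbors`, `cluster`, `sist`,
#'   * `stress_by_year` — tibble `row`, `col`, `year`, `s`, `s_norm`,
#'   * `references`, `extrema`, `settings`.
#'   Isolated rice pixels (no rice neighbour) carry `NA` Moran's I and
#'   therefore `NA` SIST.
#' @export
#' @examples
#' sc <- generate_scene(scenario_config(rows = 40, cols = 40,
#'                                       heavy_block_size = 8,
#'                                       nutrition_block_size = 6, seed = 3))
#' res <- run_pipeline(sc$scene, meteo = sc$meteo, references = sc$references)
#' glance(res)
run_pipeline <- function(scene, meteo = NULL, latitude_deg = 27.7,
                         params = crop_params(), band_radius = 3,
                         local_distance = "absolute",
                         scheme = c("row", "binary"), references = NULL) {
  scheme <- match.arg(scheme)
  scene <- validate_scene(scene)
  years <- sort(unique(scene$year))
  if (length(years) != 2) {
    abort("The pipeline needs a scene with exactly two years.",
          class = "sistr_invalid_input")
  }

  if (is.null(references)) {
    if (is.null(meteo)) {
      abort("Supply either `meteo` or precomputed `references`.",
            class = "sistr_invalid_input")
    }
    if (is.data.frame(meteo)) {
      meteo <- split(meteo, meteo$year)
    }
    references <- lapply(as.character(years), function(y) {
      m <- meteo[[y]]
      if (is.null(m)) {
        abort(paste0("run_pipeline [meteo]: no forcing for year ", y, "."),
              class = "sistr_missing_forcing")
      }
      reference_series(m, latitude_deg, params)
    })
    names(references) <- as.character(years)
  }

  # stress level per year, normalised per year, then averaged
  s <- stress_level(scene, references, band_radius, local_distance)
  extrema <- list()
  s_norm <- purrr::map_dfr(years, function(yr) {
    sub <- filter(s, .data$year == yr)
    nm <- normalize_minmax(sub$s, degenerate = 0)
    extrema[[paste0("s_", yr)]] <<- c(min = nm$vmin, max = nm$vmax)
    mutate(sub, s_norm = nm$values)
  })
  s_final <- combined_stress(s_norm)

  # temporal stability
  td <- temporal_dissimilarity(scene, years, band_radius, local_distance)
  tsres <- temporal_stability(td)
  extrema$td <- c(min = tsres$td_min, max = tsres$td_max)

  # spatial autocorrelation of temporal stability
  moran_in <- select(tsres$surfaces, "row", "col", value = "ts")
  moran <- local_morans_i(moran_in, scheme)
  nm_i <- normalize_minmax(moran$i_raw, degenerate = 0)
  extrema$i <- c(min = nm_i$vmin, max = nm_i$vmax)
  moran$i_norm <- nm_i$values

  surfaces <- s_final %>%
    inner_join(tsres$surfaces, by = c("row", "col")) %>%
    inner_join(select(moran, "row", "col", "n_neighbors", "i_raw",
                      "i_norm", "cluster"),
               by = c("row", "col")) %>%
    compute_sist()

  structure(
    list(surfaces = surfaces, stress_by_year = s_norm,
         references = references, extrema = extrema,
         settings = list(band_radius = band_radius,
                         local_distance = local_distance, scheme = scheme,
                         latitude_deg = latitude_deg, years = years)),
    class = "sist_result"
  )
}

#' @export
print.sist_result <- function(x, ...) {
  cat(sprintf("SIST pipeline result: %d rice pixels, years %s\n",
              nrow(x$surfaces),
              paste(x$settings$years, collapse = "/")))
  cat(sprintf("  mean SIST %.3f (defined on %d pixels)\n",
              mean(x$surfaces$sist, na.rm = TRUE),
              sum(!is.na(x$surfaces$sist))))
  invisible(x)
}

#' @describeIn run_pipeline Long tibble of the result surfaces: one row per
#'   pixel and surface (`s_final`, `td`, `ts`, `i_raw`, `i_norm`, `sist`).
#' @param x A `sist_result`.
#' @param ... Unused.
#' @export
tidy.sist_result <- function(x, ...) {
  x$surfaces %>%
    select("row", "col", "s_final", "td", "ts", "i_raw", "i_norm", "sist") %>%
    tidyr::pivot_longer(-c("row", "col"), names_to = "surface",
                        values_to = "value")
}

#' @describeIn run_pipeline One-row summary: pixel counts, mean surfaces,
#'   extrema used in normalisation.
#' @export
glance.sist_result <- function(x, ...) {
  s <- x$surfaces
  tibble(
    n_rice = nrow(s),
    n_defined = sum(!is.na(s$sist)),
    mean_s_final = mean(s$s_final, na.rm = TRUE),
    mean_ts = mean(s$ts, na.rm = TRUE),
    mean_sist = mean(s$sist, na.rm = TRUE),
    td_min = x$extrema$td["min"],
    td_max = x$extrema$td["max"]
  )
}

#' Plot the result surfaces of a pipeline run
#'
#' Facetted raster maps of the final stress level, temporal stability,
#' normalised local Moran's I and SIST.
#'
#' @param object A `sist_result`.
#' @param surfaces Which surfaces to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sist_result <- function(object,
                                 surfaces = c("s_final", "ts", "i_norm",
                                              "sist"),
                                 ...) {
  df <- tidy(object) %>% filter(.data$surface %in% surfaces)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~surface) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL)
}

#' Plot LAI series
#'
#' Seasonal LAI trajectories, optionally coloured by a grouping column.
#'
#' @param series A tibble with `doy`, `lai` and optionally a `group`
#'   column (e.g. year or stress class).
#' @param group Optional column name to colour by.
#' @return A ggplot object.
#' @export
plot_lai_series <- function(series, group = NULL) {
  p <- ggplot2::ggplot(series, ggplot2::aes(.data$doy, .data$lai))
  if (!is.null(group)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(
      colour = factor(.data[[group]]), group = factor(.data[[group]])))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "Day of year", y = "LAI", colour = group)
}

#' Summarise pipeline discrimination against known truth
#'
#' For synthetic scenes with known per-pixel classes: mean SIST and
#' temporal stability per class, the ranking AUC of SIST for heavy-metal
#' vs all other rice pixels, and the Pearson correlation between SIST and
#' the latent contamination level.
#'
#' @param result A `sist_result`.
#' @param truth Truth tibble (`row`, `col`, `class`, `contamination`) from
#'   [generate_scene()].
#' @return A list with `by_class` (tibble: class, n, mean_sist, mean_ts,
#'   mean_s_final), `auc`, `r_contamination`.
#' @export
evaluate_discrimination <- function(result, truth) {
  joined <- inner_join(result$surfaces, truth, by = c("row", "col"))
  by_class <- joined %>%
    group_by(.data$class) %>%
    summarise(n = n(),
              mean_sist = mean(.data$sist, na.rm = TRUE),
              mean_ts = mean(.data$ts, na.rm = TRUE),
              mean_s_final = mean(.data$s_final, na.rm = TRUE),
              .groups = "drop")
  ok <- !is.na(joined$sist)
  list(
    by_class = by_class,
    auc = ranking_auc(joined$sist[ok], joined$class[ok] == "heavy_metal"),
    r_contamination = pearson_r(joined$sist[ok], joined$contamination[ok])
  )
}
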