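# Synthetic two-year LAI scenes with known per-pixel truth.
#
# The generator realises the conceptual temporal typology that the pipeline
# is built to exploit:
#   heavy_metal — season-long depression of the stress factor, identical in
#                 both years (chronic source in the soil), spatially
#                 clustered in blocks, with a latent contamination level;
#   abrupt      — pest/disease-like: f depressed only inside a short window
#                 of ONE season, scattered pixels;
#   nutrition   — season-long depression with severity drawn independently
#                 each year (management varies between seasons), in blocks;
#   healthy     — f = 1.
# Everything else (weather, phenology shift, observation noise) is shared
# within a year.

#' Configuration of a synthetic two-year scene
#'
#' Defaults define the package's reference study conditions: a 100 x 100
#' grid, 90% rice, three 12 x 12 heavy-metal blocks with per-pixel latent
#' contamination ~ U(0.3, 0.8), two 14 x 14 nutrition zones in which 35% of
#' fields are hit with per-year severity ~ U(0.2, 0.6), 8% of the remaining
#' rice hit by a 20-day abrupt
#' stress (f = 0.4 inside the window) in one random year, additive Gaussian
#' LAI noise with sd 0.15 (floored at 0), and no phenology shift.
#'
#' @param rows,cols Grid size.
#' @param rice_fraction Fraction of pixels that are rice (non-rice pixels
#'   are scattered and carry no data).
#' @param n_heavy_blocks,heavy_block_size Count and side length of
#'   heavy-metal blocks.
#' @param heavy_level_range Range of the per-pixel latent contamination
#'   level; the stress factor is `f = 1 - 0.6 * level` in both years.
#' @param n_nutrition_blocks,nutrition_block_size Count and side of
#'   nutrition-stress zones.
#' @param nutrition_density Fraction of each zone's rice pixels actually
#'   under nutrition stress. Nutrition problems operate at field
#'   granularity — individual fields inside an affected zone are hit
#'   independently, unlike the contiguous footprint of a contaminated soil
#'   body — so the default leaves most zone pixels healthy.
#' @param nutrition_severity_range Per-year severity range; `f = 1 -
#'   severity`, drawn independently each year and each pixel.
#' @param abrupt_fraction Fraction of background rice pixels under abrupt
#'   stress.
#' @param abrupt_window_days Length of the abrupt-stress window, days.
#' @param abrupt_f Stress factor inside the window.
#' @param phenology_shift Integer 5-day steps per year, length 2
#'   (positive = later season).
#' @param year_effect_sd Standard deviation of the multiplicative per-pixel,
#'   per-year amplitude effect (natural inter-annual variation: variety,
#'   planting density, field management). The effect is damped by the
#'   pixel's mean seasonal stress factor: a chronically poisoned field has
#'   little capacity to respond to the drivers of ordinary year-to-year
#'   variation, which is what makes chronic stress inter-annually stable
#'   relative to healthy fields.
#' @param noise_sd Gaussian observation noise on sampled LAI.
#' @param years Length-2 vector of year labels.
#' @param latitude_deg Site latitude for the radiation model.
#' @param seed Integer seed (mandatory): all layout, severity, weather and
#'   noise draws flow from it.
#' @return A named list of class `scenario_config`.
#' @export
scenario_config <- function(rows = 100, cols = 100, rice_fraction = 0.9,
                            n_heavy_blocks = 3, heavy_block_size = 12,
                            heavy_level_range = c(0.3, 0.8),
                            n_nutrition_blocks = 2, nutrition_block_size = 14,
                            nutrition_density = 0.35,
                            nutrition_severity_range = c(0.2, 0.6),
                            abrupt_fraction = 0.08, abrupt_window_days = 20,
                            abrupt_f = 0.4, phenology_shift = c(0L, 0L),
                            year_effect_sd = 0.08,
                            noise_sd = 0.15, years = c(2017L, 2018L),
                            latitude_deg = 27.7, seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory for scene generation.",
          class = "sistr_invalid_input")
  }
  cfg <- list(rows = as.integer(rows), cols = as.integer(cols),
              rice_fraction = rice_fraction,
              n_heavy_blocks = n_heavy_blocks,
              heavy_block_size = as.integer(heavy_block_size),
              heavy_level_range = heavy_level_range,
              n_nutrition_blocks = n_nutrition_blocks,
              nutrition_block_size = as.integer(nutrition_block_size),
              nutrition_density = nutrition_density,
              nutrition_severity_range = nutrition_severity_range,
              abrupt_fraction = abrupt_fraction,
              abrupt_window_days = abrupt_window_days, abrupt_f = abrupt_f,
              phenology_shift = as.integer(phenology_shift),
              year_effect_sd = year_effect_sd,
              noise_sd = noise_sd, years = as.integer(years),
              latitude_deg = latitude_deg, seed = as.integer(seed))
  if (cfg$rice_fraction < 0 || cfg$rice_fraction > 1 ||
      cfg$abrupt_fraction < 0 || cfg$abrupt_fraction > 1 ||
      cfg$noise_sd < 0 || length(cfg$years) != 2 ||
      length(cfg$phenology_shift) != 2) {
    abort("Invalid scenario configuration.", class = "sistr_invalid_input")
  }
  structure(cfg, class = "scenario_config")
}

#' Season-long stress-factor profile for one pixel and year
#'
#' Returns the daily multiplier curve applied to the stress factor over DOY
#' 160-255 for a given stress regime:
#' * `healthy`: f = 1 all season.
#' * `heavy_metal`: f = 1 - 0.6 * `level` all season — pass the same
#'   `level` for both years to obtain the regime's inter-annual stability.
#' * `abrupt`: f = 1 except `abrupt_f` inside `[window_start, window_start
#'   + abrupt_window_days]`, and only when `year == stress_year`.
#' * `nutrition`: f = 1 - 0.6 * `severity` all season (the same stress gain
#'   as heavy metal, so the two chronic types overlap in seasonal signal
#'   magnitude and differ by inter-annual behaviour); `severity` is drawn from
#'   `nutrition_severity_range` (using the current RNG state) when not
#'   supplied, so successive years vary independently.
#'
#' @param kind One of `"healthy"`, `"heavy_metal"`, `"abrupt"`,
#'   `"nutrition"`.
#' @param year Year being simulated.
#' @param config A [scenario_config()].
#' @param level Latent contamination level in \[0, 1\] (heavy metal).
#' @param window_start First DOY of the abrupt window.
#' @param stress_year Year in which the abrupt stress occurs.
#' @param severity Nutrition severity; drawn if `NULL`.
#' @return Numeric vector of daily f values, one per DOY 160-255.
#' @export
stress_profile <- function(kind, year, config, level = NULL,
                           window_start = NULL, stress_year = NULL,
                           severity = NULL) {
  doys <- season_doys()
  switch(
    kind,
    healthy = rep(1, length(doys)),
    heavy_metal = {
      if (is.null(level)) {
        abort("heavy_metal profile needs a contamination `level`.",
              class = "sistr_invalid_input")
      }
      rep(1 - 0.6 * level, length(doys))
    },
    abrupt = {
      if (is.null(window_start) || is.null(stress_year)) {
        abort("abrupt profile needs `window_start` and `stress_year`.",
              class = "sistr_invalid_input")
      }
      f <- rep(1, length(doys))
      if (year == stress_year) {
        inside <- doys >= window_start &
          doys <= window_start + config$abrupt_window_days
        f[inside] <- config$abrupt_f
      }
      f
    },
    nutrition = {
      if (is.null(severity)) {
        severity <- runif(1, config$nutrition_severity_range[1],
                          config$nutrition_severity_range[2])
      }
      # same stress gain as heavy metal: chronic stress types share the
      # in-season signal magnitude and differ by inter-annual stability
      rep(1 - 0.6 * severity, length(doys))
    },
    abort(paste0("Unknown stress kind: ", kind),
          class = "sistr_invalid_input")
  )
}

# internal: place k non-overlapping size x size blocks on the grid,
# returning a list of (row0, col0); draws from the current RNG state
place_blocks <- function(rows, cols, k, size, taken) {
  if (k == 0) return(list(blocks = list(), taken = taken))
  if (size > rows || size > cols) {
    abort("Stress blocks do not fit on this grid.",
          class = "sistr_invalid_input")
  }
  blocks <- list()
  block_cells <- function(r0, c0) {
    as.vector(outer(r0:(r0 + size - 1), (c0:(c0 + size - 1) - 1) * rows,
                    "+"))
  }
  anchors <- expand.grid(r0 = seq_len(rows - size + 1),
                         c0 = seq_len(cols - size + 1))
  for (b in seq_len(k)) {
    free <- vapply(seq_len(nrow(anchors)), function(a) {
      !any(taken[block_cells(anchors$r0[a], anchors$c0[a])])
    }, logical(1))
    if (!any(free)) {
      abort("Could not place the requested stress blocks on this grid.",
            class = "sistr_invalid_input")
    }
    pick <- sample(which(free), 1)
    cells <- block_cells(anchors$r0[pick], anchors$c0[pick])
    taken[cells] <- TRUE
    blocks[[b]] <- c(anchors$r0[pick], anchors$c0[pick])
  }
  list(blocks = blocks, taken = taken)
}

#' Generate a synthetic two-year LAI scene with known truth
#'
#' Lays out the stress regimes on the grid, simulates every rice pixel's
#' daily LAI under its regime's stress-factor profile with year-specific
#' synthetic weather, samples the canonical 20-date series (optionally
#' phenology-shifted per year), adds Gaussian observation noise floored at
#' 0, and returns the scene together with its per-pixel truth. Bit
#' reproducible for a fixed config seed.
#'
#' @param config A [scenario_config()].
#' @return A list of class `sist_scene_set`:
#'   * `scene` — tibble `row`, `col`, `year`, `doy`, `lai` (rice pixels only),
#'   * `truth` — tibble `row`, `col`, `class`, `contamination` (latent level;
#'     0 outside heavy-metal blocks),
#'   * `meteo` — the two years' daily weather,
#'   * `references` — per-year unstressed reference series,
#'   * `config` — the configuration used.
#' @export
#' @examples
#' sc <- generate_scene(scenario_config(rows = 40, cols = 40,
#'                                       heavy_block_size = 8,
#'                                       nutrition_block_size = 6, seed = 7))
#' dplyr::count(sc$truth, class)
generate_scene <- function(config) {
  if (!inherits(config, "scenario_config")) {
    config <- do.call(scenario_config, config)
  }
  rows <- config$rows
  cols <- config$cols
  npix_all <- rows * cols

  withr_seed(config$seed, {
    rice <- runif(npix_all) < config$rice_fraction

    # stress layout: blocks first (they may straddle non-rice pixels, which
    # simply stay nodata), then scattered abrupt pixels
    taken <- rep(FALSE, npix_all)
    hb <- place_blocks(rows, cols, config$n_heavy_blocks,
                       config$heavy_block_size, taken)
    nb <- place_blocks(rows, cols, config$n_nutrition_blocks,
                       config$nutrition_block_size, hb$taken)
    class_vec <- rep("healthy", npix_all)
    class_vec[!rice] <- NA_character_
    for (b in hb$blocks) {
      cells <- as.vector(outer(b[1]:(b[1] + config$heavy_block_size - 1),
                               (b[2]:(b[2] + config$heavy_block_size - 1) - 1)
                               * rows, "+"))
      class_vec[cells][rice[cells]] <- "heavy_metal"
    }
    for (b in nb$blocks) {
      cells <- as.vector(outer(b[1]:(b[1] + config$nutrition_block_size - 1),
                               (b[2]:(b[2] + config$nutrition_block_size - 1)
                                - 1) * rows, "+"))
      cand <- cells[rice[cells]]
      hit <- cand[runif(length(cand)) < config$nutrition_density]
      class_vec[hit] <- "nutrition"
    }
    bg <- which(rice & class_vec == "healthy")
    n_abrupt <- round(config$abrupt_fraction * length(bg))
    abrupt_px <- sample(bg, n_abrupt)
    class_vec[abrupt_px] <- "abrupt"

    # latent attributes
    contamination <- rep(0, npix_all)
    hm <- which(!is.na(class_vec) & class_vec == "heavy_metal")
    contamination[hm] <- runif(length(hm), config$heavy_level_range[1],
                               config$heavy_level_range[2])
    win_start <- rep(NA_real_, npix_all)
    win_start[abrupt_px] <- 165 + runif(n_abrupt) *
      (250 - config$abrupt_window_days - 165)
    abrupt_year <- rep(NA_integer_, npix_all)
    abrupt_year[abrupt_px] <- sample(config$years, n_abrupt, replace = TRUE)
    nut <- which(!is.na(class_vec) & class_vec == "nutrition")
    nut_sev <- matrix(runif(2 * length(nut),
                            config$nutrition_severity_range[1],
                            config$nutrition_severity_range[2]),
                      ncol = 2)

    meteo <- lapply(seq_along(config$years), function(k) {
      synth_meteo(config$years[k], seed = config$seed + 1000L * k)
    })
    names(meteo) <- as.character(config$years)

    ridx <- which(rice)
    npix <- length(ridx)
    nday <- length(season_doys())
    doys <- season_doys()
    params <- crop_params()
    scene <- vector("list", 2)
    refs <- vector("list", 2)
    for (k in 1:2) {
      yr <- config$years[k]
      met <- sunshine_to_radiation(meteo[[k]], config$latitude_deg)
      refs[[k]] <- reference_series(met, config$latitude_deg, params)

      fmat <- matrix(1, npix, nday)
      for (p in seq_len(npix)) {
        g <- ridx[p]
        fmat[p, ] <- switch(
          class_vec[g],
          healthy = 1,
          heavy_metal = stress_profile("heavy_metal", yr, config,
                                       level = contamination[g]),
          abrupt = stress_profile("abrupt", yr, config,
                                  window_start = win_start[g],
                                  stress_year = abrupt_year[g]),
          nutrition = stress_profile("nutrition", yr, config,
                                     severity =
                                       nut_sev[match(g, nut), k])
        )
      }
      daily <- simulate_lai_daily_many(met$rs, (met$tmax + met$tmin) / 2,
                                       params, fmat)
      sample_doys <- canonical_doys() - 5L * config$phenology_shift[k]
      idx <- pmin(pmax(sample_doys - 160L + 1L, 1L), nday)
      sampled <- daily[, idx, drop = FALSE]
      if (config$year_effect_sd > 0) {
        # natural inter-annual amplitude variation, damped by chronic stress
        amp <- 1 + rnorm(npix, 0, config$year_effect_sd) * rowMeans(fmat)
        sampled <- sampled * pmax(amp, 0)
      }
      if (config$noise_sd > 0) {
        sampled <- sampled + matrix(rnorm(length(sampled), 0,
                                          config$noise_sd),
                                    nrow(sampled))
      }
      sampled <- pmax(sampled, 0)
      scene[[k]] <- tibble(
        row = rep((ridx - 1L) %% rows + 1L, times = 20),
        col = rep((ridx - 1L) %/% rows + 1L, times = 20),
        year = yr,
        doy = rep(canonical_doys(), each = npix),
        lai = as.vector(sampled)
      )
    }
  })

  truth <- tibble(
    row = (ridx - 1L) %% rows + 1L,
    col = (ridx - 1L) %/% rows + 1L,
    class = class_vec[ridx],
    contamination = contamination[ridx]
  )
  names(refs) <- as.character(config$years)
  structure(
    list(scene = bind_rows(scene), truth = truth, meteo = bind_rows(meteo),
         references = refs, config = config),
    class = "sist_scene_set"
  )
}

#' @export
print.sist_scene_set <- function(x, ...) {
  cat(sprintf("Synthetic two-year scene: %d x %d grid, %d rice pixels\n",
              x$config$rows, x$config$cols, nrow(x$truth)))
  print(dplyr::count(x$truth, .data$class))
  invisible(x)
}
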