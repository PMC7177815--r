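#' Convert NDVI to LAI
#'
#' Empirical exponential relation calibrated for paddy rice:
#' \deqn{LAI = 0.361\,e^{3.69\,NDVI}}
#' The relation is assumed constant across seasons.
#'
#' @param ndvi Numeric NDVI values, typically in \[-1, 1\].
#' @return LAI values, strictly positive and increasing in NDVI.
#' @export
#' @examples
#' ndvi_to_lai(c(0, 0.5, 0.8))
ndvi_to_lai <- function(ndvi) {
  if (!is.numeric(ndvi) || any(!is.finite(ndvi))) {
    abort("`ndvi` must be finite numeric.", class = "sistr_invalid_input")
  }
  0.361 * exp(3.69 * ndvi)
}

#' Parameters of the reduced daily rice LAI model
#'
#' The simulator is a deliberately small stand-in for a full crop-physiology
#' model: daily gross assimilation is radiation-use efficiency times
#' Beer's-law intercepted radiation, a stress factor `f` in \[0, 1\] scales
#' that assimilation, a fixed conversion turns assimilate into LAI increment,
#' and leaf senescence at a constant relative rate switches on once
#' accumulated thermal time passes a threshold. Defaults are tuned so the
#' unstressed curve rises from transplanting LAI ~0.3 to a peak near 6 in
#' mid-season and then declines, the canonical healthy paddy profile.
#'
#' @param lai_init LAI at DOY 160 (start of the simulated season).
#' @param rue Radiation-use efficiency: assimilate per MJ intercepted.
#' @param k_ext Canopy light-extinction coefficient, in (0, 1.5].
#' @param leaf_conversion LAI increment per unit assimilate.
#' @param t_base Base temperature for thermal time, degrees C.
#' @param tt_senescence Thermal time (degree-days above `t_base`) at which
#'   senescence starts.
#' @param senescence_rate Relative LAI loss per day after onset.
#' @return A named list of class `crop_params`.
#' @export
crop_params <- function(lai_init = 0.3, rue = 3, k_ext = 0.6,
                        leaf_conversion = 0.003, t_base = 8,
                        tt_senescence = 1000, senescence_rate = 0.025) {
  p <- list(lai_init = lai_init, rue = rue, k_ext = k_ext,
            leaf_conversion = leaf_conversion, t_base = t_base,
            tt_senescence = tt_senescence, senescence_rate = senescence_rate)
  if (any(!vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x) && x > 0, logical(1)))) {
    abort("All crop parameters must be single positive numbers.",
          class = "sistr_invalid_input")
  }
  if (p$k_ext > 1.5) {
    abort("`k_ext` must lie in (0, 1.5].", class = "sistr_invalid_input")
  }
  structure(p, class = "crop_params")
}

#' Simulate a seasonal rice LAI series under stress
#'
#' Runs the reduced daily LAI model over DOY 160-255 and samples the result
#' on the canonical 5-day grid. The daily update is
#' \deqn{CVF_t = RUE\; R_{s,t}\,(1 - e^{-k\,LAI_t}), \quad CVF^f_t = f\,CVF_t}
#' \deqn{LAI_{t+1} = \max(0,\; LAI_t + c\,CVF^f_t - s_t\,LAI_t)}
#' where the stress factor `f` (0 = fully stressed, 1 = healthy) multiplies
#' gross assimilation, and the senescence rate \eqn{s_t} switches from 0 to
#' `senescence_rate` once thermal time exceeds `tt_senescence`. Deterministic
#' given its inputs.
#'
#' @param meteo Daily meteorology covering every DOY in 160-255, with columns
#'   `doy`, `tmax`, `tmin`, `sunshine_hours` (see [synth_meteo()]); a
#'   precomputed `rs` column is used if present, otherwise radiation is
#'   derived via [sunshine_to_radiation()].
#' @param latitude_deg Site latitude, decimal degrees.
#' @param params A [crop_params()] object.
#' @param f Stress factor: a single value in \[0, 1\], or a daily vector
#'   (one value per DOY 160-255) for time-varying stress.
#' @param phenology_shift Integer shift, in 5-day steps, applied to the
#'   sampled series (positive = later phenology); the daily trajectory is
#'   sampled at `doy - 5 * shift`, clamped to the season.
#' @return A tibble with 20 rows: `doy`, `lai`.
#' @export
#' @examples
#' m <- synth_meteo(2017, seed = 1)
#' healthy <- simulate_lai(m, 27.7, f = 1)
#' stressed <- simulate_lai(m, 27.7, f = 0.5)
#' max(healthy$lai) > max(stressed$lai)
simulate_lai <- function(meteo, latitude_deg, params = crop_params(), f = 1,
                         phenology_shift = 0L) {
  meteo <- require_season_meteo(meteo)
  if (!inherits(params, "crop_params")) params <- do.call(crop_params, params)
  nday <- length(season_doys())
  if (!is.numeric(f) || !length(f) %in% c(1L, nday) ||
      any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
    abort("`f` must be in [0, 1], length 1 or one value per season day.",
          class = "sistr_invalid_input")
  }
  f <- rep_len(f, nday)
  if (!"rs" %in% names(meteo)) {
    meteo <- sunshine_to_radiation(meteo, latitude_deg)
  }
  daily <- simulate_lai_daily(meteo$rs, (meteo$tmax + meteo$tmin) / 2,
                              params, f)
  sample_doys <- canonical_doys() - 5L * as.integer(phenology_shift)
  idx <- pmin(pmax(sample_doys - 160L + 1L, 1L), nday)
  tibble(doy = canonical_doys(), lai = daily[idx])
}

# internal: daily loop shared by the scalar and the vectorised simulators.
# rs, tmean: length-96 vectors; f: length-96; returns daily LAI (length 96).
simulate_lai_daily <- function(rs, tmean, params, f) {
  nday <- length(rs)
  lai <- numeric(nday)
  lai[1] <- params$lai_init
  tt <- 0
  for (t in seq_len(nday - 1)) {
    tt <- tt + max(0, tmean[t] - params$t_base)
    cvf <- params$rue * rs[t] * (1 - exp(-params$k_ext * lai[t]))
    # past the senescence threshold assimilate no longer builds leaf
    # (partitioning shifts to grain) and leaves die at a constant rate
    post <- tt > params$tt_senescence
    grow <- if (post) 0 else params$leaf_conversion * f[t] * cvf
    sen <- if (post) params$senescence_rate else 0
    lai[t + 1] <- max(0, lai[t] + grow - sen * lai[t])
  }
  lai
}

# internal: simulate many pixels at once. f_mat is npix x nday; returns
# npix x nday daily LAI. Same recurrence as simulate_lai_daily, vectorised
# over pixels (weather is shared).
simulate_lai_daily_many <- function(rs, tmean, params, f_mat) {
  npix <- nrow(f_mat)
  nday <- length(rs)
  lai <- matrix(0, npix, nday)
  lai[, 1] <- params$lai_init
  tt <- 0
  for (t in seq_len(nday - 1)) {
    tt <- tt + max(0, tmean[t] - params$t_base)
    post <- tt > params$tt_senescence
    if (post) {
      lai[, t + 1] <- pmax(0, lai[, t] - params$senescence_rate * lai[, t])
    } else {
      cvf <- params$rue * rs[t] * (1 - exp(-params$k_ext * lai[, t]))
      lai[, t + 1] <- pmax(0, lai[, t] +
                             params$leaf_conversion * f_mat[, t] * cvf)
    }
  }
  lai
}

#' Mean-squared-error cost between observed and simulated LAI
#'
#' \deqn{C = \frac{1}{N}\sum_{i=1}^N (LAI_{m,i} - LAI_{s,i})^2}
#' Observations are matched to the nearest simulated DOY; a match farther
#' than `max_doy_gap` days is an error (satellite acquisition dates rarely
#' coincide with the 5-day simulation grid).
#'
#' @param observed A data frame with columns `doy` and `lai` (N >= 1 rows).
#' @param simulated A simulated series: tibble with `doy`, `lai`.
#' @param max_doy_gap Maximum tolerated |observed DOY - matched DOY|, days.
#' @return The mean squared difference (a single non-negative number).
#' @export
#' @examples
#' sim <- tibble::tibble(doy = canonical_doys(), lai = 1)
#' obs <- tibble::tibble(doy = c(161, 200), lai = c(1.5, 1))
#' lai_cost(obs, sim)  # mean of (0.5^2, 0)
lai_cost <- function(observed, simulated, max_doy_gap = 2) {
  if (!is.data.frame(observed) || nrow(observed) == 0 ||
      !all(c("doy", "lai") %in% names(observed))) {
    abort("`observed` must be a non-empty data frame with doy and lai.",
          class = "sistr_invalid_input")
  }
  idx <- vapply(observed$doy,
                function(d) which.min(abs(simulated$doy - d)), integer(1))
  gap <- abs(simulated$doy[idx] - observed$doy)
  if (any(gap > max_doy_gap)) {
    abort(paste0("Observation DOYs ",
                 paste(observed$doy[gap > max_doy_gap], collapse = ", "),
                 " are farther than ", max_doy_gap,
                 " days from any simulated DOY."),
          class = "sistr_invalid_input")
  }
  mean((observed$lai - simulated$lai[idx])^2)
}

#' Particle swarm optimisation settings
#'
#' Global-best PSO over the one-dimensional stress factor, bounded to
#' \[0, 1\]. Defaults: 20 particles, 100 iterations, inertia 0.72 and
#' cognitive/social coefficients 1.49 (standard constriction-like values).
#'
#' @param n_particles Swarm size.
#' @param max_iterations Iteration cap (0 allowed: returns the best initial
#'   particle).
#' @param cost_threshold Early-stop threshold on the best cost.
#' @param inertia,cognitive,social PSO velocity coefficients.
#' @param seed Integer seed; mandatory for reproducibility.
#' @return A named list of class `pso_config`.
#' @export
pso_config <- function(n_particles = 20, max_iterations = 100,
                       cost_threshold = 1e-8, inertia = 0.72,
                       cognitive = 1.49, social = 1.49, seed = 1L) {
  if (n_particles < 1 || max_iterations < 0 || is.null(seed)) {
    abort("PSO needs n_particles >= 1, max_iterations >= 0 and a seed.",
          class = "sistr_invalid_input")
  }
  structure(list(n_particles = as.integer(n_particles),
                 max_iterations = as.integer(max_iterations),
                 cost_threshold = cost_threshold, inertia = inertia,
                 cognitive = cognitive, social = social,
                 seed = as.integer(seed)),
            class = "pso_config")
}

#' Calibrate the stress factor against sparse LAI observations
#'
#' Finds the season-constant stress factor `f` in \[0, 1\] whose simulated
#' LAI series best matches the observations in the mean-squared-error sense
#' ([lai_cost()]), using global-best particle swarm optimisation. Particles
#' are clamped to the \[0, 1\] search box. With a fixed seed the result is
#' bit-reproducible. Non-convergence is not an error: the best-so-far
#' position is returned and flagged in the trace.
#'
#' @param observed Data frame with columns `doy`, `lai` (the observations; an
#'   `ndvi` column is converted via [ndvi_to_lai()] if `lai` is absent).
#' @param meteo,latitude_deg,params Forcing and parameters passed to
#'   [simulate_lai()].
#' @param pso A [pso_config()].
#' @return An object of class `sist_calibration` with elements `f_hat`,
#'   `cost_hat`, `converged`, `iterations` and `trace` (a tibble of the best
#'   cost per iteration). [tidy()] and [glance()] methods are provided.
#' @export
#' @examples
#' m <- synth_meteo(2017, seed = 1)
#' truth <- simulate_lai(m, 27.7, f = 0.6)
#' fit <- calibrate_stress_factor(truth, m, 27.7, pso = pso_config(seed = 42))
#' glance(fit)
calibrate_stress_factor <- function(observed, meteo, latitude_deg,
                                    params = crop_params(),
                                    pso = pso_config()) {
  if (!inherits(pso, "pso_config")) pso <- do.call(pso_config, pso)
  if (is.data.frame(observed) && !"lai" %in% names(observed) &&
      "ndvi" %in% names(observed)) {
    observed$lai <- ndvi_to_lai(observed$ndvi)
  }
  meteo <- require_season_meteo(meteo)
  if (!"rs" %in% names(meteo)) {
    meteo <- sunshine_to_radiation(meteo, latitude_deg)
  }
  cost_of <- function(f) {
    lai_cost(observed, simulate_lai(meteo, latitude_deg, params, f))
  }

  n <- pso$n_particles
  withr_seed(pso$seed, {
    x <- runif(n, 0, 1)
    v <- runif(n, -0.5, 0.5)
    cost <- vapply(x, cost_of, numeric(1))
    pbest_x <- x
    pbest_c <- cost
    g <- which.min(cost)
    gbest_x <- x[g]
    gbest_c <- cost[g]
    trace <- numeric(0)
    iter_done <- 0L
    if (pso$max_iterations > 0) {
      for (iter in seq_len(pso$max_iterations)) {
        r1 <- runif(n)
        r2 <- runif(n)
        v <- pso$inertia * v + pso$cognitive * r1 * (pbest_x - x) +
          pso$social * r2 * (gbest_x - x)
        x <- pmin(1, pmax(0, x + v))
        cost <- vapply(x, cost_of, numeric(1))
        upd <- cost < pbest_c
        pbest_x[upd] <- x[upd]
        pbest_c[upd] <- cost[upd]
        g <- which.min(pbest_c)
        if (pbest_c[g] < gbest_c) {
          gbest_c <- pbest_c[g]
          gbest_x <- pbest_x[g]
        }
        trace <- c(trace, gbest_c)
        iter_done <- iter
        if (gbest_c <= pso$cost_threshold) break
      }
    }
  })
  structure(
    list(f_hat = gbest_x, cost_hat = gbest_c,
         converged = gbest_c <= pso$cost_threshold,
         iterations = iter_done,
         trace = tibble(iteration = seq_along(trace), best_cost = trace),
         config = pso),
    class = "sist_calibration"
  )
}

#' @export
print.sist_calibration <- function(x, ...) {
  cat("Stress-factor calibration (PSO)\n")
  cat(sprintf("  f_hat = %.4f   cost = %.6g   iterations = %d%s\n",
              x$f_hat, x$cost_hat, x$iterations,
              if (x$converged) "   (converged)" else ""))
  invisible(x)
}

#' @export
tidy.sist_calibration <- function(x, ...) {
  tibble(term = "f", estimate = x$f_hat, cost = x$cost_hat)
}

#' @export
glance.sist_calibration <- function(x, ...) {
  tibble(f_hat = x$f_hat, cost = x$cost_hat, iterations = x$iterations,
         converged = x$converged)
}
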