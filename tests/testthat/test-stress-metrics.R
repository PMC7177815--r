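ref_series <- function(values) {
  tibble::tibble(doy = canonical_doys(), lai = values)
}

test_that("min-max normalisation matches hand evaluation", {
  expect_equal(normalize_minmax(c(2, 4, 6))$values, c(0, 0.5, 1))
  expect_equal(normalize_minmax(c(-1, 0, 3))$values, c(0, 0.25, 1))
  one <- normalize_minmax(5)
  expect_equal(one$values, 0)
  nm <- normalize_minmax(c(NA, 1, 3, NA))
  expect_equal(nm$values, c(NA, 0, 1, NA))
  expect_equal(nm$vmin, 1)
  expect_equal(nm$vmax, 3)
  expect_error(normalize_minmax(c(NA_real_, NA_real_)),
               class = "sistr_invalid_input")
})

test_that("stress level is the DTW distance to the healthy reference", {
  base <- 6 * exp(-(canonical_doys() - 215)^2 / 800)
  ref <- ref_series(base)
  series <- list(
    list(row = 1, col = 1, lai = list(base)),          # healthy
    list(row = 1, col = 2, lai = list(0.8 * base)),    # mild stress
    list(row = 2, col = 1, lai = list(0.5 * base)),    # strong stress
    list(row = 2, col = 2, lai = list(base + 0.1))
  )
  scene <- scene_from_series(series, years = 2017)
  s <- stress_level(scene, list(`2017` = ref))
  s11 <- s$s[s$row == 1 & s$col == 1]
  s12 <- s$s[s$row == 1 & s$col == 2]
  s21 <- s$s[s$row == 2 & s$col == 1]
  expect_equal(s11, 0)
  expect_gt(s21, s12)  # deeper depression, larger stress level

  # raster operator agrees with per-pixel scalar calls
  for (k in seq_along(series)) {
    d <- dtw_distance(ref$lai, series[[k]]$lai[[1]])$distance
    expect_equal(s$s[s$row == series[[k]]$row & s$col == series[[k]]$col],
                 d, tolerance = 1e-12)
  }
})

test_that("combined stress averages the per-year normalised levels", {
  s_norm <- tibble::tibble(row = c(1, 1, 2, 2), col = c(1, 2, 1, 2),
                           year = c(2017, 2017, 2017, 2017),
                           s_norm = c(0, 1, 0.2, 0.5)) %>%
    dplyr::bind_rows(tibble::tibble(row = c(1, 1, 2, 2), col = c(1, 2, 1, 2),
                                    year = 2018,
                                    s_norm = c(0, 1, 0.8, 0.9)))
  out <- combined_stress(s_norm)
  expect_equal(out$s_final[out$row == 1 & out$col == 1], 0)
  expect_equal(out$s_final[out$row == 1 & out$col == 2], 1)
  expect_equal(out$s_final[out$row == 2 & out$col == 1], 0.5)
  expect_equal(out$s_final[out$row == 2 & out$col == 2], 0.7)

  # random rasters: elementwise mean oracle
  set.seed(9)
  sn <- tidyr::expand_grid(row = 1:4, col = 1:4, year = c(2017, 2018)) %>%
    dplyr::mutate(s_norm = runif(dplyr::n()))
  out2 <- combined_stress(sn)
  oracle <- stats::aggregate(s_norm ~ row + col, data = sn, FUN = mean)
  joined <- merge(out2, oracle)
  expect_equal(joined$s_final, joined$s_norm, tolerance = 1e-12)

  expect_error(combined_stress(s_norm[-1, ]), class = "sistr_invalid_input")
})

test_that("temporal dissimilarity separates abrupt from chronic stress", {
  base <- 6 * exp(-(canonical_doys() - 215)^2 / 800)
  dip <- base
  dip[8:12] <- dip[8:12] * 0.4  # one-season window collapse
  chronic <- 0.6 * base
  series <- list(
    list(row = 1, col = 1, lai = list(base, base)),        # healthy
    list(row = 1, col = 2, lai = list(dip, base)),         # abrupt in y1
    list(row = 2, col = 1, lai = list(chronic, chronic)),  # heavy metal
    list(row = 2, col = 2, lai = list(base, 0.9 * base))
  )
  scene <- scene_from_series(series, years = c(2017, 2018))
  td <- temporal_dissimilarity(scene)
  td_at <- function(r, c) td$td[td$row == r & td$col == c]
  expect_equal(td_at(1, 1), 0)
  expect_equal(td_at(2, 1), 0)  # identical both years: chronic signature
  expect_gt(td_at(1, 2), td_at(2, 1))

  # a one-step phenological shift costs less than aligned distance
  shifted <- c(base[1], base[-20])
  sc2 <- scene_from_series(list(list(row = 1, col = 1,
                                     lai = list(base, shifted))),
                           years = c(2017, 2018))
  td2 <- temporal_dissimilarity(sc2)
  expect_lt(td2$td, sum(abs(base - shifted)))
})

test_that("temporal stability is the min-max complement of TD", {
  td <- tibble::tibble(row = 1:3, col = 1, td = c(0, 5, 10))
  ts <- temporal_stability(td)
  expect_equal(ts$surfaces$ts, c(1, 0.5, 0))
  expect_equal(ts$td_min, 0)
  expect_equal(ts$td_max, 10)

  flat <- temporal_stability(tibble::tibble(row = 1:3, col = 1, td = 4))
  expect_equal(flat$surfaces$ts, c(1, 1, 1))  # degenerate: maximal stability

  set.seed(2)
  rnd <- tibble::tibble(row = 1:10, col = 1, td = runif(10, 0, 30))
  expect_equal(temporal_stability(rnd)$surfaces$ts,
               1 - normalize_minmax(rnd$td)$values)
})

test_that("reference series equals an unstressed simulation", {
  m <- constant_meteo(rs = 15)
  expect_identical(reference_series(m, 27.7), simulate_lai(m, 27.7, f = 1))
  # lower radiation, pointwise no-greater canopy
  low <- reference_series(constant_meteo(rs = 10), 27.7)
  high <- reference_series(constant_meteo(rs = 18), 27.7)
  expect_true(all(low$lai <= high$lai + 1e-12))
})

test_that("mismatched scenes are rejected", {
  base <- rep(1, 20)
  sc <- scene_from_series(list(list(row = 1, col = 1,
                                    lai = list(base, base))),
                          years = c(2017, 2018))
  expect_error(temporal_dissimilarity(sc, years = c(2017, 2018, 2019)),
               class = "sistr_invalid_input")
  expect_error(stress_level(sc, list()), class = "sistr_invalid_input")
  bad <- sc
  bad$doy[1] <- 161
  expect_error(stress_level(bad, NULL), class = "sistr_invalid_input")
})
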