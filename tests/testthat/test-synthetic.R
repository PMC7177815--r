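small_config <- function(seed, ...) {
  scenario_config(rows = 24, cols = 24, heavy_block_size = 6,
                  nutrition_block_size = 6, seed = seed, ...)
}

test_that("stress profiles encode the temporal typology", {
  cfg <- small_config(1)
  # chronic contamination: identical depression in both years
  f17 <- stress_profile("heavy_metal", 2017, cfg, level = 0.5)
  f18 <- stress_profile("heavy_metal", 2018, cfg, level = 0.5)
  expect_identical(f17, f18)
  expect_true(all(f17 == 1 - 0.6 * 0.5))

  # abrupt stress exists in one season only
  a17 <- stress_profile("abrupt", 2017, cfg, window_start = 190,
                        stress_year = 2017)
  a18 <- stress_profile("abrupt", 2018, cfg, window_start = 190,
                        stress_year = 2017)
  expect_true(all(a18 == 1))
  inside <- sistr:::season_doys() >= 190 &
    sistr:::season_doys() <= 190 + cfg$abrupt_window_days
  expect_true(all(a17[inside] == cfg$abrupt_f))
  expect_true(all(a17[!inside] == 1))

  expect_error(stress_profile("hail", 2017, cfg),
               class = "sistr_invalid_input")
})

test_that("nutrition varies between years while heavy metal does not", {
  cfg <- small_config(1)
  diffs_nut <- vapply(1:100, function(s) {
    set.seed(s)
    y1 <- stress_profile("nutrition", 2017, cfg)[1]
    y2 <- stress_profile("nutrition", 2018, cfg)[1]
    y1 - y2
  }, numeric(1))
  diffs_hm <- vapply(1:100, function(s) {
    set.seed(s)
    lv <- runif(1, 0.3, 0.8)
    stress_profile("heavy_metal", 2017, cfg, level = lv)[1] -
      stress_profile("heavy_metal", 2018, cfg, level = lv)[1]
  }, numeric(1))
  expect_gt(sd(diffs_nut), 0)
  expect_equal(sd(diffs_hm), 0)
})

test_that("scene generation is bit-reproducible for a fixed seed", {
  a <- generate_scene(small_config(33))
  b <- generate_scene(small_config(33))
  expect_identical(a$scene, b$scene)
  expect_identical(a$truth, b$truth)
  c <- generate_scene(small_config(34))
  expect_false(identical(a$scene, c$scene))
})

test_that("an all-healthy noiseless scene reproduces the reference", {
  cfg <- scenario_config(rows = 10, cols = 10, rice_fraction = 1,
                         n_heavy_blocks = 0, n_nutrition_blocks = 0,
                         abrupt_fraction = 0, noise_sd = 0,
                         year_effect_sd = 0, seed = 2)
  sc <- generate_scene(cfg)
  expect_true(all(sc$truth$class == "healthy"))
  for (yr in cfg$years) {
    ref <- sc$references[[as.character(yr)]]
    px <- dplyr::filter(sc$scene, year == yr, row == 4, col == 7)
    expect_equal(px$lai, ref$lai, tolerance = 1e-12)
  }
  # downstream: zero stress everywhere
  s <- stress_level(sc$scene, sc$references)
  expect_true(all(s$s == 0))
})

test_that("scene layout and latent attributes respect the configuration", {
  cfg <- small_config(7)
  sc <- generate_scene(cfg)
  counts <- table(sc$truth$class)
  expect_true(all(c("healthy", "heavy_metal", "abrupt", "nutrition") %in%
                    names(counts)))
  hm <- dplyr::filter(sc$truth, class == "heavy_metal")
  expect_true(all(hm$contamination >= cfg$heavy_level_range[1] &
                    hm$contamination <= cfg$heavy_level_range[2]))
  expect_true(all(sc$truth$contamination[sc$truth$class != "heavy_metal"]
                  == 0))
  expect_true(all(sc$scene$lai >= 0))
  # ~90% rice of the full grid
  expect_gt(nrow(sc$truth), 0.8 * 24 * 24)
  expect_lt(nrow(sc$truth), 0.97 * 24 * 24)
})

test_that("heavy-metal pixels are depressed but inter-annually stable", {
  cfg <- small_config(11, noise_sd = 0, year_effect_sd = 0)
  sc <- generate_scene(cfg)
  td <- temporal_dissimilarity(sc$scene)
  joined <- dplyr::inner_join(td, sc$truth, by = c("row", "col"))
  agg <- dplyr::summarise(dplyr::group_by(joined, class),
                          td = mean(td), .groups = "drop")
  td_of <- function(cl) agg$td[agg$class == cl]
  expect_lt(td_of("heavy_metal"), td_of("abrupt"))
  expect_lt(td_of("heavy_metal"), td_of("nutrition"))
})
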