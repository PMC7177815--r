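test_that("band mask implements the slope-adjusted diagonal constraint", {
  b0 <- dtw_band(5, 5, 0)
  expect_identical(b0, diag(5) == 1)

  expect_true(all(dtw_band(20, 20, 20)))

  # unequal lengths: direct inequality evaluation per cell
  b <- dtw_band(4, 2, 0.5)
  manual <- matrix(NA, 4, 2)
  for (i in 1:4) for (j in 1:2) manual[i, j] <- abs(j - (2 / 4) * i) <= 0.5
  expect_identical(b, manual)
  expect_error(dtw_band(0, 3, 1), class = "sistr_invalid_input")
})

test_that("small DTW distances match exhaustive path enumeration", {
  d1 <- dtw_distance(c(1, 2, 3), c(1, 3), band_radius = Inf)
  expect_equal(d1$distance, 1)
  expect_equal(d1$distance, dtw_enum_oracle(c(1, 2, 3), c(1, 3)))

  d2 <- dtw_distance(c(0, 0), c(1, 1), band_radius = Inf)
  expect_equal(d2$distance, 2)
  expect_equal(d2$distance, dtw_enum_oracle(c(0, 0), c(1, 1)))
})

test_that("identical series give zero distance and a diagonal path", {
  a <- c(0.3, 1.2, 4, 6.1, 5, 2)
  d <- dtw_distance(a, a, band_radius = 2, return_path = TRUE)
  expect_equal(d$distance, 0)
  expect_identical(d$path, cbind(1:6, 1:6))
})

test_that("a timing shift costs DTW far less than aligned distance", {
  a <- c(0, 1, 0, 0)
  b <- c(0, 0, 1, 0)
  d <- dtw_distance(a, b, band_radius = Inf)
  expect_lt(d$distance, sum(abs(a - b)))
  expect_equal(d$distance, 0)
})

test_that("the warping path is valid and achieves the distance", {
  set.seed(11)
  for (k in 1:20) {
    m <- sample(3:10, 1)
    n <- sample(3:10, 1)
    a <- runif(m, 0, 6)
    b <- runif(n, 0, 6)
    r <- sample(c(2, 3, Inf), 1)
    res <- try(dtw_distance(a, b, band_radius = r, return_path = TRUE),
               silent = TRUE)
    if (inherits(res, "try-error")) next  # infeasible band draw
    p <- res$path
    expect_equal(unname(p[1, ]), c(1, 1))
    expect_equal(unname(p[nrow(p), ]), c(m, n))
    steps <- diff(p)
    expect_true(all(steps[, 1] %in% 0:1 & steps[, 2] %in% 0:1 &
                      rowSums(steps) >= 1))
    if (is.finite(r)) {
      expect_true(all(abs(p[, 2] - (n / m) * p[, 1]) <= r))
    }
    expect_equal(sum(abs(a[p[, 1]] - b[p[, 2]])), res$distance,
                 tolerance = 1e-12)
  }
})

test_that("DTW is symmetric, band-monotone, and diagonally bounded", {
  set.seed(21)
  for (k in 1:20) {
    a <- runif(8, 0, 6)
    b <- runif(8, 0, 6)
    expect_equal(dtw_distance(a, b, band_radius = 3)$distance,
                 dtw_distance(b, a, band_radius = 3)$distance)
    d_tight <- dtw_distance(a, b, band_radius = 1)$distance
    d_mid <- dtw_distance(a, b, band_radius = 3)$distance
    d_free <- dtw_distance(a, b, band_radius = Inf)$distance
    expect_gte(d_tight, d_mid - 1e-12)
    expect_gte(d_mid, d_free - 1e-12)
    expect_lte(d_free, sum(abs(a - b)) + 1e-12)
  }
})

test_that("squared local distance is supported", {
  a <- c(1, 2, 4)
  b <- c(1, 3, 3)
  d <- dtw_distance(a, b, band_radius = Inf, local_distance = "squared")
  expect_equal(d$distance, dtw_enum_oracle(a, b, squared = TRUE))
})

test_that("degenerate inputs raise typed errors", {
  expect_error(dtw_distance(numeric(0), 1:3),
               class = "sistr_invalid_input")
  expect_error(dtw_distance(c(1, NA), 1:2),
               class = "sistr_invalid_input")
  # radius 0 with unequal lengths excludes the endpoints
  expect_error(dtw_distance(1:6, 1:3, band_radius = 0),
               class = "sistr_infeasible_band")
})

test_that("the vectorised many-pairs DTW agrees with scalar calls", {
  set.seed(31)
  A <- matrix(runif(8 * 20, 0, 7), 8, 20)
  B <- matrix(runif(8 * 20, 0, 7), 8, 20)
  for (r in c(2, 3, Inf)) {
    many <- sistr:::dtw_distance_many(A, B, band_radius = r)
    scalar <- vapply(1:8, function(i) {
      dtw_distance(A[i, ], B[i, ], band_radius = r)$distance
    }, numeric(1))
    expect_equal(many, scalar, tolerance = 1e-12)
  }
})
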