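# Independent oracles used across the suite. These deliberately take naive,
# separate code paths from the package internals they check.

# --- DTW oracles -----------------------------------------------------------

# All monotone warping paths from (1,1) to (m,n), enumerated once per shape
# and cached. Each path is a k x 2 matrix of 1-based indices.
.path_cache <- new.env(parent = emptyenv())

enumerate_paths <- function(m, n) {
  key <- paste(m, n)
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  paths <- list()
  walk <- function(i, j, trail) {
    trail[[length(trail) + 1]] <- c(i, j)
    if (i == m && j == n) {
      paths[[length(paths) + 1]] <<- do.call(rbind, trail)
      return(invisible())
    }
    if (i < m) walk(i + 1, j, trail)
    if (i < m && j < n) walk(i + 1, j + 1, trail)
    if (j < n) walk(i, j + 1, trail)
  }
  walk(1, 1, list())
  .path_cache[[key]] <- paths
  paths
}

# Exhaustive-enumeration DTW: minimum summed local cost over every monotone
# path whose nodes all satisfy the band constraint.
dtw_enum_oracle <- function(a, b, r = Inf, squared = FALSE) {
  m <- length(a)
  n <- length(b)
  delta <- abs(outer(a, b, "-"))
  if (squared) delta <- delta^2
  best <- Inf
  for (p in enumerate_paths(m, n)) {
    if (is.finite(r) && any(abs(p[, 2] - (n / m) * p[, 1]) > r)) next
    best <- min(best, sum(delta[p]))
  }
  best
}

# Top-down memoised DTW recursion (independent of the package's iterative
# banded dynamic program).
dtw_memo_oracle <- function(a, b, r = Inf) {
  m <- length(a)
  n <- length(b)
  memo <- matrix(NA_real_, m, n)
  admissible <- function(i, j) !is.finite(r) || abs(j - (n / m) * i) <= r
  rec <- function(i, j) {
    if (i < 1 || j < 1 || !admissible(i, j)) return(Inf)
    if (!is.na(memo[i, j])) return(memo[i, j])
    d <- abs(a[i] - b[j])
    val <- if (i == 1 && j == 1) d else
      d + min(rec(i - 1, j), rec(i - 1, j - 1), rec(i, j - 1))
    memo[i, j] <<- val
    val
  }
  rec(m, n)
}

# --- Local Moran oracle ----------------------------------------------------

# Direct double-loop evaluation of Anselin's local statistic with 3x3
# queen weights restricted to present pixels.
local_moran_oracle <- function(df, scheme = "row") {
  df <- df[order(df$row, df$col), ]
  n <- nrow(df)
  xbar <- mean(df$value)
  m2 <- sum((df$value - xbar)^2) / n
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(abs(df$row - df$row[i]) <= 1 & abs(df$col - df$col[i]) <= 1 &
                  !(df$row == df$row[i] & df$col == df$col[i]))
    if (length(nb) == 0) {
      out[i] <- NA_real_
      next
    }
    w <- if (scheme == "row") rep(1 / length(nb), length(nb)) else
      rep(1, length(nb))
    out[i] <- (df$value[i] - xbar) / m2 * sum(w * (df$value[nb] - xbar))
  }
  out
}

# --- Connected components oracle -------------------------------------------

# Recursive flood fill labelling, 4- or 8-connectivity.
flood_fill_oracle <- function(mask, connectivity = 4) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  fill <- function(r, c, id) {
    if (r < 1 || r > nr || c < 1 || c > nc) return(invisible())
    if (!mask[r, c] || lab[r, c] != 0L) return(invisible())
    lab[r, c] <<- id
    fill(r - 1, c, id)
    fill(r + 1, c, id)
    fill(r, c - 1, id)
    fill(r, c + 1, id)
    if (connectivity == 8) {
      fill(r - 1, c - 1, id)
      fill(r - 1, c + 1, id)
      fill(r + 1, c - 1, id)
      fill(r + 1, c + 1, id)
    }
  }
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (mask[r, c] && lab[r, c] == 0L) {
        cur <- cur + 1L
        fill(r, c, cur)
      }
    }
  }
  lab
}

# --- Small fixtures --------------------------------------------------------

# Constant-radiation season: isolates the crop model from the weather model.
constant_meteo <- function(rs = 15, tmean = 27) {
  tibble::tibble(doy = 160:255, tmax = tmean + 4, tmin = tmean - 4,
                 sunshine_hours = 6, rs = rs)
}

# A tiny all-rice scene from explicit per-pixel series.
scene_from_series <- function(series_list, years) {
  purrr::map_dfr(seq_along(series_list), function(k) {
    px <- series_list[[k]]
    purrr::map_dfr(seq_along(years), function(y) {
      tibble::tibble(row = px$row, col = px$col, year = years[y],
                     doy = sistr::canonical_doys(), lai = px$lai[[y]])
    })
  })
}
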