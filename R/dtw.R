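#' Sakoe-Chiba band admissibility mask
#'
#' Cell (i, j) of the m x n alignment grid (1-based) is admissible when
#' \deqn{|j - \tfrac{n}{m} i| \le r,}
#' i.e. the warping path must stay within `r` samples of the slope-adjusted
#' main diagonal.
#'
#' @param m,n Series lengths (rows and columns of the grid).
#' @param r Band radius in sample units, >= 0. `r >= max(m, n)` admits every
#'   cell.
#' @return An `m x n` logical matrix, TRUE where admissible.
#' @export
#' @examples
#' dtw_band(5, 5, 0)   # exactly the main diagonal
dtw_band <- function(m, n, r) {
  if (m < 1 || n < 1 || r < 0) {
    abort("Need m, n >= 1 and r >= 0.", class = "sistr_invalid_input")
  }
  i <- matrix(seq_len(m), m, n)
  j <- matrix(seq_len(n), m, n, byrow = TRUE)
  abs(j - (n / m) * i) <= r
}

#' Dynamic time warping distance between two series
#'
#' Computes the constrained DTW distance
#' \deqn{D_{i,j} = \delta(a_i, b_j) + \min\{D_{i-1,j},\, D_{i-1,j-1},\,
#'   D_{i,j-1}\}}
#' with boundary path ends fixed at (1,1) and (m,n), steps restricted to
#' right/down/diagonal (continuous and monotone), and the warping path
#' confined to the Sakoe-Chiba band of radius `band_radius` ([dtw_band()]).
#' The local cost is `|a_i - b_j|` (default, keeping the distance in LAI
#' units) or the squared difference. The accumulated distance is not
#' path-length normalised; downstream min-max normalisation absorbs scale.
#'
#' @param a,b Numeric series (non-empty, finite).
#' @param band_radius Sakoe-Chiba radius in samples; `Inf` disables the
#'   global constraint. Default 3 (15 days on the 5-day LAI grid).
#' @param local_distance `"absolute"` or `"squared"`.
#' @param return_path If TRUE, also return the optimal warping path and the
#'   accumulated cost matrix.
#' @return An object of class `sist_dtw`: list with `distance`, and when
#'   requested `path` (two-column matrix of 1-based (i, j) pairs) and
#'   `cost_matrix`.
#' @export
#' @examples
#' dtw_distance(c(0, 1, 0, 0), c(0, 0, 1, 0))$distance  # < Euclidean sum 2
dtw_distance <- function(a, b, band_radius = 3,
                         local_distance = c("absolute", "squared"),
                         return_path = FALSE) {
  local_distance <- match.arg(local_distance)
  if (length(a) == 0 || length(b) == 0 ||
      any(!is.finite(a)) || any(!is.finite(b))) {
    abort("Series must be non-empty and finite.",
          class = "sistr_invalid_input")
  }
  m <- length(a)
  n <- length(b)
  band <- if (is.finite(band_radius)) dtw_band(m, n, band_radius) else
    matrix(TRUE, m, n)
  if (!band[1, 1] || !band[m, n]) {
    abort("Band excludes the path endpoints: radius too small.",
          class = "sistr_infeasible_band")
  }
  delta <- abs(outer(a, b, "-"))
  if (local_distance == "squared") delta <- delta^2
  delta[!band] <- Inf

  D <- matrix(Inf, m + 1, n + 1)
  D[1, 1] <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      if (band[i, j]) {
        D[i + 1, j + 1] <- delta[i, j] +
          min(D[i, j + 1], D[i, j], D[i + 1, j])
      }
    }
  }
  dist <- D[m + 1, n + 1]
  if (!is.finite(dist)) {
    abort("Band admits no complete warping path.",
          class = "sistr_infeasible_band")
  }
  out <- list(distance = dist, band_radius = band_radius,
              local_distance = local_distance)
  if (return_path) {
    path <- matrix(NA_integer_, m + n, 2)
    i <- as.integer(m)
    j <- as.integer(n)
    k <- 0L
    while (i >= 1 && j >= 1) {
      k <- k + 1L
      path[k, ] <- c(i, j)
      if (i == 1 && j == 1) break
      steps <- c(D[i, j], D[i, j + 1], D[i + 1, j])  # diag, up, left
      pick <- which.min(steps)
      if (pick == 1) {
        i <- i - 1L
        j <- j - 1L
      } else if (pick == 2) {
        i <- i - 1L
      } else {
        j <- j - 1L
      }
    }
    out$path <- path[k:1, , drop = FALSE]
    out$cost_matrix <- D[-1, -1, drop = FALSE]
  }
  structure(out, class = "sist_dtw")
}

#' @export
print.sist_dtw <- function(x, ...) {
  cat(sprintf("DTW distance %.6g (band radius %s, %s local cost)\n",
              x$distance, format(x$band_radius), x$local_distance))
  if (!is.null(x$path)) {
    cat("  path length", nrow(x$path), "\n")
  }
  invisible(x)
}

# internal: DTW distances for many series pairs at once.
# A, B: npix x len matrices (row k of A aligned against row k of B).
# Same recursion as dtw_distance, vectorised across rows; used by the
# raster-scale stress metrics. Returns a numeric vector of length npix.
dtw_distance_many <- function(A, B, band_radius = 3,
                              local_distance = "absolute") {
  m <- ncol(A)
  n <- ncol(B)
  stopifnot(nrow(A) == nrow(B))
  npix <- nrow(A)
  if (npix == 0) return(numeric(0))
  band <- if (is.finite(band_radius)) dtw_band(m, n, band_radius) else
    matrix(TRUE, m, n)
  if (!band[1, 1] || !band[m, n]) {
    abort("Band excludes the path endpoints: radius too small.",
          class = "sistr_infeasible_band")
  }
  prev <- matrix(Inf, npix, n + 1)
  prev[, 1] <- 0  # D[0, 0] = 0; D[0, j>0] = Inf
  first <- TRUE
  for (i in seq_len(m)) {
    cur <- matrix(Inf, npix, n + 1)
    for (j in seq_len(n)) {
      if (band[i, j]) {
        d <- abs(A[, i] - B[, j])
        if (local_distance == "squared") d <- d * d
        cur[, j + 1] <- d + pmin(prev[, j + 1], pmin(prev[, j], cur[, j]))
      }
    }
    prev <- cur
    if (first) first <- FALSE
  }
  res <- prev[, n + 1]
  if (any(!is.finite(res))) {
    abort("Band admits no complete warping path.",
          class = "sistr_infeasible_band")
  }
  res
}
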