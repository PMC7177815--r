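# Spatial autocorrelation of a rice-masked surface with a 3x3 neighbourhood
# (queen contiguity, centre excluded). Only rice pixels — the (row, col)
# keys present in the input — are ever used as neighbours; edge pixels use
# truncated neighbourhoods, never padded ones.

# internal: neighbour pairs (i -> j) for the 3x3 window over present pixels
neighbor_pairs <- function(pixels) {
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  keyed <- mutate(pixels, .id = dplyr::row_number())
  purrr::map_dfr(seq_len(nrow(offs)), function(k) {
    shifted <- mutate(keyed, row = .data$row + offs$dr[k],
                      col = .data$col + offs$dc[k])
    inner_join(select(keyed, "row", "col", i = ".id"),
               select(shifted, "row", "col", j = ".id"),
               by = c("row", "col"))
  }) %>% select("i", "j")
}

#' Local Moran's I of a surface on the rice mask
#'
#' Computes Anselin's local indicator of spatial association for every rice
#' pixel i with at least one rice neighbour in its 3x3 window:
#' \deqn{I_i = \frac{x_i - \bar x}{m_2} \sum_j w_{ij} (x_j - \bar x), \quad
#'   m_2 = \frac{1}{n}\sum_k (x_k - \bar x)^2,}
#' with the mean and variance taken over all rice pixels. Positive values
#' flag local clustering of similar values, negative values local
#' dispersion. Pixels with no rice neighbour are labelled `isolated` and get
#' `NA`. A zero-variance field is degenerate: all I are defined as 0 with a
#' warning.
#'
#' Cluster labels follow the value/mean and I signs: `I > 0` with
#' `x > mean` is `high-high`, `I > 0` with `x < mean` is `low-low`; `I < 0`
#' gives `high-low`/`low-high`; exact ties map to `none`.
#'
#' @param values A tibble with columns `row`, `col`, `value` (rice pixels
#'   only; absent keys are non-rice).
#' @param scheme Spatial weights: `"row"` (row-standardised binary, each of
#'   a pixel's k rice neighbours weighted 1/k; the default, comparable
#'   between edge and interior pixels) or `"binary"` (weight 1 each).
#' @return A tibble `row`, `col`, `value`, `n_neighbors`, `i_raw`,
#'   `cluster`, carrying attributes `global_mean`, `m2` and `s0`.
#' @export
#' @examples
#' field <- tidyr::expand_grid(row = 1:5, col = 1:5)
#' field$value <- as.numeric(field$row > 2)  # high half / low half
#' local_morans_i(field)
local_morans_i <- function(values, scheme = c("row", "binary")) {
  scheme <- match.arg(scheme)
  if (!is.data.frame(values) ||
      !all(c("row", "col", "value") %in% names(values))) {
    abort("`values` needs columns row, col, value.",
          class = "sistr_invalid_input")
  }
  values <- arrange(as_tibble(values), .data$row, .data$col)
  x <- values$value
  n <- length(x)
  if (n < 2) {
    abort("Need at least 2 rice pixels.", class = "sistr_invalid_input")
  }
  xbar <- mean(x)
  m2 <- sum((x - xbar)^2) / n
  pairs <- neighbor_pairs(select(values, "row", "col"))
  deg <- tabulate(pairs$i, nbins = n)

  if (m2 == 0) {
    warn("Zero-variance field: all local Moran's I set to 0.",
         class = "sistr_degenerate_field")
    i_raw <- ifelse(deg > 0, 0, NA_real_)
  } else {
    w <- if (scheme == "row") 1 / deg[pairs$i] else rep(1, nrow(pairs))
    lag <- rep(0, n)
    contrib <- w * (x[pairs$j] - xbar)
    lag_agg <- rowsum(contrib, pairs$i)
    lag[as.integer(rownames(lag_agg))] <- lag_agg[, 1]
    i_raw <- (x - xbar) / m2 * lag
    i_raw[deg == 0] <- NA_real_
  }

  cluster <- dplyr::case_when(
    deg == 0 ~ "isolated",
    is.na(i_raw) | i_raw == 0 | x == xbar ~ "none",
    i_raw > 0 & x > xbar ~ "high-high",
    i_raw > 0 & x < xbar ~ "low-low",
    i_raw < 0 & x > xbar ~ "high-low",
    TRUE ~ "low-high"
  )
  out <- mutate(values, n_neighbors = deg, i_raw = i_raw, cluster = cluster)
  attr(out, "global_mean") <- xbar
  attr(out, "m2") <- m2
  attr(out, "s0") <- if (scheme == "row") sum(deg > 0) else nrow(pairs)
  out
}

#' Global Moran's I of a surface on the rice mask
#'
#' \deqn{I = \frac{n}{S_0}\,
#'   \frac{\sum_i \sum_j w_{ij}(x_i - \bar x)(x_j - \bar x)}
#'        {\sum_i (x_i - \bar x)^2}, \qquad S_0 = \sum_i\sum_j w_{ij}.}
#' With row-standardised weights on a fully connected mask, the mean of the
#' local statistics from [local_morans_i()] equals this global value.
#'
#' @inheritParams local_morans_i
#' @return A single number.
#' @export
global_morans_i <- function(values, scheme = c("row", "binary")) {
  scheme <- match.arg(scheme)
  values <- arrange(as_tibble(values), .data$row, .data$col)
  x <- values$value
  n <- length(x)
  xbar <- mean(x)
  denom <- sum((x - xbar)^2)
  if (denom == 0) {
    warn("Zero-variance field: global Moran's I set to 0.",
         class = "sistr_degenerate_field")
    return(0)
  }
  pairs <- neighbor_pairs(select(values, "row", "col"))
  deg <- tabulate(pairs$i, nbins = n)
  w <- if (scheme == "row") 1 / deg[pairs$i] else rep(1, nrow(pairs))
  num <- sum(w * (x[pairs$i] - xbar) * (x[pairs$j] - xbar))
  s0 <- sum(w)
  n / s0 * num / denom
}
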