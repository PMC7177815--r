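#' Composite spatio-temporal stress index (SIST)
#'
#' Combines the three normalised components — final stress level, temporal
#' stability, and local Moran's I of temporal stability — into
#' \deqn{SIST = \sqrt[3]{S_{norm} \times TS \times I_{norm}},}
#' the geometric mean of the three factors, so SIST lies in \[0, 1\]. A high
#' SIST marks a pixel that is strongly stressed, stressed the same way in
#' both years, and sits in a spatial cluster of equally stable pixels — the
#' signature of chronic heavy-metal stress. A zero in any component zeroes
#' the index. Nodata (`NA`) in any component propagates.
#'
#' @param components A tibble with columns `row`, `col`, `s_final`, `ts`,
#'   `i_norm`, each component in \[0, 1\] where defined.
#' @return The input tibble with a `sist` column appended.
#' @export
#' @examples
#' compute_sist(tibble::tibble(row = 1, col = 1:3,
#'                             s_final = c(1, 0.5, 0.9),
#'                             ts = c(1, 0.5, 0.8),
#'                             i_norm = c(1, 0.5, 0.1)))
compute_sist <- function(components) {
  need <- c("row", "col", "s_final", "ts", "i_norm")
  if (!is.data.frame(components) || !all(need %in% names(components))) {
    abort(paste0("`components` needs columns ",
                 paste(need, collapse = ", "), "."),
          class = "sistr_invalid_input")
  }
  for (nm in c("s_final", "ts", "i_norm")) {
    v <- components[[nm]]
    if (any(v < -1e-12 | v > 1 + 1e-12, na.rm = TRUE)) {
      abort(paste0("Component `", nm, "` outside [0, 1]: upstream ",
                   "normalisation bug."),
            class = "sistr_invalid_input")
    }
  }
  mutate(as_tibble(components),
         sist = (pmin(pmax(.data$s_final, 0), 1) *
                   pmin(pmax(.data$ts, 0), 1) *
                   pmin(pmax(.data$i_norm, 0), 1))^(1 / 3))
}

#' Zonal summary of a SIST surface
#'
#' @param sist A tibble with `row`, `col`, `sist`.
#' @param zones A tibble with `row`, `col`, `zone` (co-registered labels).
#' @param threshold SIST level above which a pixel counts as flagged
#'   (configuration, default 0.5).
#' @return One row per zone: `zone`, `n`, `mean_sist`, `median_sist`,
#'   `frac_above`. Zones with no defined SIST pixels report `n = 0`.
#' @export
zonal_summary <- function(sist, zones, threshold = 0.5) {
  joined <- left_join(zones, sist, by = c("row", "col"))
  joined %>%
    group_by(.data$zone) %>%
    summarise(
      n = sum(!is.na(.data$sist)),
      mean_sist = if (n > 0) mean(.data$sist, na.rm = TRUE) else NA_real_,
      median_sist = if (n > 0) median(.data$sist, na.rm = TRUE) else NA_real_,
      frac_above = if (n > 0) mean(.data$sist > threshold, na.rm = TRUE)
                   else NA_real_,
      .groups = "drop"
    )
}

#' Pearson correlation between an index and reference values
#'
#' Standard product-moment correlation, used to relate SIST to an external
#' reference such as soil contaminant concentration.
#'
#' @param x,y Paired numeric vectors, at least 3 complete pairs, each with
#'   nonzero variance.
#' @return The correlation coefficient r in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) {
    abort("Need at least 3 complete pairs.", class = "sistr_invalid_input")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined: zero variance.",
          class = "sistr_undefined_correlation")
  }
  cor(x, y)
}

#' Ranking AUC of an index against a binary truth
#'
#' Probability that a randomly chosen positive pixel outranks a randomly
#' chosen negative one (Mann-Whitney form), used to quantify how well SIST
#' separates heavy-metal pixels from the rest on synthetic scenes.
#'
#' @param score Numeric scores (higher = more likely positive).
#' @param positive Logical vector, TRUE for positives.
#' @return AUC in \[0, 1\].
#' @export
ranking_auc <- function(score, positive) {
  ok <- is.finite(score) & !is.na(positive)
  score <- score[ok]
  positive <- as.logical(positive[ok])
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) {
    abort("Need both positive and negative pixels.",
          class = "sistr_invalid_input")
  }
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
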