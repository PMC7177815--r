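# Plain-text serialisation. Rasters travel as long CSV keyed on (row, col):
# absent keys are nodata, which is never silently converted to 0. A sidecar
# JSON records normalisation extrema and settings for provenance.

#' Read / write a scene CSV
#'
#' Long format with columns `row,col,year,doy,lai`; rice pixels only.
#' Round-trips exactly (`write` then `read` restores the data).
#'
#' @param path File path.
#' @return `read_scene_csv()`: a validated scene tibble.
#' @export
read_scene_csv <- function(path) {
  validate_scene(as_tibble(read.csv(path)))
}

#' @param scene Scene tibble to write.
#' @rdname read_scene_csv
#' @export
write_scene_csv <- function(scene, path) {
  write.csv(validate_scene(scene), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sparse LAI observations
#'
#' Columns `pixel_id,year,doy,lai` or `pixel_id,year,doy,ndvi` (NDVI is
#' converted to LAI via [ndvi_to_lai()]).
#'
#' @param path File path.
#' @return A tibble with columns `pixel_id`, `year`, `doy`, `lai`.
#' @export
read_observations_csv <- function(path) {
  df <- as_tibble(read.csv(path))
  if (!"lai" %in% names(df)) {
    if (!"ndvi" %in% names(df)) {
      abort("Observations need a `lai` or `ndvi` column.",
            class = "sistr_invalid_input")
    }
    df$lai <- ndvi_to_lai(df$ndvi)
  }
  df
}

#' Write pipeline result surfaces
#'
#' Writes the per-pixel surfaces as CSV and a sidecar JSON with the
#' normalisation extrema and settings.
#'
#' @param result A `sist_result` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  surf_path <- file.path(dir, "surfaces.csv")
  stress_path <- file.path(dir, "stress_by_year.csv")
  meta_path <- file.path(dir, "provenance.json")
  write.csv(result$surfaces, surf_path, row.names = FALSE)
  write.csv(result$stress_by_year, stress_path, row.names = FALSE)
  jsonlite::write_json(
    list(extrema = result$extrema, settings = result$settings),
    meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(surf_path, stress_path, meta_path))
}
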