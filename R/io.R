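# Plain-text interchange: CSV for tables and (small) cubes, JSON for the
# community manifest. Intended for desk-scale worlds and for handing results
# to other tools; large real-data rasters are out of scope here.

#' Write / read a climate cube as CSV
#'
#' The cube is written as two files in `dir`: `climate.csv` (long format:
#' `year`, `fine_row`, `fine_col`, `temperature`, `precipitation`) and
#' `elevation.csv` (`fine_row`, `fine_col`, `elevation`), plus `config.json`.
#' Practical for desk-scale worlds only.
#'
#' @param cube A [climate_cube()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_climate_cube <- function(cube, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(cube$temperature)
  long <- data.frame(
    year = rep(seq_len(d[1]), times = d[2] * d[3]),
    fine_row = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    fine_col = rep(seq_len(d[3]), each = d[1] * d[2]),
    temperature = as.vector(cube$temperature),
    precipitation = as.vector(cube$precipitation)
  )
  utils::write.csv(long, file.path(dir, "climate.csv"), row.names = FALSE)
  elev <- data.frame(
    fine_row = rep(seq_len(d[2]), times = d[3]),
    fine_col = rep(seq_len(d[3]), each = d[2]),
    elevation = as.vector(cube$elevation)
  )
  utils::write.csv(elev, file.path(dir, "elevation.csv"), row.names = FALSE)
  cfg <- unclass(cube$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_climate_cube
#' @export
read_climate_cube <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- do.call(world_config, cfg[names(cfg) %in% names(formals(world_config))])
  long <- utils::read.csv(file.path(dir, "climate.csv"))
  d <- c(config$n_years,
         config$n_coarse_rows * config$fine_per_coarse,
         config$n_coarse_cols * config$fine_per_coarse)
  ord <- order(long$fine_col, long$fine_row, long$year)
  temperature <- array(long$temperature[ord], dim = d)
  precipitation <- array(long$precipitation[ord], dim = d)
  elev <- utils::read.csv(file.path(dir, "elevation.csv"))
  elevation <- matrix(elev$elevation[order(elev$fine_col, elev$fine_row)],
                      d[2], d[3])
  climate_cube(temperature, precipitation, elevation, config)
}

#' Write a predictor table as CSV
#'
#' @param table A [predictor_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictor_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictor_table
#' @export
read_predictor_table <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("predictor_table", "data.frame")
  out
}

#' Write species occurrences and a community manifest
#'
#' Occurrences go to a tidy CSV (`species_id`, `cell_id`, `archetype`), the
#' manifest (ground-truth archetypes, exclusion flags, niche parameters are
#' not serialized) to JSON.
#'
#' @param community An `sdm_community` or list of [species_occurrence()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  species <- if (inherits(community, "sdm_community")) community$species else community
  occ <- do.call(rbind, lapply(species, function(s) {
    if (!length(s$presence_cells)) return(NULL)
    data.frame(species_id = s$species_id, cell_id = s$presence_cells,
               archetype = s$archetype)
  }))
  utils::write.csv(occ, file.path(dir, "occurrences.csv"), row.names = FALSE)
  manifest <- if (inherits(community, "sdm_community")) community$manifest else
    data.frame(species_id = vapply(species, `[[`, character(1), "species_id"),
               archetype = vapply(species, `[[`, character(1), "archetype"),
               excluded = vapply(species, `[[`, character(1), "excluded"),
               n_cells = vapply(species, function(s) length(s$presence_cells),
                                integer(1)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Write evaluation records as tidy CSV
#'
#' @param records Records from [evaluate_community()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) utils::read.csv(path)
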