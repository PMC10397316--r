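# Aggregation of the fine-grain climate cube to coarse-cell predictors.
#
# Conventions (kept strictly apart so the spatial and temporal predictor
# families stay orthogonal):
#   * mean_*        : mean over all fine cells of each fine cell's across-year
#                     mean (order of averaging is immaterial for the mean).
#   * spatial_sd_*  : SD across fine cells, within a coarse cell, of the
#                     per-fine-cell long-term (across-year) means -- pure
#                     sub-grid spatial heterogeneity, no interannual leakage.
#   * temporal_sd_temp / temporal_rsd_prec : aggregate each year to the coarse
#                     cell first (spatial mean), then take the SD (temperature)
#                     or SD/mean (precipitation) of the yearly coarse series --
#                     pure interannual variability.
# Sample (n-1) standard deviations throughout.

# column-sum helper: per-coarse-cell sums of a fine-grain matrix
.coarse_sum <- function(m, ids) rowsum(as.vector(m), as.vector(ids))

.fine_climatology <- function(cube) {
  list(temp = colMeans(cube$temperature, dims = 1),
       prec = colMeans(cube$precipitation, dims = 1))
}

#' Aggregate long-term means to the coarse grid
#'
#' @param cube A [climate_cube()].
#' @return A data.frame with `cell_id`, `mean_temp` (degrees C) and
#'   `mean_prec` (mm), one row per coarse cell.
#' @export
aggregate_mean <- function(cube) {
  stopifnot(inherits(cube, "climate_cube"))
  ids <- fine_to_coarse_ids(cube$config)
  nfc <- cube$config$fine_per_coarse^2
  clim <- .fine_climatology(cube)
  data.frame(
    cell_id = seq_len(n_cells(cube$config)),
    mean_temp = as.vector(.coarse_sum(clim$temp, ids)) / nfc,
    mean_prec = as.vector(.coarse_sum(clim$prec, ids)) / nfc
  )
}

#' Sub-grid spatial variability per coarse cell
#'
#' Standard deviation, across the fine cells within each coarse cell, of the
#' per-fine-cell long-term means. Coarse cells with a single fine cell get 0.
#'
#' @param cube A [climate_cube()].
#' @return A data.frame with `cell_id`, `spatial_sd_temp`, `spatial_sd_prec`.
#' @export
spatial_sd <- function(cube) {
  stopifnot(inherits(cube, "climate_cube"))
  cfg <- cube$config
  ids <- fine_to_coarse_ids(cfg)
  nfc <- cfg$fine_per_coarse^2
  clim <- .fine_climatology(cube)
  sd_of <- function(m) {
    if (nfc < 2) return(rep(0, n_cells(cfg)))
    s <- .coarse_sum(m, ids); s2 <- .coarse_sum(m^2, ids)
    as.vector(sqrt(pmax(0, (s2 - s^2 / nfc) / (nfc - 1))))
  }
  data.frame(cell_id = seq_len(n_cells(cfg)),
             spatial_sd_temp = sd_of(clim$temp),
             spatial_sd_prec = sd_of(clim$prec))
}

#' Interannual variability per coarse cell
#'
#' Each year is first aggregated to the coarse cell (spatial mean), then the
#' yearly coarse series is summarized: sample SD for temperature
#' (`temporal_sd_temp`, degrees C) and relative SD, i.e. the coefficient of
#' variation SD/mean, for the annual precipitation sum (`temporal_rsd_prec`,
#' dimensionless).
#'
#' @param cube A [climate_cube()] with at least 2 years.
#' @return A data.frame with `cell_id`, `temporal_sd_temp`, `temporal_rsd_prec`.
#' @export
temporal_variability <- function(cube) {
  stopifnot(inherits(cube, "climate_cube"))
  cfg <- cube$config
  if (cfg$n_years < 2)
    stop("temporal variability needs at least 2 years", call. = FALSE)
  ids <- fine_to_coarse_ids(cfg)
  nfc <- cfg$fine_per_coarse^2
  N <- n_cells(cfg); Y <- cfg$n_years
  yearly_t <- matrix(0, Y, N); yearly_p <- matrix(0, Y, N)
  for (y in seq_len(Y)) {
    yearly_t[y, ] <- .coarse_sum(cube$temperature[y, , ], ids) / nfc
    yearly_p[y, ] <- .coarse_sum(cube$precipitation[y, , ], ids) / nfc
  }
  sd_t <- apply(yearly_t, 2, stats::sd)
  mu_p <- colMeans(yearly_p)
  if (any(mu_p < 1e-9))
    stop("mean precipitation below 1e-9 in some cells; cannot form a CV",
         call. = FALSE)
  data.frame(cell_id = seq_len(N),
             temporal_sd_temp = sd_t,
             temporal_rsd_prec = apply(yearly_p, 2, stats::sd) / mu_p)
}

#' Build the full coarse-grid predictor table
#'
#' Combines [aggregate_mean()], [spatial_sd()] and [temporal_variability()]
#' into one table with the six predictors used by the four predictor groups,
#' plus grid coordinates and the nominal latitude of each coarse cell.
#'
#' @param cube A [climate_cube()].
#' @return A data.frame of class `predictor_table`: `cell_id`, `row`, `col`,
#'   `lat`, `mean_temp`, `mean_prec`, `spatial_sd_temp`, `spatial_sd_prec`,
#'   `temporal_sd_temp`, `temporal_rsd_prec`.
#' @export
predictor_table <- function(cube) {
  g <- cell_grid(cube$config)[, c("cell_id", "row", "col", "lat")]
  out <- Reduce(function(a, b) merge(a, b, by = "cell_id", sort = TRUE),
                list(g, aggregate_mean(cube), spatial_sd(cube),
                     temporal_variability(cube)))
  out <- out[order(out$cell_id), ]
  rownames(out) <- NULL
  class(out) <- c("predictor_table", "data.frame")
  out
}

#' Predictor group definitions
#'
#' The four predictor groups: `mean` (long-term means only), `spatial`
#' (means plus sub-grid spatial SDs), `temporal` (means plus interannual
#' variability) and `sp-temp` (all six). The spatial and temporal groups have
#' the same number of predictors (4), so their comparison is not confounded by
#' model complexity.
#'
#' @return A named list of character vectors of predictor-column names.
#' @export
predictor_groups <- function() {
  mean_cols <- c("mean_temp", "mean_prec")
  spat_cols <- c("spatial_sd_temp", "spatial_sd_prec")
  temp_cols <- c("temporal_sd_temp", "temporal_rsd_prec")
  list("mean" = mean_cols,
       "spatial" = c(mean_cols, spat_cols),
       "temporal" = c(mean_cols, temp_cols),
       "sp-temp" = c(mean_cols, spat_cols, temp_cols))
}

#' Design matrix for a predictor group
#'
#' @param table A [predictor_table()].
#' @param group Group name: `"mean"`, `"spatial"`, `"temporal"` or `"sp-temp"`.
#' @param cells Coarse-cell ids selecting (and ordering) the rows; defaults to
#'   all cells.
#' @return A numeric matrix with one row per requested cell (rownames are the
#'   cell ids) and the group's predictor columns in stable order.
#' @export
build_group_matrix <- function(table, group, cells = table$cell_id) {
  groups <- predictor_groups()
  if (!group %in% names(groups))
    stop("unknown predictor group '", group, "'; expected one of: ",
         paste(names(groups), collapse = ", "), call. = FALSE)
  cols <- groups[[group]]
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("predictor table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  idx <- match(cells, table$cell_id)
  if (anyNA(idx))
    stop("unknown cell ids: ", paste(utils::head(cells[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  m <- as.matrix(table[idx, cols, drop = FALSE])
  rownames(m) <- as.character(cells)
  m
}
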