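# From ranges to modelling datasets: gridding, the minimum-range-size filter,
# the buffered modelling domain, and class-balancing weights.

#' Grid a species range onto the coarse grid
#'
#' Any non-empty intersection makes a cell a presence cell (intersection rule,
#' not majority rule). In synthetic mode the range already is a set of coarse
#' cell ids and the operation is the identity (after validation). A polygon
#' (2-column matrix of vertices in km coordinates, one ring) is rasterized by
#' testing a corner-inclusive lattice of sample points per cell, so slivers
#' touching cell corners or edges register; interior slivers narrower than the
#' lattice spacing (cell size / `lattice_n`) can be missed.
#'
#' @param range_geometry Integer vector of coarse-cell ids, or a 2-column
#'   numeric matrix of polygon vertices (km).
#' @param config A [world_config()].
#' @param lattice_n Lattice subdivisions per cell side for polygon mode.
#' @return Sorted integer vector of presence cell ids.
#' @export
grid_range <- function(range_geometry, config, lattice_n = 10) {
  if (is.matrix(range_geometry)) {
    if (ncol(range_geometry) != 2 || nrow(range_geometry) < 3)
      stop("polygon must be a 2-column matrix with >= 3 vertices", call. = FALSE)
    g <- cell_grid(config)
    half <- config$cell_size_km / 2
    off <- seq(-half, half, length.out = lattice_n + 1)
    pts <- expand.grid(dx = off, dy = off)
    present <- logical(nrow(g))
    for (i in seq_len(nrow(g))) {
      xy <- cbind(g$x_km[i] + pts$dx, g$y_km[i] + pts$dy)
      if (any(mgcv::in.out(range_geometry, xy))) present[i] <- TRUE
    }
    # vertices falling inside a cell also count as intersection
    vr <- ceiling(range_geometry[, 2] / config$cell_size_km)
    vc <- ceiling(range_geometry[, 1] / config$cell_size_km)
    ok <- vr >= 1 & vr <= config$n_coarse_rows & vc >= 1 & vc <= config$n_coarse_cols
    present[(vr[ok] - 1) * config$n_coarse_cols + vc[ok]] <- TRUE
    if (!any(present)) stop("polygon does not intersect the grid", call. = FALSE)
    return(which(present))
  }
  cells <- sort(unique(as.integer(range_geometry)))
  if (!length(cells)) stop("empty range geometry", call. = FALSE)
  if (any(cells < 1 | cells > n_cells(config)))
    stop("cell ids outside the coarse grid", call. = FALSE)
  cells
}

#' Apply the minimum-range-size filter
#'
#' Species whose presences cover fewer than `min_cells` coarse cells are
#' flagged `excluded = "too_few_cells"`; the default of 72 cells guarantees at
#' least six data points per fitted parameter for a quadratic model on the
#' largest predictor group.
#'
#' @param species A list of [species_occurrence()] or an `sdm_community`.
#' @param min_cells Minimum number of presence cells (default 72).
#' @return A list with `kept` and `excluded` lists of [species_occurrence()];
#'   excluded species carry the updated flag. Species already excluded for
#'   another reason stay excluded.
#' @export
apply_minimum_size_filter <- function(species, min_cells = 72) {
  if (inherits(species, "sdm_community")) species <- species$species
  kept <- list(); excluded <- list()
  for (s in species) {
    if (is.na(s$excluded) && length(s$presence_cells) >= min_cells) {
      kept[[s$species_id]] <- s
    } else {
      if (is.na(s$excluded)) s$excluded <- "too_few_cells"
      excluded[[s$species_id]] <- s
    }
  }
  list(kept = kept, excluded = excluded)
}

#' Buffered modelling domain around a range
#'
#' All coarse cells whose centre lies within `buffer_km` (planar,
#' centre-to-centre) of the nearest presence-cell centre. Presence cells are
#' always contained (distance 0). Model fitting and testing are restricted to
#' this extent so absences are drawn near the range rather than from climates
#' the species never disperses into.
#'
#' @param presence_cells Integer coarse-cell ids.
#' @param config A [world_config()].
#' @param buffer_km Buffer distance in km (default 3000).
#' @return Sorted integer vector of domain cell ids (a superset of
#'   `presence_cells`).
#' @export
build_domain <- function(presence_cells, config, buffer_km = 3000) {
  if (!length(presence_cells)) stop("empty presence set", call. = FALSE)
  g <- cell_grid(config)
  pres <- g[match(presence_cells, g$cell_id), ]
  if (anyNA(pres$cell_id)) stop("presence cells outside the grid", call. = FALSE)
  # min distance from every cell centre to the presence centres, chunked
  mind2 <- rep(Inf, nrow(g))
  for (start in seq(1, nrow(pres), by = 512)) {
    idx <- start:min(start + 511, nrow(pres))
    d2 <- outer(g$x_km, pres$x_km[idx], `-`)^2 +
      outer(g$y_km, pres$y_km[idx], `-`)^2
    mind2 <- pmin(mind2, apply(d2, 1, min))
  }
  g$cell_id[mind2 <= buffer_km^2 + 1e-9]
}

#' Class-balancing observation weights
#'
#' Presences get weight 1; absences get `n_presences / n_absences`, so the
#' summed weight of each class is equal and models see a balanced prevalence
#' despite the (often strong) presence/absence imbalance in buffered domains.
#'
#' @param labels 0/1 vector (1 = presence).
#' @return Positive numeric weights, same length as `labels`.
#' @export
compute_weights <- function(labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both presences and absences are required to balance weights",
         call. = FALSE)
  ifelse(labels == 1, 1, n1 / n0)
}

#' Build a modelling dataset for one species and predictor group
#'
#' Labels every cell of the species' buffered domain (presence = 1, absence =
#' 0), attaches class-balancing weights and the predictor design matrix of the
#' requested group.
#'
#' @param occurrence A [species_occurrence()].
#' @param predictors A [predictor_table()].
#' @param group Predictor group name (see [predictor_groups()]).
#' @param config A [world_config()].
#' @param buffer_km Buffer distance in km (default 3000).
#' @return An object of class `modeling_dataset`: `species_id`, `group`,
#'   `cell_ids`, `labels`, `weights`, `x` (design matrix aligned to
#'   `cell_ids`).
#' @export
build_dataset <- function(occurrence, predictors, group, config,
                          buffer_km = 3000) {
  stopifnot(inherits(occurrence, "species_occurrence"))
  domain <- build_domain(occurrence$presence_cells, config, buffer_km)
  labels <- as.integer(domain %in% occurrence$presence_cells)
  if (all(labels == 1L))
    stop("no absence cells within the buffer for species '",
         occurrence$species_id,
         "'; increase buffer_km or use a larger world", call. = FALSE)
  structure(list(
    species_id = occurrence$species_id, group = group,
    cell_ids = domain, labels = labels,
    weights = compute_weights(labels),
    x = build_group_matrix(predictors, group, domain)
  ), class = "modeling_dataset")
}

#' @export
print.modeling_dataset <- function(x, ...) {
  cat("<modeling_dataset> ", x$species_id, " / ", x$group, ": ",
      sum(x$labels == 1), " presences, ", sum(x$labels == 0),
      " absences, ", ncol(x$x), " predictors\n", sep = "")
  invisible(x)
}
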