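# Virtual species: Gaussian niche responses on coarse-grid predictors.
#
# A virtual species occupies the coarse cells where the product of Gaussian
# responses on its niche axes exceeds an occupancy cutoff. Archetypes encode
# which predictor families constrain the species -- the testable analog of
# organisms that are (in)sensitive to climate variability:
#   mean_only          : the two long-term mean axes only
#   spatial_sensitive  : means + at least one sub-grid spatial-SD axis
#   temporal_sensitive : means + at least one interannual-variability axis
#   mixed              : means + at least one spatial and one temporal axis

NICHE_ARCHETYPES <- c("mean_only", "spatial_sensitive", "temporal_sensitive",
                      "mixed")

.mean_axes <- c("mean_temp", "mean_prec")
.spatial_axes <- c("spatial_sd_temp", "spatial_sd_prec")
.temporal_axes <- c("temporal_sd_temp", "temporal_rsd_prec")

#' Specify a virtual species' niche
#'
#' @param archetype One of `"mean_only"`, `"spatial_sensitive"`,
#'   `"temporal_sensitive"`, `"mixed"`.
#' @param optima Named numeric vector: niche optimum per predictor axis used.
#' @param breadths Named numeric vector (same names): Gaussian niche breadth
#'   (sigma) per axis; all must be positive. The suitability contribution of
#'   axis x is `exp(-(x - optimum)^2 / (2 * breadth^2))`.
#' @param occupancy_cutoff Suitability threshold in (0, 1] above which a cell
#'   is occupied (0 is allowed and occupies every cell).
#' @param cohesion If `TRUE`, the realized range is restricted to the single
#'   4-connected component containing the most suitable cell.
#' @return An object of class `niche_spec`.
#' @export
niche_spec <- function(archetype, optima, breadths, occupancy_cutoff = 0.3,
                       cohesion = TRUE) {
  archetype <- match.arg(archetype, NICHE_ARCHETYPES)
  axes <- names(optima)
  if (is.null(axes) || !identical(sort(axes), sort(names(breadths))))
    stop("'optima' and 'breadths' must be named consistently", call. = FALSE)
  if (any(breadths <= 0)) stop("all niche breadths must be > 0", call. = FALSE)
  known <- c(.mean_axes, .spatial_axes, .temporal_axes)
  if (!all(axes %in% known))
    stop("unknown niche axes: ", paste(setdiff(axes, known), collapse = ", "),
         call. = FALSE)
  has_sp <- any(axes %in% .spatial_axes)
  has_tm <- any(axes %in% .temporal_axes)
  ok <- switch(archetype,
    mean_only = setequal(axes, .mean_axes),
    spatial_sensitive = all(.mean_axes %in% axes) && has_sp && !has_tm,
    temporal_sensitive = all(.mean_axes %in% axes) && has_tm && !has_sp,
    mixed = all(.mean_axes %in% axes) && has_sp && has_tm)
  if (!ok)
    stop("axes {", paste(axes, collapse = ", "),
         "} are inconsistent with archetype '", archetype, "'", call. = FALSE)
  if (length(occupancy_cutoff) != 1 || occupancy_cutoff < 0 || occupancy_cutoff > 1)
    stop("'occupancy_cutoff' must be a single value in [0, 1]", call. = FALSE)
  structure(list(archetype = archetype, optima = optima, breadths = breadths,
                 occupancy_cutoff = occupancy_cutoff,
                 cohesion = isTRUE(cohesion)),
            class = "niche_spec")
}

#' Suitability of every coarse cell for a niche
#'
#' Product of Gaussian responses over the niche's axes, in (0, 1].
#'
#' @param niche A [niche_spec()].
#' @param predictors A [predictor_table()].
#' @return Numeric vector aligned to `predictors$cell_id`.
#' @export
niche_suitability <- function(niche, predictors) {
  axes <- names(niche$optima)
  missing_axes <- setdiff(axes, names(predictors))
  if (length(missing_axes))
    stop("predictor table lacks niche axes: ",
         paste(missing_axes, collapse = ", "), call. = FALSE)
  s <- rep(1, nrow(predictors))
  for (a in axes) {
    z <- (predictors[[a]] - niche$optima[[a]]) / niche$breadths[[a]]
    s <- s * exp(-z^2 / 2)
  }
  s
}

# 4-connected component of `cells` (coarse ids) containing `start`
.connected_component <- function(cells, start, config) {
  C <- config$n_coarse_cols
  inset <- logical(n_cells(config)); inset[cells] <- TRUE
  seen <- logical(length(inset))
  queue <- start; seen[start] <- TRUE
  comp <- integer(0)
  while (length(queue)) {
    id <- queue[[1]]; queue <- queue[-1]
    comp <- c(comp, id)
    r <- (id - 1L) %/% C + 1L; cc <- (id - 1L) %% C + 1L
    nb <- c(if (r > 1L) id - C, if (r < config$n_coarse_rows) id + C,
            if (cc > 1L) id - 1L, if (cc < C) id + 1L)
    nb <- nb[inset[nb] & !seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  sort(comp)
}

#' Realize a virtual species' range on the coarse grid
#'
#' Occupied cells are those with suitability at or above the occupancy cutoff;
#' with cohesion on, only the 4-connected component containing the
#' highest-suitability cell is kept (ties broken by the lowest cell id). If
#' fewer than `min_cells` cells result, the cutoff is relaxed (multiplied by
#' `relax`) and the range recomputed, up to `max_attempts` times; a species
#' still below the minimum is flagged `excluded = "too_few_cells"`.
#'
#' The operation is deterministic: all randomness lives in the niche sampling
#' of [generate_community()].
#'
#' @param predictors A [predictor_table()] computed from the same world.
#' @param niche A [niche_spec()].
#' @param species_id Identifier string.
#' @param min_cells Minimum range size in coarse cells (72 emulates the
#'   6-data-points-per-parameter rule for a quadratic two-predictor model).
#' @param max_attempts Maximum number of cutoff relaxations.
#' @param relax Multiplicative cutoff relaxation per attempt.
#' @return An object of class `species_occurrence`: `species_id`,
#'   `presence_cells` (sorted coarse ids), `archetype`, `excluded`
#'   (`NA`, `"too_few_cells"` or `"domestic_or_aquatic"`), `niche`,
#'   `cutoff_used`.
#' @export
generate_species <- function(predictors, niche, species_id = "sp1",
                             min_cells = 72, max_attempts = 5, relax = 0.7) {
  suit <- niche_suitability(niche, predictors)
  best <- which(suit == max(suit))[1]  # lowest cell id on ties
  cutoff <- niche$occupancy_cutoff
  presence <- integer(0)
  for (attempt in seq_len(max_attempts)) {
    presence <- predictors$cell_id[suit >= cutoff]
    if (niche$cohesion && length(presence) && cutoff > 0) {
      presence <- .connected_component(presence, predictors$cell_id[best],
                                       .table_config(predictors))
    }
    if (length(presence) >= min_cells || attempt == max_attempts) break
    cutoff <- cutoff * relax
  }
  species_occurrence(
    species_id = species_id, presence_cells = presence,
    archetype = niche$archetype,
    excluded = if (length(presence) < min_cells) "too_few_cells" else NA_character_,
    niche = niche, cutoff_used = cutoff
  )
}

# grid geometry implied by a predictor table (row/col columns)
.table_config <- function(predictors) {
  structure(list(n_coarse_rows = max(predictors$row),
                 n_coarse_cols = max(predictors$col)),
            class = "world_config")
}

#' Construct a species occurrence record
#'
#' @param species_id Identifier.
#' @param presence_cells Integer coarse-cell ids (stored sorted, unique).
#' @param archetype Ground-truth niche archetype tag (synthetic mode), or `NA`.
#' @param excluded `NA` if the species is usable, else the exclusion reason
#'   (`"too_few_cells"` or `"domestic_or_aquatic"`).
#' @param niche Optional [niche_spec()] (ground truth).
#' @param cutoff_used Occupancy cutoff that produced the range.
#' @return An object of class `species_occurrence`.
#' @export
species_occurrence <- function(species_id, presence_cells,
                               archetype = NA_character_,
                               excluded = NA_character_, niche = NULL,
                               cutoff_used = NA_real_) {
  if (!is.na(excluded) &&
      !excluded %in% c("too_few_cells", "domestic_or_aquatic"))
    stop("unknown exclusion reason '", excluded, "'", call. = FALSE)
  structure(list(species_id = as.character(species_id),
                 presence_cells = sort(unique(as.integer(presence_cells))),
                 archetype = archetype, excluded = excluded,
                 niche = niche, cutoff_used = cutoff_used),
            class = "species_occurrence")
}

#' @export
print.species_occurrence <- function(x, ...) {
  cat("<species_occurrence> ", x$species_id, ": ",
      length(x$presence_cells), " presence cells",
      if (!is.na(x$archetype)) paste0(" [", x$archetype, "]"),
      if (!is.na(x$excluded)) paste0(" (excluded: ", x$excluded, ")"),
      "\n", sep = "")
  invisible(x)
}

# sample a niche of the given archetype around a random cell of the world
.sample_niche <- function(archetype, predictors, mean_breadth = 0.6,
                          var_breadth = 0.45, occupancy_cutoff = 0.3,
                          cohesion = TRUE) {
  axes <- switch(archetype,
    mean_only = .mean_axes,
    spatial_sensitive = c(.mean_axes, .spatial_axes),
    temporal_sensitive = c(.mean_axes, .temporal_axes),
    mixed = c(.mean_axes, .spatial_axes, .temporal_axes))
  centre <- predictors[sample.int(nrow(predictors), 1), ]
  optima <- vapply(axes, function(a) centre[[a]], numeric(1))
  base <- ifelse(axes %in% .mean_axes, mean_breadth, var_breadth)
  breadths <- vapply(seq_along(axes), function(i) {
    axis_sd <- stats::sd(predictors[[axes[i]]])
    max(base[i] * axis_sd * stats::runif(1, 0.8, 1.2), 1e-8)
  }, numeric(1))
  names(breadths) <- axes
  niche_spec(archetype, optima, breadths, occupancy_cutoff, cohesion)
}

#' Generate a community of virtual species with known archetypes
#'
#' Samples, for each requested archetype, niches centred on random cells of
#' the world (optimum = the centre cell's predictor values; breadth
#' proportional to each axis' global SD) and realizes their ranges with
#' [generate_species()]. Deterministic given `seed`.
#'
#' @param predictors A [predictor_table()].
#' @param n_per_archetype Named integer vector, e.g.
#'   `c(mean_only = 10, temporal_sensitive = 10)`; or a single unnamed count
#'   applied to all four archetypes.
#' @param seed Integer seed for niche sampling.
#' @param mean_breadth,var_breadth Niche breadth as a fraction of each axis'
#'   global SD, for mean axes and variability axes respectively (jittered
#'   uniformly between 0.8 and 1.2 of the base value per species).
#' @param occupancy_cutoff,cohesion,min_cells,max_attempts,relax Passed to
#'   [niche_spec()] / [generate_species()].
#' @return An object of class `sdm_community`: a list with `species` (list of
#'   [species_occurrence()]) and `manifest` (data.frame with `species_id`,
#'   `archetype`, `excluded`, `n_cells`, `cutoff_used` -- the ground-truth
#'   record for recovery tests).
#' @export
generate_community <- function(predictors, n_per_archetype, seed = 1,
                               mean_breadth = 0.6, var_breadth = 0.45,
                               occupancy_cutoff = 0.3, cohesion = TRUE,
                               min_cells = 72, max_attempts = 5, relax = 0.7) {
  if (is.null(names(n_per_archetype))) {
    stopifnot(length(n_per_archetype) == 1)
    n_per_archetype <- stats::setNames(rep(n_per_archetype, 4), NICHE_ARCHETYPES)
  }
  bad <- setdiff(names(n_per_archetype), NICHE_ARCHETYPES)
  if (length(bad))
    stop("unknown archetypes: ", paste(bad, collapse = ", "), call. = FALSE)
  set.seed(seed)
  species <- list()
  for (arch in names(n_per_archetype)) {
    n <- n_per_archetype[[arch]]
    for (i in seq_len(n)) {
      id <- sprintf("%s_%02d", arch, i)
      niche <- .sample_niche(arch, predictors, mean_breadth, var_breadth,
                             occupancy_cutoff, cohesion)
      species[[id]] <- generate_species(predictors, niche, species_id = id,
                                        min_cells = min_cells,
                                        max_attempts = max_attempts,
                                        relax = relax)
    }
  }
  manifest <- data.frame(
    species_id = vapply(species, `[[`, character(1), "species_id"),
    archetype = vapply(species, `[[`, character(1), "archetype"),
    excluded = vapply(species, `[[`, character(1), "excluded"),
    n_cells = vapply(species, function(s) length(s$presence_cells), integer(1)),
    cutoff_used = vapply(species, `[[`, numeric(1), "cutoff_used"),
    row.names = NULL
  )
  structure(list(species = species, manifest = manifest),
            class = "sdm_community")
}

#' @export
print.sdm_community <- function(x, ...) {
  cat("<sdm_community> ", length(x$species), " species (",
      sum(is.na(x$manifest$excluded)), " usable)\n", sep = "")
  print(table(x$manifest$archetype))
  invisible(x)
}
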