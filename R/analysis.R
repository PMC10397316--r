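# Statistical and geographic comparison of predictor groups.

GROUP_LEVELS <- c("mean", "spatial", "temporal", "sp-temp")

# mean metric per species x algorithm x group (drops failed repeats)
.aggregate_records <- function(records, response) {
  if (!response %in% names(records))
    stop("records lack a '", response, "' column", call. = FALSE)
  ok <- !is.na(records[[response]])
  r <- records[ok, , drop = FALSE]
  agg <- stats::aggregate(r[[response]],
                          by = list(species_id = r$species_id,
                                    algorithm = r$algorithm,
                                    group = r$group),
                          FUN = mean)
  names(agg)[4] <- "value"
  agg
}

#' Compare predictor groups with a linear mixed-effects model
#'
#' Fits `value ~ group + (1 | algorithm) + (1 | species_id)` by REML, where
#' `value` is the chosen performance metric averaged over split repeats per
#' species x algorithm x group (set `use_repeats = TRUE` to keep every repeat
#' as a row instead). The predictor group is treatment-coded with reference
#' `"mean"`, so each coefficient is the performance gain of that group over
#' SDMs built from long-term means alone. Random intercepts absorb
#' between-algorithm and between-species differences in baseline performance.
#' With a single algorithm the algorithm intercept is dropped.
#'
#' Singular fits (a variance component estimated at 0) are reported with a
#' warning, not an error.
#'
#' @param records Evaluation records from [evaluate_community()].
#' @param response `"tss"` or `"auc"`.
#' @param use_repeats Keep individual repeats as rows (default `FALSE`:
#'   means per combination, avoiding pseudo-replication).
#' @return An object of class `predictor_group_effects`: list with
#'   `coefficients` (data.frame `group`, `estimate`, `se`, `lower`, `upper`;
#'   reference row has estimate 0), `varcomp` (data.frame `term`, `sd`),
#'   `response`, `reference`, and the underlying `model` (lme4 fit).
#' @export
fit_mixed_model <- function(records, response = c("tss", "auc"),
                            use_repeats = FALSE) {
  response <- match.arg(response)
  dat <- if (use_repeats) {
    ok <- !is.na(records[[response]])
    data.frame(species_id = records$species_id[ok],
               algorithm = records$algorithm[ok],
               group = records$group[ok], value = records[[response]][ok])
  } else .aggregate_records(records, response)
  if (length(unique(dat$group)) < 2 || length(unique(dat$species_id)) < 2)
    stop("mixed model needs records for >= 2 groups and >= 2 species",
         call. = FALSE)
  dat$group <- factor(dat$group,
                      levels = intersect(GROUP_LEVELS, unique(dat$group)))
  multi_alg <- length(unique(dat$algorithm)) > 1
  fml <- if (multi_alg) {
    value ~ group + (1 | algorithm) + (1 | species_id)
  } else value ~ group + (1 | species_id)
  fit <- suppressMessages(lme4::lmer(fml, data = dat, REML = TRUE))
  if (lme4::isSingular(fit))
    warning("singular mixed-model fit: a variance component is estimated at 0",
            call. = FALSE)
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  grp_terms <- grep("^group", names(fe))
  coefs <- data.frame(
    group = c(levels(dat$group)[1], sub("^group", "", names(fe)[grp_terms])),
    estimate = c(0, unname(fe[grp_terms])),
    se = c(NA_real_, unname(se[grp_terms])))
  coefs$lower <- coefs$estimate - 1.96 * coefs$se
  coefs$upper <- coefs$estimate + 1.96 * coefs$se
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- data.frame(term = vc$grp, sd = vc$sdcor)
  structure(list(coefficients = coefs, varcomp = varcomp,
                 response = response, reference = levels(dat$group)[1],
                 model = fit),
            class = "predictor_group_effects")
}

#' @export
print.predictor_group_effects <- function(x, ...) {
  cat("<predictor_group_effects> response:", x$response,
      "| reference group:", x$reference, "\n")
  print(x$coefficients, row.names = FALSE)
  cat("random-effect SDs:\n")
  print(x$varcomp, row.names = FALSE)
  invisible(x)
}

#' Contrast two predictor-group coefficients
#'
#' Wald comparison of two fixed-effect coefficients from
#' [fit_mixed_model()], using the fitted covariance of the estimates.
#'
#' @param effects A `predictor_group_effects`.
#' @param a,b Group names; the contrast is `a - b` (either may be the
#'   reference group, whose coefficient is 0).
#' @param alternative `"greater"` (one-sided, a > b), `"less"` or
#'   `"two.sided"`.
#' @return List with `difference`, `se`, `z` and `p_value`.
#' @export
compare_groups <- function(effects, a, b, alternative = c("greater", "less",
                                                          "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(effects, "predictor_group_effects"))
  V <- as.matrix(stats::vcov(effects$model))
  fe <- lme4::fixef(effects$model)
  wt <- function(g) {
    if (g == effects$reference) return(numeric(length(fe)))
    term <- paste0("group", g)
    if (!term %in% names(fe)) stop("no coefficient for group '", g, "'",
                                   call. = FALSE)
    as.numeric(names(fe) == term)
  }
  w <- wt(a) - wt(b)
  diff <- sum(w * fe)
  se <- sqrt(drop(t(w) %*% V %*% w))
  z <- diff / se
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  list(difference = diff, se = se, z = z, p_value = p)
}

#' Stack a per-species metric onto the coarse grid
#'
#' Assigns each species' scalar metric to every cell of its range, stacks all
#' ranges, and averages per cell. Cells covered by no species are absent from
#' the result (not zero).
#'
#' @param values Named numeric vector, one value per species id.
#' @param species A list of [species_occurrence()] or an `sdm_community`.
#' @return A data.frame (`geo_metric_map`): `cell_id`, `value` (mean over
#'   covering species), `n_species`.
#' @export
stack_metric <- function(values, species) {
  if (inherits(species, "sdm_community")) species <- species$species
  ids <- vapply(species, `[[`, character(1), "species_id")
  cells <- integer(0); vals <- numeric(0)
  for (nm in names(values)) {
    idx <- match(nm, ids)
    s <- if (is.na(idx)) NULL else species[[idx]]
    if (is.null(s) || !length(s$presence_cells)) {
      warning("species '", nm, "' has a metric value but no range cells; skipped",
              call. = FALSE)
      next
    }
    cells <- c(cells, s$presence_cells)
    vals <- c(vals, rep(values[[nm]], length(s$presence_cells)))
  }
  if (!length(cells))
    return(data.frame(cell_id = integer(0), value = numeric(0),
                      n_species = integer(0)))
  mean_v <- tapply(vals, cells, mean)
  n_sp <- tapply(vals, cells, length)
  out <- data.frame(cell_id = as.integer(names(mean_v)),
                    value = as.vector(mean_v),
                    n_species = as.integer(n_sp))
  out[order(out$cell_id), ]
}

#' Pairwise per-species performance difference, stacked geographically
#'
#' For each species, the metric is averaged over repeats per algorithm, the
#' difference `groupA - groupB` is taken per algorithm, and the per-algorithm
#' differences are averaged; the per-species deltas are then stacked over the
#' species' ranges with [stack_metric()]. Species missing either group are
#' excluded (count reported in the result).
#'
#' @param records Evaluation records.
#' @param species A list of [species_occurrence()] or an `sdm_community`.
#' @param pair Character vector `c(groupA, groupB)`.
#' @param metric `"tss"` or `"auc"`.
#' @return List with `map` (stacked data.frame as in [stack_metric()]),
#'   `per_species` (named vector of deltas) and `n_excluded`.
#' @export
delta_maps <- function(records, species, pair = c("temporal", "mean"),
                       metric = c("tss", "auc")) {
  metric <- match.arg(metric)
  stopifnot(length(pair) == 2)
  agg <- .aggregate_records(records, metric)
  agg <- agg[agg$group %in% pair, , drop = FALSE]
  deltas <- c(); n_excluded <- 0L
  for (sp in unique(agg$species_id)) {
    d_alg <- c()
    for (al in unique(agg$algorithm[agg$species_id == sp])) {
      va <- agg$value[agg$species_id == sp & agg$algorithm == al &
                        agg$group == pair[1]]
      vb <- agg$value[agg$species_id == sp & agg$algorithm == al &
                        agg$group == pair[2]]
      if (length(va) == 1 && length(vb) == 1) d_alg <- c(d_alg, va - vb)
    }
    if (length(d_alg)) deltas[sp] <- mean(d_alg)
    else n_excluded <- n_excluded + 1L
  }
  list(map = stack_metric(deltas, species), per_species = deltas,
       n_excluded = n_excluded)
}

#' Latitudinal profile of a stacked metric
#'
#' Groups the cell values of a stacked map into latitudinal bands of
#' `band_width` degrees (nominal latitude of each cell's row) and reports the
#' per-band mean and sample SD. Bands containing no cells are absent; a band
#' with one cell has `sd = NA`.
#'
#' @param map A stacked map from [stack_metric()] or `delta_maps()$map`.
#' @param config A [world_config()].
#' @param band_width Band width in degrees (default 1).
#' @return A data.frame: `lat_band` (band centre), `mean`, `sd`, `n_cells`.
#' @export
latitudinal_profile <- function(map, config, band_width = 1) {
  g <- cell_grid(config)
  lat <- g$lat[match(map$cell_id, g$cell_id)]
  band <- floor(lat / band_width) * band_width + band_width / 2
  mean_v <- tapply(map$value, band, mean)
  sd_v <- tapply(map$value, band, function(v) if (length(v) > 1) stats::sd(v) else NA_real_)
  n <- tapply(map$value, band, length)
  data.frame(lat_band = as.numeric(names(mean_v)),
             mean = as.vector(mean_v), sd = as.vector(sd_v),
             n_cells = as.integer(n), row.names = NULL)
}

#' Observed vs predicted range size: mean squared deviation
#'
#' For each species, an SDM is refit on the full buffered dataset, occurrence
#' probabilities are predicted for every domain cell, and the predicted range
#' size is the number of cells at or above the species' threshold (the
#' TSS-optimized threshold averaged over that species' evaluation repeats for
#' the same algorithm and group). The observed range size is the number of
#' presence cells. MSD is the mean over species of the squared difference.
#'
#' @param community An `sdm_community` or list of [species_occurrence()].
#' @param predictors A [predictor_table()].
#' @param records Evaluation records providing the thresholds.
#' @param config A [world_config()].
#' @param group Predictor group to refit.
#' @param algorithm Algorithm to refit.
#' @param buffer_km Buffer distance in km.
#' @param seed RNG seed (random forest refits).
#' @param min_cells Skip species below this range size.
#' @param control An [sdm_control()].
#' @return List with `msd` and `per_species` (data.frame `species_id`,
#'   `observed`, `predicted`, `threshold`); species whose refit fails are
#'   excluded and counted in `n_failed`.
#' @export
range_size_msd <- function(community, predictors, records, config,
                           group = "mean", algorithm = "GLM",
                           buffer_km = 3000, seed = 1, min_cells = 72,
                           control = sdm_control()) {
  if (inherits(community, "sdm_community")) community <- community$species
  rec <- records[records$group == group & records$algorithm == algorithm &
                   !is.na(records$threshold), , drop = FALSE]
  thr_by_sp <- tapply(rec$threshold, rec$species_id, mean)
  rows <- list(); n_failed <- 0L
  for (s in community) {
    if (!is.na(s$excluded) || length(s$presence_cells) < min_cells) next
    thr <- thr_by_sp[[s$species_id]]
    if (is.null(thr) || is.na(thr)) next
    res <- tryCatch({
      ds <- build_dataset(s, predictors, group, config, buffer_km = buffer_km)
      fit <- fit_sdm(ds, algorithm, seed = seed, control = control)
      p <- predict(fit, ds$x)
      data.frame(species_id = s$species_id,
                 observed = length(s$presence_cells),
                 predicted = sum(p >= thr), threshold = thr)
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else rows[[s$species_id]] <- res
  }
  per_species <- do.call(rbind, rows)
  if (is.null(per_species))
    return(list(msd = NA_real_, per_species = NULL, n_failed = n_failed))
  rownames(per_species) <- NULL
  list(msd = mean((per_species$predicted - per_species$observed)^2),
       per_species = per_species, n_failed = n_failed)
}
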