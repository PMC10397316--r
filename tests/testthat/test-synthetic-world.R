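# Synthetic world generator: climate cubes and virtual species.

test_that("world_config validates its inputs", {
  expect_error(world_config(n_coarse_rows = 0), "n_coarse_rows")
  expect_error(world_config(n_years = 0), "n_years")
  expect_error(world_config(cell_size_km = -1), "cell_size_km")
  expect_error(world_config(anomaly_sd_range = c(2, 1)), "anomaly_sd_range")
})

test_that("climate generation is deterministic given the config seed", {
  cfg <- world_config(n_coarse_rows = 6, n_coarse_cols = 6,
                      fine_per_coarse = 3, n_years = 5, seed = 11)
  c1 <- generate_climate(cfg)
  c2 <- generate_climate(cfg)
  expect_identical(c1$temperature, c2$temperature)
  expect_identical(c1$precipitation, c2$precipitation)
  expect_identical(c1$elevation, c2$elevation)
  c3 <- generate_climate(world_config(n_coarse_rows = 6, n_coarse_cols = 6,
                                      fine_per_coarse = 3, n_years = 5,
                                      seed = 12))
  expect_false(identical(c1$temperature, c3$temperature))
})

test_that("precipitation is strictly positive and shapes are consistent", {
  expect_true(all(fx_cube$precipitation > 0))
  expect_identical(dim(fx_cube$temperature), dim(fx_cube$precipitation))
  expect_identical(dim(fx_cube$elevation), dim(fx_cube$temperature)[2:3])
})

test_that("zero injected anomaly yields zero interannual temperature SD", {
  cfg <- world_config(n_coarse_rows = 5, n_coarse_cols = 5,
                      fine_per_coarse = 3, n_years = 8, seed = 3,
                      anomaly_sd_range = c(0, 0))
  tv <- temporal_variability(generate_climate(cfg))
  expect_equal(tv$temporal_sd_temp, rep(0, 25), tolerance = 1e-12)
})

test_that("flat terrain leaves only the latitudinal gradient in spatial SD", {
  cfg <- world_config(n_coarse_rows = 4, n_coarse_cols = 4,
                      fine_per_coarse = 4, n_years = 3, seed = 5,
                      relief_m = 0, anomaly_sd_range = c(0, 0))
  cube <- generate_climate(cfg)
  ssd <- spatial_sd(cube)
  # oracle: fine-row temperatures repeat across the f columns of a coarse cell
  f <- cfg$fine_per_coarse
  FR <- cfg$n_coarse_rows * f
  lat_fine <- cfg$lat_range[1] + (seq_len(FR) - 0.5) / FR * diff(cfg$lat_range)
  t_fine <- cfg$temp_equator - cfg$temp_lat_gradient * lat_fine -
    cfg$lapse_rate * cfg$base_elev_m / 1000
  for (r in seq_len(cfg$n_coarse_rows)) {
    vals <- rep(t_fine[((r - 1) * f + 1):(r * f)], times = f)
    expect_equal(ssd$spatial_sd_temp[ssd$cell_id ==
                                       (r - 1) * cfg$n_coarse_cols + 1],
                 sd(vals), tolerance = 1e-10)
  }
  # and with the gradient removed too, spatial SD is exactly zero
  cfg0 <- world_config(n_coarse_rows = 4, n_coarse_cols = 4,
                       fine_per_coarse = 4, n_years = 3, seed = 5,
                       relief_m = 0, temp_lat_gradient = 0,
                       anomaly_sd_range = c(0, 0))
  ssd0 <- spatial_sd(generate_climate(cfg0))
  expect_equal(ssd0$spatial_sd_temp, rep(0, 16), tolerance = 1e-12)
})

test_that("interannual temperature variability increases polewards", {
  tv <- merge(temporal_variability(fx_cube), cell_grid(fx_config),
              by = "cell_id")
  polar <- mean(tv$temporal_sd_temp[tv$row == fx_config$n_coarse_rows])
  equatorial <- mean(tv$temporal_sd_temp[tv$row == 1])
  expect_gt(polar, equatorial)
})

test_that("the mountain block carries high sub-grid relief", {
  ssd <- merge(spatial_sd(fx_cube), cell_grid(fx_config), by = "cell_id")
  mrows <- ceiling(fx_config$mountain_rows * fx_config$n_coarse_rows)
  mcols <- ceiling(fx_config$mountain_cols * fx_config$n_coarse_cols)
  inblock <- ssd$row >= mrows[1] & ssd$row <= mrows[2] &
    ssd$col >= mcols[1] & ssd$col <= mcols[2]
  expect_gt(min(ssd$spatial_sd_temp[inblock]),
            max(ssd$spatial_sd_temp[!inblock]))
})

test_that("coarse-scale temporal SD recovers the injected anomaly SD", {
  tv <- temporal_variability(fx_cube)
  truth <- as.vector(t(fx_cube$anomaly_sd))  # anomaly_sd is [row, col]
  se <- truth / sqrt(2 * (fx_config$n_years - 1))
  frac <- mean(abs(tv$temporal_sd_temp - truth) <= 3 * se)
  expect_gte(frac, 0.95)
})

test_that("niche_spec enforces archetype-axis consistency", {
  expect_error(
    niche_spec("mean_only", c(mean_temp = 10, temporal_sd_temp = 1),
               c(mean_temp = 2, temporal_sd_temp = 0.5)),
    "inconsistent")
  expect_error(
    niche_spec("temporal_sensitive", c(mean_temp = 10, mean_prec = 800),
               c(mean_temp = 2, mean_prec = 100)),
    "inconsistent")
  expect_error(
    niche_spec("mean_only", c(mean_temp = 10, mean_prec = 800),
               c(mean_temp = 0, mean_prec = 100)),
    "breadths")
  expect_s3_class(
    niche_spec("temporal_sensitive",
               c(mean_temp = 10, mean_prec = 800, temporal_sd_temp = 1),
               c(mean_temp = 2, mean_prec = 100, temporal_sd_temp = 0.5)),
    "niche_spec")
})

test_that("zero occupancy cutoff without cohesion occupies every cell", {
  niche <- niche_spec("mean_only",
                      c(mean_temp = 0, mean_prec = 800),
                      c(mean_temp = 1, mean_prec = 10),
                      occupancy_cutoff = 0, cohesion = FALSE)
  sp <- generate_species(fx_predictors, niche, min_cells = 1)
  expect_identical(sp$presence_cells, fx_predictors$cell_id)
})

test_that("a narrow mean-temperature niche stays near its optimum", {
  mu <- max(fx_predictors$mean_temp)
  sigma <- sd(fx_predictors$mean_temp) / 4
  niche <- niche_spec("mean_only",
                      c(mean_temp = mu, mean_prec = median(fx_predictors$mean_prec)),
                      c(mean_temp = sigma, mean_prec = 1e6),
                      occupancy_cutoff = 0.2, cohesion = FALSE)
  sp <- generate_species(fx_predictors, niche, min_cells = 1, max_attempts = 1)
  temps <- fx_predictors$mean_temp[match(sp$presence_cells,
                                         fx_predictors$cell_id)]
  expect_true(all(abs(temps - mu) <= 3 * sigma))
})

test_that("undersized ranges are relaxed and finally flagged too_few_cells", {
  # a narrow niche cannot reach 72 cells even after relaxation ...
  niche <- niche_spec("mean_only",
                      c(mean_temp = median(fx_predictors$mean_temp),
                        mean_prec = median(fx_predictors$mean_prec)),
                      c(mean_temp = sd(fx_predictors$mean_temp) / 8,
                        mean_prec = sd(fx_predictors$mean_prec) / 8),
                      occupancy_cutoff = 0.9, cohesion = FALSE)
  sp <- generate_species(fx_predictors, niche, min_cells = 72)
  expect_lt(length(sp$presence_cells), 72)
  expect_identical(sp$excluded, "too_few_cells")
  # ... but clears a permissive minimum without being flagged, at a cutoff
  # no lower than the relaxation schedule allows
  sp2 <- generate_species(fx_predictors, niche, min_cells = 1)
  expect_true(is.na(sp2$excluded))
  expect_gte(sp2$cutoff_used, 0.9 * 0.7^4 - 1e-12)
})

test_that("cohesive ranges form exactly one 4-connected component", {
  com <- generate_community(fx_predictors, c(mean_only = 4, mixed = 4),
                            seed = 5, min_cells = 20)
  for (sp in com$species) {
    if (!is.na(sp$excluded)) next
    expect_identical(n_components_igraph(sp$presence_cells, fx_config), 1L)
  }
})

test_that("community generation is deterministic and manifest-complete", {
  n <- c(mean_only = 3, spatial_sensitive = 3, temporal_sensitive = 3,
         mixed = 3)
  c1 <- generate_community(fx_predictors, n, seed = 9, min_cells = 20)
  c2 <- generate_community(fx_predictors, n, seed = 9, min_cells = 20)
  expect_identical(lapply(c1$species, `[[`, "presence_cells"),
                   lapply(c2$species, `[[`, "presence_cells"))
  expect_identical(nrow(c1$manifest), 12L)
  expect_setequal(unique(c1$manifest$archetype), names(n))
  ok <- is.na(c1$manifest$excluded)
  expect_true(all(c1$manifest$n_cells[ok] >= 20))
  # empty request yields an empty community
  c0 <- generate_community(fx_predictors, c(mean_only = 0), seed = 1)
  expect_length(c0$species, 0)
  expect_identical(nrow(c0$manifest), 0L)
})
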