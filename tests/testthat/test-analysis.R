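# Mixed-model comparison of predictor groups and geographic synthesis.

test_that("mixed model recovers known group effects within 3 SE", {
  rec <- simulate_eval_records(n_species = 120, seed = 41)
  eff <- suppressWarnings(fit_mixed_model(rec, "tss"))
  truth <- c("spatial" = 0.03, "temporal" = 0.09, "sp-temp" = 0.09)
  for (g in names(truth)) {
    row <- eff$coefficients[eff$coefficients$group == g, ]
    expect_lt(abs(row$estimate - truth[[g]]), 3 * row$se)
  }
  expect_identical(eff$coefficients$estimate[eff$coefficients$group == "mean"],
                   0)
  expect_true(all(eff$varcomp$sd >= 0))
})

test_that("identical responses give zero coefficients and variance", {
  rec <- simulate_eval_records(n_species = 20, species_sd = 0,
                               algorithm_sd = 0, residual_sd = 0,
                               group_offsets = c("mean" = 0, "spatial" = 0,
                                                 "temporal" = 0),
                               seed = 42)
  eff <- suppressWarnings(fit_mixed_model(rec, "tss"))
  expect_equal(eff$coefficients$estimate, rep(0, 3), tolerance = 1e-10)
  expect_equal(eff$varcomp$sd, rep(0, nrow(eff$varcomp)), tolerance = 1e-8)
})

test_that("with one algorithm the coefficient is the paired mean difference", {
  rec <- simulate_eval_records(n_species = 50, algorithms = "GLM",
                               group_offsets = c("mean" = 0, "temporal" = 0.08),
                               species_sd = 0.05, algorithm_sd = 0,
                               residual_sd = 0.02, seed = 43)
  eff <- suppressWarnings(fit_mixed_model(rec, "tss"))
  agg <- aggregate(tss ~ species_id + group, rec, mean)
  wide <- reshape(agg, idvar = "species_id", timevar = "group",
                  direction = "wide")
  paired <- mean(wide$tss.temporal - wide$tss.mean)
  est <- eff$coefficients$estimate[eff$coefficients$group == "temporal"]
  expect_equal(est, paired, tolerance = 1e-3)
})

test_that("group contrasts use the fitted covariance", {
  rec <- simulate_eval_records(n_species = 80, seed = 44)
  eff <- suppressWarnings(fit_mixed_model(rec, "tss"))
  cmp <- compare_groups(eff, "temporal", "spatial")
  expect_equal(cmp$difference,
               eff$coefficients$estimate[eff$coefficients$group == "temporal"] -
                 eff$coefficients$estimate[eff$coefficients$group == "spatial"],
               tolerance = 1e-10)
  expect_lt(cmp$p_value, 0.05)  # 0.06 offset at this design is detectable
  cmp2 <- compare_groups(eff, "spatial", "temporal")
  expect_equal(cmp2$difference, -cmp$difference, tolerance = 1e-12)
  # contrast against the reference group equals the coefficient itself
  cmp3 <- compare_groups(eff, "temporal", "mean")
  expect_equal(cmp3$difference,
               eff$coefficients$estimate[eff$coefficients$group == "temporal"],
               tolerance = 1e-12)
})

test_that("stacking averages species metrics per covered cell", {
  spA <- species_occurrence("A", c(1L, 2L))
  spB <- species_occurrence("B", c(2L, 3L))
  map <- stack_metric(c(A = 0.6), list(spA, spB))
  expect_identical(map$cell_id, c(1L, 2L))
  expect_equal(map$value, c(0.6, 0.6), tolerance = 1e-12)
  map2 <- stack_metric(c(A = 0.4, B = 0.8), list(spA, spB))
  expect_equal(map2$value[map2$cell_id == 2], 0.6, tolerance = 1e-12)
  expect_identical(map2$n_species, c(1L, 2L, 1L))
  # bounded by the min/max of contributing values
  expect_true(all(map2$value >= 0.4 & map2$value <= 0.8))
  # empty input and unknown species
  expect_identical(nrow(stack_metric(numeric(0), list(spA))), 0L)
  expect_warning(stack_metric(c(Z = 0.5), list(spA)), "no range cells")
})

test_that("delta maps are pairwise, averaged per algorithm, antisymmetric", {
  rec <- rbind(
    data.frame(species_id = "A", algorithm = "GLM", group = "temporal",
               rep = 1:2, tss = c(0.8, 0.8), auc = 0.9),
    data.frame(species_id = "A", algorithm = "GLM", group = "mean",
               rep = 1:2, tss = c(0.7, 0.7), auc = 0.85),
    data.frame(species_id = "A", algorithm = "RF", group = "temporal",
               rep = 1:2, tss = c(0.9, 0.9), auc = 0.9),
    data.frame(species_id = "A", algorithm = "RF", group = "mean",
               rep = 1:2, tss = c(0.6, 0.6), auc = 0.85))
  spA <- species_occurrence("A", c(4L, 5L))
  dm <- delta_maps(rec, list(spA), pair = c("temporal", "mean"))
  # per-algorithm deltas 0.1 and 0.3, averaged to 0.2, over the range
  expect_equal(unname(dm$per_species["A"]), 0.2, tolerance = 1e-12)
  expect_equal(dm$map$value, c(0.2, 0.2), tolerance = 1e-12)
  rev <- delta_maps(rec, list(spA), pair = c("mean", "temporal"))
  expect_equal(rev$map$value, -dm$map$value, tolerance = 1e-12)
  # identical pair gives a zero map
  same <- delta_maps(rec, list(spA), pair = c("mean", "mean"))
  expect_equal(same$map$value, c(0, 0), tolerance = 1e-12)
  # species missing one group are excluded and counted
  rec_b <- rec[rec$group == "temporal", ]
  rec_b$species_id <- "B"
  dm2 <- delta_maps(rbind(rec, rec_b), list(spA, species_occurrence("B", 9L)),
                    pair = c("temporal", "mean"))
  expect_identical(dm2$n_excluded, 1L)
})

test_that("latitudinal profiles bin stacked values by nominal latitude", {
  g <- cell_grid(fx_config)
  # constant map: every band mean equals the constant, SD 0
  map <- data.frame(cell_id = g$cell_id, value = 0.25,
                    n_species = 1L)
  prof <- latitudinal_profile(map, fx_config, band_width = 10)
  expect_true(all(abs(prof$mean - 0.25) < 1e-12))
  expect_true(all(prof$sd == 0))
  expect_identical(sum(prof$n_cells), nrow(g))
  # two disjoint bands with distinct values
  cells_low <- g$cell_id[g$row == 1]
  cells_high <- g$cell_id[g$row == fx_config$n_coarse_rows]
  map2 <- data.frame(cell_id = c(cells_low, cells_high),
                     value = rep(c(0.1, 0.3),
                                 c(length(cells_low), length(cells_high))),
                     n_species = 1L)
  prof2 <- latitudinal_profile(map2, fx_config, band_width = 5)
  expect_equal(min(prof2$mean), 0.1, tolerance = 1e-12)
  expect_equal(max(prof2$mean), 0.3, tolerance = 1e-12)
  # a band holding a single cell has undefined (missing) SD
  map3 <- data.frame(cell_id = g$cell_id[1], value = 0.5, n_species = 1L)
  prof3 <- latitudinal_profile(map3, fx_config, band_width = 1)
  expect_identical(nrow(prof3), 1L)
  expect_true(is.na(prof3$sd))
})

test_that("range-size deviation compares observed and predicted pixel counts", {
  com <- generate_community(fx_predictors, c(mean_only = 3), seed = 45,
                            min_cells = 20)
  rec <- evaluate_community(com, fx_predictors, fx_config, groups = "mean",
                            algorithms = "GLM", n_repeats = 3, seed = 6,
                            min_cells = 20)
  res <- range_size_msd(com, fx_predictors, rec, fx_config, group = "mean",
                        algorithm = "GLM", min_cells = 20)
  ps <- res$per_species
  expect_gt(nrow(ps), 0)
  # observed sizes match the ranges; MSD matches its own definition
  sizes <- vapply(com$species, function(s) length(s$presence_cells),
                  integer(1))
  expect_identical(ps$observed,
                   unname(sizes[match(ps$species_id, names(sizes))]))
  expect_equal(res$msd, mean((ps$predicted - ps$observed)^2),
               tolerance = 1e-12)
  # a reasonable model lands in the right order of magnitude
  expect_true(all(ps$predicted > 0))
  # invariance to species ordering
  res2 <- range_size_msd(rev(com$species), fx_predictors, rec, fx_config,
                         group = "mean", algorithm = "GLM", min_cells = 20)
  expect_equal(res2$msd, res$msd, tolerance = 1e-12)
})
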