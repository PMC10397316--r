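# End-to-end synthetic experiment and a record-level simulator for
# mixed-model calibration checks.

#' Run the full synthetic variability experiment
#'
#' Generates a climate cube, aggregates it to the predictor table, samples a
#' community of virtual species, and evaluates every (species x predictor
#' group x algorithm) combination by repeated split-sampling. This is the
#' one-call analog of the full pipeline: climate, ranges, SDMs, evaluation.
#'
#' @param config A [world_config()] (its seed drives the world).
#' @param n_per_archetype Passed to [generate_community()].
#' @param groups,algorithms,buffer_km,n_repeats,threshold_on,control Passed to
#'   [evaluate_community()].
#' @param seed Seed for community sampling and evaluation splits.
#' @param ... Further arguments to [generate_community()] (niche breadths,
#'   cutoff, ...).
#' @return List with `config`, `predictors`, `community` and `records`.
#' @export
run_variability_experiment <- function(config = world_config(),
                                       n_per_archetype = c(mean_only = 10,
                                                           temporal_sensitive = 10),
                                       groups = c("mean", "spatial", "temporal"),
                                       algorithms = c("GLM", "RF"),
                                       buffer_km = 3000, n_repeats = 10,
                                       seed = 1, threshold_on = "test",
                                       control = sdm_control(), ...) {
  cube <- generate_climate(config)
  predictors <- predictor_table(cube)
  community <- generate_community(predictors, n_per_archetype, seed = seed, ...)
  records <- evaluate_community(community, predictors, config,
                                groups = groups, algorithms = algorithms,
                                buffer_km = buffer_km, n_repeats = n_repeats,
                                seed = seed, threshold_on = threshold_on,
                                control = control)
  list(config = config, predictors = predictors, community = community,
       records = records)
}

#' Simulate evaluation records with known effect structure
#'
#' Draws performance records from the generative model that
#' [fit_mixed_model()] assumes: `value = baseline + group offset + species
#' intercept + algorithm intercept + residual`, with Gaussian random effects.
#' Used for parameter-recovery and interval-calibration checks of the mixed
#' model.
#'
#' @param n_species Number of species.
#' @param algorithms Algorithm labels.
#' @param group_offsets Named numeric vector of fixed group effects; the first
#'   element is the reference and should be 0.
#' @param species_sd,algorithm_sd,residual_sd Random-effect and residual SDs.
#' @param baseline Grand mean of the response.
#' @param n_repeats Repeats per combination (residual noise is drawn per
#'   repeat).
#' @param seed Integer seed.
#' @return A data.frame shaped like [evaluate_community()] output, with the
#'   simulated metric in both `tss` and `auc` columns.
#' @export
simulate_eval_records <- function(n_species = 200,
                                  algorithms = c("GLM", "GAM", "RF"),
                                  group_offsets = c("mean" = 0,
                                                    "spatial" = 0.03,
                                                    "temporal" = 0.09,
                                                    "sp-temp" = 0.09),
                                  species_sd = 0.05, algorithm_sd = 0.02,
                                  residual_sd = 0.01, baseline = 0.7,
                                  n_repeats = 1, seed = 1) {
  set.seed(seed)
  sp_ids <- sprintf("sim_sp_%03d", seq_len(n_species))
  sp_eff <- stats::rnorm(n_species, sd = species_sd)
  alg_eff <- stats::rnorm(length(algorithms), sd = algorithm_sd)
  grid <- expand.grid(species_id = sp_ids, algorithm = algorithms,
                      group = names(group_offsets), rep = seq_len(n_repeats),
                      stringsAsFactors = FALSE)
  mu <- baseline + group_offsets[grid$group] +
    sp_eff[match(grid$species_id, sp_ids)] +
    alg_eff[match(grid$algorithm, algorithms)]
  value <- mu + stats::rnorm(nrow(grid), sd = residual_sd)
  data.frame(species_id = grid$species_id, algorithm = grid$algorithm,
             group = grid$group, rep = grid$rep,
             tss = value, auc = value, threshold = NA_real_,
             n_train = NA_integer_, n_test = NA_integer_,
             error = NA_character_, stringsAsFactors = FALSE)
}
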