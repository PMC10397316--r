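# Shared fixtures: a small synthetic world and hand-built climate cubes.
# Everything is generated in code; nothing is read from disk.

# small world used across test files (cached once per test run)
fx_config <- world_config(n_coarse_rows = 12, n_coarse_cols = 12,
                          fine_per_coarse = 4, n_years = 35, seed = 42)
fx_cube <- generate_climate(fx_config)
fx_predictors <- predictor_table(fx_cube)

# hand-built cube: one coarse cell, explicit per-year fine-cell values.
# `temp_years` / `prec_years` are lists of f x f matrices, one per year.
manual_cube <- function(temp_years, prec_years = NULL, cell_size_km = 50) {
  f <- nrow(temp_years[[1]])
  Y <- length(temp_years)
  if (is.null(prec_years))
    prec_years <- replicate(Y, matrix(500, f, f), simplify = FALSE)
  cfg <- world_config(n_coarse_rows = 1, n_coarse_cols = 1,
                      fine_per_coarse = f, n_years = Y,
                      cell_size_km = cell_size_km, seed = 1)
  tarr <- array(0, dim = c(Y, f, f))
  parr <- array(0, dim = c(Y, f, f))
  for (y in seq_len(Y)) {
    tarr[y, , ] <- temp_years[[y]]
    parr[y, , ] <- prec_years[[y]]
  }
  climate_cube(tarr, parr, matrix(0, f, f), cfg)
}

# a presence/absence toy dataset wrapped as a modeling_dataset
toy_dataset <- function(x, labels, species_id = "toy", group = "mean") {
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  structure(list(species_id = species_id, group = group,
                 cell_ids = seq_along(labels), labels = labels,
                 weights = compute_weights(labels), x = x),
            class = "modeling_dataset")
}

# brute-force O(n^2) AUC: pair counting with ties = 1/2
auc_bruteforce <- function(labels, scores) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) tot <- tot + sum(a > s0) + 0.5 * sum(a == s0)
  tot / (length(s1) * length(s0))
}

# TSS of predictions scores >= thr against labels
tss_at <- function(labels, scores, thr) {
  pred <- as.integer(scores >= thr)
  tss(tp = sum(pred == 1 & labels == 1), fn = sum(pred == 0 & labels == 1),
      tn = sum(pred == 0 & labels == 0), fp = sum(pred == 1 & labels == 0))
}

# number of 4-connected components of a cell set (independent of the
# package's flood fill: igraph on the lattice adjacency)
n_components_igraph <- function(cells, config) {
  if (length(cells) <= 1) return(length(cells))
  C <- config$n_coarse_cols
  r <- (cells - 1) %/% C + 1; cc <- (cells - 1) %% C + 1
  edges <- integer(0)
  for (i in seq_along(cells)) {
    for (j in seq_along(cells)) {
      if (i < j && abs(r[i] - r[j]) + abs(cc[i] - cc[j]) == 1)
        edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(cells), directed = FALSE)
  as.integer(igraph::components(g)$no)
}
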