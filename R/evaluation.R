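# Repeated stratified split-sample evaluation with TSS and AUC.

#' True Skill Statistic from a confusion matrix
#'
#' `TSS = sensitivity + specificity - 1 = tp/(tp+fn) + tn/(tn+fp) - 1`,
#' in `[-1, 1]` and insensitive to prevalence.
#'
#' @param tp,fn,tn,fp Confusion-matrix counts (presence = positive class).
#' @return TSS value.
#' @export
tss <- function(tp, fn, tn, fp) {
  if (any(c(tp, fn, tn, fp) < 0)) stop("counts must be >= 0", call. = FALSE)
  if (tp + fn == 0 || tn + fp == 0)
    stop("TSS undefined: one class has no observations", call. = FALSE)
  tp / (tp + fn) + tn / (tn + fp) - 1
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen presence
#' receives a higher score than a randomly chosen absence, with ties counted
#' one half. Equals the trapezoidal area under the ROC curve. Invariant to
#' strictly increasing transforms of the scores.
#'
#' @param labels 0/1 vector (1 = presence).
#' @param scores Numeric scores, same length.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' TSS-optimizing threshold
#'
#' Evaluates TSS at every candidate threshold -- the unique score values plus
#' 0 and 1, with predicted presence meaning `score >= threshold` -- and
#' returns the maximizer (ties broken by the smallest threshold). This is the
#' exact optimum over all thresholds, since TSS only changes at observed
#' score values.
#'
#' @param labels 0/1 vector (1 = presence).
#' @param scores Numeric scores, same length.
#' @return List with `threshold` and `tss` (TSS at that threshold).
#' @export
optimize_threshold <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  cand <- sort(unique(c(0, scores, 1)))
  s1 <- sort(scores[labels == 1]); s0 <- sort(scores[labels == 0])
  # tp(t) = #(presence scores >= t); fp(t) = #(absence scores >= t)
  tp <- n1 - findInterval(cand, s1, left.open = TRUE)
  fp <- n0 - findInterval(cand, s0, left.open = TRUE)
  tssv <- tp / n1 + (n0 - fp) / n0 - 1
  best <- max(tssv)
  i <- which(tssv >= best - 1e-12)[1]
  list(threshold = cand[i], tss = tssv[i])
}

#' Repeated stratified train/test splits
#'
#' Presences and absences are partitioned independently (stratified) so every
#' repeat's test fraction has the same prevalence as the full dataset. The
#' test side gets `floor((1 - train_frac) * n)` observations per class,
#' guarded to at least 1. Deterministic given `seed`.
#'
#' @param labels 0/1 vector (1 = presence); at least 5 per class.
#' @param n_repeats Number of repeats (default 30).
#' @param train_frac Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return An object of class `split_plan`: a list of `n_repeats` elements,
#'   each with integer index vectors `train` and `test` into `labels`.
#' @export
make_splits <- function(labels, n_repeats = 30, train_frac = 0.8, seed = 1) {
  idx1 <- which(labels == 1); idx0 <- which(labels == 0)
  if (length(idx1) < 5 || length(idx0) < 5)
    stop("need at least 5 presences and 5 absences to split", call. = FALSE)
  if (train_frac <= 0 || train_frac >= 1)
    stop("'train_frac' must be in (0, 1)", call. = FALSE)
  set.seed(seed)
  nt1 <- max(1L, floor((1 - train_frac) * length(idx1) + 1e-9))
  nt0 <- max(1L, floor((1 - train_frac) * length(idx0) + 1e-9))
  plan <- lapply(seq_len(n_repeats), function(r) {
    t1 <- sample(idx1, nt1); t0 <- sample(idx0, nt0)
    test <- sort(c(t1, t0))
    list(train = setdiff(seq_along(labels), test), test = test)
  })
  structure(plan, class = "split_plan", n_repeats = n_repeats,
            train_frac = train_frac, seed = seed)
}

.empty_record <- function(species_id, algorithm, group, rep, n_train, n_test,
                          reason) {
  data.frame(species_id = species_id, algorithm = algorithm, group = group,
             rep = rep, tss = NA_real_, auc = NA_real_,
             threshold = NA_real_, n_train = n_train, n_test = n_test,
             error = reason, stringsAsFactors = FALSE)
}

#' Evaluate SDM algorithms on one dataset by repeated split-sampling
#'
#' For every repeat of the split plan: fit on the training side (weights
#' rebalanced on the training labels), score the test side, record AUC of the
#' raw scores and TSS at a TSS-optimized threshold. The threshold is selected
#' on the test scores by default (`threshold_on = "train"` selects it on
#' training scores and applies it to the test side). Fit failures are
#' recorded as missing rows with a reason, never silently dropped.
#'
#' @param dataset A [build_dataset()] result.
#' @param algorithms Character vector among `"GLM"`, `"GAM"`, `"RF"`.
#' @param splits A [make_splits()] plan for `dataset$labels` (built with
#'   defaults when `NULL`).
#' @param n_repeats,seed Used to build the plan when `splits` is `NULL`; the
#'   seed also drives the random forest (offset per repeat).
#' @param threshold_on `"test"` or `"train"`.
#' @param control An [sdm_control()].
#' @return A data.frame of evaluation records: one row per algorithm x repeat
#'   with `species_id`, `algorithm`, `group`, `rep`, `tss`, `auc`,
#'   `threshold`, `n_train`, `n_test`, `error`.
#' @export
evaluate_dataset <- function(dataset, algorithms = c("GLM", "GAM", "RF"),
                             splits = NULL, n_repeats = 30, seed = 1,
                             threshold_on = c("test", "train"),
                             control = sdm_control()) {
  threshold_on <- match.arg(threshold_on)
  if (is.null(splits))
    splits <- make_splits(dataset$labels, n_repeats = n_repeats, seed = seed)
  out <- vector("list", length(algorithms) * length(splits))
  k <- 0
  for (alg in algorithms) {
    for (r in seq_along(splits)) {
      k <- k + 1
      tr <- splits[[r]]$train; te <- splits[[r]]$test
      train <- structure(list(
        species_id = dataset$species_id, group = dataset$group,
        cell_ids = dataset$cell_ids[tr], labels = dataset$labels[tr],
        weights = compute_weights(dataset$labels[tr]),
        x = dataset$x[tr, , drop = FALSE]), class = "modeling_dataset")
      rec <- tryCatch({
        fit <- fit_sdm(train, alg, seed = seed + r, control = control)
        sc_te <- predict(fit, dataset$x[te, , drop = FALSE])
        y_te <- dataset$labels[te]
        thr <- if (threshold_on == "test") {
          optimize_threshold(y_te, sc_te)$threshold
        } else {
          optimize_threshold(train$labels, predict(fit, train$x))$threshold
        }
        pred <- as.integer(sc_te >= thr)
        data.frame(species_id = dataset$species_id, algorithm = alg,
                   group = dataset$group, rep = r,
                   tss = tss(tp = sum(pred == 1 & y_te == 1),
                             fn = sum(pred == 0 & y_te == 1),
                             tn = sum(pred == 0 & y_te == 0),
                             fp = sum(pred == 1 & y_te == 0)),
                   auc = auc(y_te, sc_te), threshold = thr,
                   n_train = length(tr), n_test = length(te),
                   error = NA_character_, stringsAsFactors = FALSE)
      }, error = function(e) {
        .empty_record(dataset$species_id, alg, dataset$group, r,
                      length(tr), length(te), conditionMessage(e))
      })
      out[[k]] <- rec
    }
  }
  do.call(rbind, out)
}

#' Evaluate a community of species across predictor groups and algorithms
#'
#' Builds, for every non-excluded species, one dataset per predictor group
#' (sharing the species' buffered domain and split plan across groups and
#' algorithms, so comparisons are paired) and runs [evaluate_dataset()].
#'
#' @param community An `sdm_community` (or list of [species_occurrence()]).
#' @param predictors A [predictor_table()].
#' @param config A [world_config()].
#' @param groups Predictor group names (default all four).
#' @param algorithms Algorithms to fit (default all three).
#' @param buffer_km Buffer distance in km.
#' @param n_repeats Split repeats per combination (default 30).
#' @param seed Base seed; each species gets a derived split seed.
#' @param min_cells Minimum range size; smaller species are skipped (they are
#'   flagged, not modelled).
#' @param threshold_on,control Passed to [evaluate_dataset()].
#' @return A tidy data.frame of evaluation records (one row per species x
#'   algorithm x group x repeat).
#' @export
evaluate_community <- function(community, predictors, config,
                               groups = names(predictor_groups()),
                               algorithms = c("GLM", "GAM", "RF"),
                               buffer_km = 3000, n_repeats = 30, seed = 1,
                               min_cells = 72,
                               threshold_on = "test",
                               control = sdm_control()) {
  flt <- apply_minimum_size_filter(community, min_cells = min_cells)
  out <- list()
  for (i in seq_along(flt$kept)) {
    sp <- flt$kept[[i]]
    sp_seed <- seed + 7919L * i
    splits <- NULL
    for (grp in groups) {
      ds <- build_dataset(sp, predictors, grp, config, buffer_km = buffer_km)
      if (is.null(splits))
        splits <- make_splits(ds$labels, n_repeats = n_repeats, seed = sp_seed)
      out[[paste(sp$species_id, grp)]] <- evaluate_dataset(
        ds, algorithms = algorithms, splits = splits, seed = sp_seed,
        threshold_on = threshold_on, control = control)
    }
  }
  if (!length(out)) {
    return(.empty_record(character(0), character(0), character(0), integer(0),
                         integer(0), integer(0), character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
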