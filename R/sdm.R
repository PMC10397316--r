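# The three SDM algorithms.
#
# All algorithms consume a modeling_dataset and return a `fitted_sdm` whose
# predict method yields occurrence probabilities in [0, 1]. Predictors are
# z-scored on the training data inside the fit (means/scales stored on the
# model) so quadratic terms stay well conditioned across climate units;
# constant columns are dropped with a warning.
#
#   GLM : weighted logistic regression with linear + quadratic terms, fitted
#         by iteratively reweighted least squares with a tiny ridge penalty
#         (default 1e-6, intercept unpenalized) so complete separation --
#         common for sharply delimited virtual species -- stays finite.
#   GAM : binomial additive model with one thin-plate-spline smooth per
#         predictor, basis dimension k = 5 (an upper limit of 4 effective
#         degrees of freedom per smooth), via mgcv.
#   RF  : classification random forest (1500 trees by default) in which every
#         tree is grown on a subsample with equal numbers of presences and
#         absences (per-class size = the minority class count, drawn with
#         replacement within class by default).
#
# GLM and GAM use the class-balancing observation weights; the RF balances
# classes through its per-tree subsampling instead, so it takes no weights.

#' SDM algorithm settings
#'
#' @param glm_ridge Ridge penalty on GLM coefficients (intercept excluded).
#' @param gam_k Basis dimension of each thin-plate-spline smooth (upper limit
#'   of `gam_k - 1` degrees of freedom per smooth).
#' @param rf_trees Number of random-forest trees.
#' @param rf_replace Draw per-tree class subsamples with replacement?
#' @return A list of class `sdm_control`.
#' @export
sdm_control <- function(glm_ridge = 1e-6, gam_k = 5, rf_trees = 1500,
                        rf_replace = TRUE) {
  stopifnot(glm_ridge >= 0, gam_k >= 2, rf_trees >= 1)
  structure(list(glm_ridge = glm_ridge, gam_k = gam_k,
                 rf_trees = rf_trees, rf_replace = rf_replace),
            class = "sdm_control")
}

# z-score columns on training data (weighted moments, so reweighting schemes
# that preserve the weighted distribution leave fits unchanged); drop
# constant columns with a warning
.standardize_train <- function(x, species_id = "?", weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(x))
  wn <- weights / sum(weights)
  centre <- colSums(x * wn)
  scale <- sqrt(colSums(sweep(x, 2, centre)^2 * wn))
  keep <- scale > 0
  if (!all(keep))
    warning("dropping constant predictor column(s) for '", species_id, "': ",
            paste(colnames(x)[!keep], collapse = ", "), call. = FALSE)
  if (!any(keep))
    stop("all predictor columns constant for '", species_id, "'", call. = FALSE)
  x <- x[, keep, drop = FALSE]
  z <- sweep(sweep(x, 2, centre[keep]), 2, scale[keep], `/`)
  list(z = z, centre = centre[keep], scale = scale[keep],
       columns = colnames(x))
}

.apply_standardize <- function(fitted, newdata) {
  miss <- setdiff(fitted$columns, colnames(newdata))
  if (length(miss))
    stop("prediction matrix lacks training column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  x <- as.matrix(newdata[, fitted$columns, drop = FALSE])
  sweep(sweep(x, 2, fitted$centre), 2, fitted$scale, `/`)
}

# weighted ridge-penalized logistic regression (IRLS with step halving);
# the intercept is unpenalized. Returns the coefficient vector for cbind(1, X).
.ridge_logistic <- function(X, y, w, ridge = 1e-6, max_iter = 100,
                            tol = 1e-10) {
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(ridge, p - 1)), p)
  pdev <- function(beta) {
    eta <- pmin(pmax(drop(Xd %*% beta), -30), 30)
    mu <- stats::plogis(eta)
    -2 * sum(w * (y * log(pmax(mu, 1e-12)) +
                    (1 - y) * log(pmax(1 - mu, 1e-12)))) +
      ridge * sum(beta[-1]^2)
  }
  beta <- numeric(p)
  pbar <- stats::weighted.mean(y, w)
  beta[1] <- stats::qlogis(min(max(pbar, 1e-6), 1 - 1e-6))
  dev <- pdev(beta)
  for (iter in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(Xd %*% beta), -30), 30)
    mu <- stats::plogis(eta)
    wirls <- pmax(w * mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / pmax(mu * (1 - mu), 1e-10)
    xtw <- crossprod(Xd, Xd * wirls) + pen
    beta_new <- tryCatch(
      drop(solve(xtw, crossprod(Xd, wirls * z))),
      error = function(e) stop("GLM failed to converge (singular system)",
                               call. = FALSE))
    # step-halve towards the current iterate until the penalized deviance
    # does not increase (guards against IRLS divergence under separation)
    dev_new <- pdev(beta_new)
    half <- 0
    while (dev_new > dev + 1e-8 && half < 30) {
      beta_new <- (beta_new + beta) / 2
      dev_new <- pdev(beta_new)
      half <- half + 1
    }
    converged <- abs(dev - dev_new) < tol * (abs(dev_new) + 1)
    beta <- beta_new
    dev <- dev_new
    if (converged) break
  }
  list(beta = beta, deviance = dev - ridge * sum(beta[-1]^2))
}

# expand z-scored matrix with quadratic terms
.quad_expand <- function(z) {
  q <- z^2
  colnames(q) <- paste0(colnames(z), "^2")
  cbind(z, q)
}

#' Fit an SDM
#'
#' Dispatches to [fit_sdm_glm()], [fit_sdm_gam()] or [fit_sdm_rf()].
#'
#' @param dataset A [build_dataset()] result.
#' @param algorithm `"GLM"`, `"GAM"` or `"RF"`.
#' @param seed RNG seed (used by the random forest only).
#' @param control An [sdm_control()].
#' @return A `fitted_sdm` object; see [predict.fitted_sdm()].
#' @export
fit_sdm <- function(dataset, algorithm = c("GLM", "GAM", "RF"), seed = 1,
                    control = sdm_control()) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
         GLM = fit_sdm_glm(dataset, control = control),
         GAM = fit_sdm_gam(dataset, control = control),
         RF = fit_sdm_rf(dataset, seed = seed, control = control))
}

.check_classes <- function(dataset) {
  if (sum(dataset$labels == 1) == 0 || sum(dataset$labels == 0) == 0)
    stop("dataset for '", dataset$species_id,
         "' must contain both presences and absences", call. = FALSE)
}

#' @rdname fit_sdm
#' @export
fit_sdm_glm <- function(dataset, control = sdm_control()) {
  .check_classes(dataset)
  st <- .standardize_train(dataset$x, dataset$species_id, dataset$weights)
  X <- .quad_expand(st$z)
  fit <- tryCatch(
    .ridge_logistic(X, dataset$labels, dataset$weights,
                    ridge = control$glm_ridge),
    error = function(e) stop("GLM fit failed for species '",
                             dataset$species_id, "', group '", dataset$group,
                             "': ", conditionMessage(e), call. = FALSE))
  structure(list(algorithm = "GLM", beta = fit$beta, deviance = fit$deviance,
                 columns = st$columns, centre = st$centre, scale = st$scale,
                 control = control),
            class = "fitted_sdm")
}

#' @rdname fit_sdm
#' @export
fit_sdm_gam <- function(dataset, control = sdm_control()) {
  .check_classes(dataset)
  st <- .standardize_train(dataset$x, dataset$species_id, dataset$weights)
  df <- as.data.frame(st$z)
  df$.y <- dataset$labels
  terms <- vapply(colnames(st$z), function(cn) {
    k <- min(control$gam_k, length(unique(st$z[, cn])))
    if (k >= 3) sprintf("s(%s, k = %d, bs = \"tp\")", cn, k) else cn
  }, character(1))
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(mgcv::gam(fml, family = stats::binomial(),
                               weights = dataset$weights, data = df,
                               method = "REML")),
    error = function(e) stop("GAM fit failed for species '",
                             dataset$species_id, "', group '", dataset$group,
                             "': ", conditionMessage(e), call. = FALSE))
  structure(list(algorithm = "GAM", model = fit,
                 columns = st$columns, centre = st$centre, scale = st$scale,
                 control = control),
            class = "fitted_sdm")
}

#' @rdname fit_sdm
#' @export
fit_sdm_rf <- function(dataset, seed = 1, control = sdm_control()) {
  .check_classes(dataset)
  st <- .standardize_train(dataset$x, dataset$species_id)
  y <- factor(dataset$labels, levels = c("0", "1"))
  m <- min(table(y))
  if (m < 2)
    stop("random forest needs at least 2 cells in each class for species '",
         dataset$species_id, "'", call. = FALSE)
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = st$z, y = y, ntree = control$rf_trees,
    strata = y, sampsize = c(m, m), replace = control$rf_replace,
    keep.inbag = TRUE)
  structure(list(algorithm = "RF", model = fit, seed = seed,
                 columns = st$columns, centre = st$centre, scale = st$scale,
                 control = control),
            class = "fitted_sdm")
}

#' Predict occurrence probabilities from a fitted SDM
#'
#' @param object A `fitted_sdm`.
#' @param newdata Matrix or data.frame containing the training predictor
#'   columns (by name); extra columns are ignored.
#' @param ... Unused.
#' @return Probabilities in `[0, 1]`, one per row of `newdata` (vote fractions
#'   for the random forest).
#' @export
predict.fitted_sdm <- function(object, newdata, ...) {
  if (NROW(newdata) == 0) return(numeric(0))
  z <- .apply_standardize(object, newdata)
  switch(object$algorithm,
    GLM = {
      X <- cbind(1, .quad_expand(z))
      stats::plogis(pmin(pmax(drop(X %*% object$beta), -30), 30))
    },
    GAM = {
      as.vector(mgcv::predict.gam(object$model, newdata = as.data.frame(z),
                                  type = "response"))
    },
    RF = {
      unname(stats::predict(object$model, newdata = z, type = "prob")[, "1"])
    })
}

#' @export
print.fitted_sdm <- function(x, ...) {
  cat("<fitted_sdm> ", x$algorithm, " on ", length(x$columns),
      " predictor(s): ", paste(x$columns, collapse = ", "), "\n", sep = "")
  invisible(x)
}
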