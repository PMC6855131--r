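# The four classifier families. Ridge and lasso logistic regression are
# backed by glmnet with the penalty chosen by internal 5-fold CV on the
# training rows; random forests and gradient boosting run on the package's
# own tree engine (src/trees.cpp) since no tree-learning package is
# assumed at run time.

#' Specify a classifier
#'
#' @param family One of `"ridge"`, `"lasso"`, `"random_forest"`,
#'   `"gradient_boosting"`.
#' @param seed Integer seed for every stochastic step (internal CV fold
#'   draws, bootstraps, feature subsampling).
#' @param ... Family-specific hyperparameters overriding the defaults:
#'   ridge/lasso: `internal_folds` (5), `lambda` (optional fixed penalty
#'   bypassing internal CV); random_forest: `n_trees` (1000), `mtry`
#'   (default `floor(sqrt(n_voxels))`), `min_node` (1); gradient_boosting:
#'   `depth_grid` (1:3), `shrinkage_grid` (c(0.1, 0.01)), `n_trees_max`
#'   (500), `internal_folds` (5), `min_node` (10).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("ridge", "lasso", "random_forest",
                                       "gradient_boosting"),
                            seed = 1L, ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    ridge = list(alpha = 0, internal_folds = 5L, lambda = NULL),
    lasso = list(alpha = 1, internal_folds = 5L, lambda = NULL),
    random_forest = list(n_trees = 1000L, mtry = NULL, min_node = 1L),
    gradient_boosting = list(depth_grid = 1:3, shrinkage_grid = c(0.1, 0.01),
                             n_trees_max = 500L, internal_folds = 5L,
                             min_node = 10L))
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop_mmfuse(paste0("unknown hyperparameters for ", family, ": ",
                       paste(unknown, collapse = ", ")), "mmfuse_config_error")
  hp <- utils::modifyList(defaults, override)
  structure(c(list(family = family, seed = as.integer(seed)), hp),
            class = "classifier_spec")
}

col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  sqrt(pmax(colSums(x^2) - n * mu^2, 0) / (n - 1))
}

check_training_classes <- function(y) {
  if (length(unique(y)) < 2)
    stop_mmfuse("training fold contains a single class", "mmfuse_single_class_error")
}

#' Fit one classifier on a training fold
#'
#' @param x Training feature matrix (subjects x voxels), already
#'   residualized and standardized by the caller.
#' @param y Binary training labels (1 = patient).
#' @param spec A [classifier_spec()].
#' @return A fitted classifier (class `mmfuse_fit`) exposing per-voxel
#'   scores via [classifier_scores()] and probabilities via
#'   [predict_prob()].
#' @export
fit_classifier <- function(x, y, spec) {
  x <- as.matrix(x)
  y <- as.integer(y)
  check_training_classes(y)
  fit <- switch(spec$family,
    ridge = ,
    lasso = fit_glmnet_family(x, y, spec),
    random_forest = fit_rf(x, y, spec),
    gradient_boosting = fit_gbm(x, y, spec))
  structure(c(fit, list(family = spec$family, spec = spec, n_voxels = ncol(x))),
            class = "mmfuse_fit")
}

fit_glmnet_family <- function(x, y, spec) {
  if (all(col_sds(x) == 0)) {
    # glmnet cannot fit when every predictor is constant; the correct
    # limiting model is intercept-only
    return(list(model = NULL, intercept_only = TRUE, prob = mean(y),
                n_coef = ncol(x)))
  }
  padded <- FALSE
  if (ncol(x) < 2) {             # glmnet requires >= 2 columns
    x <- cbind(x, pad__ = 0)
    padded <- TRUE
  }
  if (!is.null(spec$lambda)) {
    model <- glmnet::glmnet(x, y, family = "binomial", alpha = spec$alpha,
                            lambda = spec$lambda, standardize = FALSE)
    lambda <- spec$lambda
  } else {
    set.seed(spec$seed)
    foldid <- sample(rep_len(seq_len(spec$internal_folds), length(y)))
    model <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = spec$alpha,
                               foldid = foldid, standardize = FALSE,
                               type.measure = "deviance")
    lambda <- model$lambda.min
  }
  list(model = model, lambda = lambda, padded = padded)
}

fit_rf <- function(x, y, spec) {
  mtry <- spec$mtry %||% max(1L, floor(sqrt(ncol(x))))
  set.seed(spec$seed)
  rf <- rf_fit_cpp(x, as.double(y), as.integer(spec$n_trees),
                   as.integer(mtry), as.integer(spec$min_node), 0L)
  list(model = rf, mtry = mtry)
}

fit_gbm <- function(x, y, spec) {
  grid <- expand.grid(depth = spec$depth_grid, shrinkage = spec$shrinkage_grid)
  n <- length(y)
  set.seed(spec$seed)
  foldid <- sample(rep_len(seq_len(spec$internal_folds), n))
  # guard: every internal training part must contain both classes
  for (k in seq_len(spec$internal_folds)) check_training_classes(y[foldid != k])
  best <- list(deviance = Inf)
  for (g in seq_len(nrow(grid))) {
    dev <- matrix(0, nrow = spec$n_trees_max, ncol = 1)
    for (k in seq_len(spec$internal_folds)) {
      tr <- foldid != k
      fit_k <- gbm_fit_cpp(x[tr, , drop = FALSE], as.double(y[tr]),
                           as.integer(spec$n_trees_max), grid$depth[g],
                           grid$shrinkage[g], as.integer(spec$min_node))
      link <- gbm_staged_link_cpp(fit_k$trees, fit_k$f0, fit_k$shrinkage,
                                  x[!tr, , drop = FALSE])
      p <- pmin(pmax(1 / (1 + exp(-link)), 1e-12), 1 - 1e-12)
      yk <- y[!tr]
      dev <- dev - 2 * colSums(yk * log(p) + (1 - yk) * log(1 - p))
    }
    stage <- which.min(dev)
    if (dev[stage] < best$deviance)
      best <- list(deviance = dev[stage], depth = grid$depth[g],
                   shrinkage = grid$shrinkage[g], n_trees = stage)
  }
  model <- gbm_fit_cpp(x, as.double(y), as.integer(best$n_trees),
                       best$depth, best$shrinkage, as.integer(spec$min_node))
  list(model = model, depth = best$depth, shrinkage = best$shrinkage,
       n_trees = best$n_trees)
}

#' Predict patient-class probabilities from a fitted classifier
#'
#' @param fit An `mmfuse_fit`.
#' @param x Feature matrix preprocessed identically to training.
#' @return Probabilities in `[0, 1]`, one per row of `x`.
#' @export
predict_prob <- function(fit, x) {
  x <- as.matrix(x)
  if (ncol(x) != fit$n_voxels)
    stop_mmfuse("feature count does not match the fitted model",
                "mmfuse_incompatible_data_error")
  switch(fit$family,
    ridge = ,
    lasso = {
      if (isTRUE(fit$intercept_only)) return(rep(fit$prob, nrow(x)))
      if (isTRUE(fit$padded)) x <- cbind(x, pad__ = 0)
      as.numeric(stats::predict(fit$model, newx = x, s = fit$lambda,
                                type = "response"))
    },
    random_forest = as.numeric(forest_vote_cpp(fit$model$trees, x)),
    gradient_boosting = {
      link <- gbm_link_cpp(fit$model$trees, fit$model$f0,
                           fit$model$shrinkage, x, length(fit$model$trees))
      1 / (1 + exp(-as.numeric(link)))
    })
}

#' Per-voxel relevance scores of a fitted classifier
#'
#' Ridge/lasso expose logistic regression coefficients (at the selected
#' penalty); random forests expose mean-decrease-in-impurity importances;
#' gradient boosting exposes total split gain.
#'
#' @param fit An `mmfuse_fit`.
#' @return Numeric vector, one score per voxel.
#' @export
classifier_scores <- function(fit) {
  switch(fit$family,
    ridge = ,
    lasso = {
      if (isTRUE(fit$intercept_only)) return(rep(0, fit$n_coef))
      cf <- as.numeric(stats::coef(fit$model, s = fit$lambda))[-1]  # drop intercept
      if (isTRUE(fit$padded)) cf <- cf[-length(cf)]
      cf
    },
    random_forest = ,
    gradient_boosting = as.numeric(fit$model$importance))
}
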