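# Strategy 1: post-classification integration. The five unimodal outcome
# probabilities of a test subject are combined by (a) their mean, (b) the
# most confident modality, or (c) a logistic model on the log-odds of the
# training subjects' in-sample unimodal probabilities.

check_probs <- function(probs) {
  if (anyNA(probs))
    stop_mmfuse("missing modality probability (no silent imputation)",
                "mmfuse_argument_error")
  if (any(probs < 0 | probs > 1))
    stop_mmfuse("probabilities must be in [0,1]", "mmfuse_argument_error")
}

#' Mean-probability fusion
#'
#' @param probs Per-modality patient probabilities for one subject.
#' @return List with `prob` (arithmetic mean) and `label`
#'   (1 iff `prob > 0.5`; a tie predicts control).
#' @export
fuse_mean <- function(probs) {
  check_probs(probs)
  p <- mean(probs)
  list(prob = p, label = as.integer(p > 0.5))
}

#' Most-confident-modality fusion
#'
#' Selects the modality whose probability is furthest from 0.5 (the
#' "maximum probability" rule read as maximum confidence, since the raw
#' maximum of patient probabilities would be trivially patient-biased) and
#' returns that modality's probability and implied label. Confidence ties
#' are broken by modality order.
#'
#' @inheritParams fuse_mean
#' @return List with `prob`, `label` and `which` (index of the modality
#'   used).
#' @export
fuse_max <- function(probs) {
  check_probs(probs)
  i <- which.max(abs(probs - 0.5))  # which.max takes the first on ties
  list(prob = probs[[i]], label = as.integer(probs[[i]] > 0.5), which = i)
}

#' Fit a logistic stacking model on training probabilities
#'
#' Predictors are `log(p/(1-p))` of the unimodal probabilities (computed on
#' the training subjects by their own fold models), clipped to
#' `[eps, 1-eps]`; the response is the diagnosis. Under perfect separation
#' the maximum-likelihood fit is replaced by a ridge-stabilized logistic
#' fit with a warning.
#'
#' @param train_probs Matrix (training subjects x modalities) of in-sample
#'   unimodal probabilities.
#' @param train_labels Binary labels.
#' @param eps Clipping bound in `(0, 0.5)`, default `1e-6`.
#' @return A `stack_model` with `intercept`, per-modality `coef`, `eps`.
#' @export
fit_stack <- function(train_probs, train_labels, eps = 1e-6) {
  train_probs <- as.matrix(train_probs)
  if (eps <= 0 || eps >= 0.5)
    stop_mmfuse("eps must be in (0, 0.5)", "mmfuse_argument_error")
  z <- stats::qlogis(pmin(pmax(train_probs, eps), 1 - eps))
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, z), train_labels, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # fitted probabilities numerically at 0/1 or non-convergence mean
  # separation in practice even when glm.fit does not emit its warning
  eps_fit <- 1e-8
  separated <- separated || !isTRUE(fit$converged) ||
    any(fit$fitted.values > 1 - eps_fit | fit$fitted.values < eps_fit)
  if (separated) {
    warning("separation in stacking model; using ridge-stabilized fit")
    zr <- if (ncol(z) < 2) cbind(z, 0) else z
    rfit <- glmnet::glmnet(zr, train_labels, family = "binomial", alpha = 0,
                           lambda = 0.01, standardize = FALSE)
    cf <- as.numeric(stats::coef(rfit))
    coefs <- cf[-1][seq_len(ncol(z))]
    intercept <- cf[1]
  } else {
    coefs <- fit$coefficients[-1]
    intercept <- fit$coefficients[1]
  }
  coefs[is.na(coefs)] <- 0
  structure(list(intercept = unname(intercept), coef = unname(coefs),
                 eps = eps, stabilized = separated),
            class = "stack_model")
}

#' Predict from a logistic stacking model
#'
#' @param model A `stack_model`.
#' @param probs Per-modality probabilities, one subject per row (a vector is
#'   treated as a single subject).
#' @return List with `prob` and `label` vectors.
#' @export
predict_stack <- function(model, probs) {
  probs <- if (is.matrix(probs)) probs else matrix(probs, nrow = 1)
  if (ncol(probs) != length(model$coef))
    stop_mmfuse("modality count does not match stacking model",
                "mmfuse_incompatible_data_error")
  z <- stats::qlogis(pmin(pmax(probs, model$eps), 1 - model$eps))
  eta <- model$intercept + as.numeric(z %*% model$coef)
  p <- stats::plogis(eta)
  list(prob = p, label = as.integer(p > 0.5))
}

#' Cross-validated probability-level fusion
#'
#' Per fold, fits the unimodal pipeline (confounds, standardization,
#' classifier) for every modality, then combines the test probabilities by
#' the mean rule, the most-confident rule, and logistic stacking trained on
#' the fold's in-sample training probabilities. The fold plan is the same
#' object used by the unimodal analyses.
#'
#' @param cohort A `multimodal_cohort`.
#' @param spec A [classifier_spec()] (one family fused across modalities).
#' @param foldplan A [make_folds()] plan.
#' @param modalities Modalities to fuse (default: all in the cohort).
#' @param eps Stacking clipping bound.
#' @return A `prediction_table` with sources `fusion_mean`, `fusion_max`,
#'   `fusion_logistic`.
#' @export
cross_validate_fusion <- function(cohort, spec, foldplan,
                                  modalities = names(cohort$data), eps = 1e-6) {
  check_foldplan(cohort, foldplan)
  tables <- lapply(seq_len(foldplan$n_folds), function(k) {
    train <- foldplan$assignment != k
    test <- which(!train)
    fold_models <- lapply(modalities, function(mod)
      fit_unimodal_fold(cohort$data[[mod]], cohort$age, cohort$sex,
                        cohort$labels, train, spec,
                        derive_seed(spec$seed, "unimodal", mod, spec$family, k)))
    names(fold_models) <- modalities
    test_probs <- vapply(modalities, function(mod)
      predict_unimodal_fold(fold_models[[mod]], cohort$data[[mod]],
                            cohort$age, cohort$sex, test),
      numeric(length(test)))
    train_probs <- vapply(modalities, function(mod)
      fold_models[[mod]]$train_probs, numeric(sum(train)))
    test_probs <- matrix(test_probs, ncol = length(modalities))
    train_probs <- matrix(train_probs, ncol = length(modalities))

    mean_p <- apply(test_probs, 1, function(p) fuse_mean(p)$prob)
    max_p <- apply(test_probs, 1, function(p) fuse_max(p)$prob)
    stack <- fit_stack(train_probs, cohort$labels[train], eps)
    stack_p <- predict_stack(stack, test_probs)$prob

    truth <- cohort$labels[test]
    ids <- cohort$subject_id[test]
    bind_predictions(
      new_prediction_table(ids, k, "fusion_mean", spec$family, mean_p, truth),
      new_prediction_table(ids, k, "fusion_max", spec$family, max_p, truth),
      new_prediction_table(ids, k, "fusion_logistic", spec$family, stack_p, truth))
  })
  do.call(bind_predictions, tables)
}
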