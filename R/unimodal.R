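# Cross-validated unimodal classification. Inside every fold: fit age/sex
# confound models on the training rows, residualize train and test,
# standardize features by training mean/SD, fit the classifier, score the
# test rows. Every subject receives exactly one test prediction per
# (source, algorithm).

preprocess_fit <- function(train_x, age, sex) {
  conf <- fit_confounds(train_x, age, sex)
  res <- remove_confounds(conf, train_x, age, sex)
  center <- colMeans(res)
  scl <- apply(res, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(confounds = conf, center = center, scale = scl)
}

preprocess_apply <- function(prep, x, age, sex) {
  res <- remove_confounds(prep$confounds, x, age, sex)
  sweep(sweep(res, 2, prep$center), 2, prep$scale, "/")
}

# Fit one fold of one modality: preprocessing + classifier + in-sample
# training probabilities (needed by the logistic stacking strategy).
fit_unimodal_fold <- function(x, age, sex, y, train, spec, seed) {
  prep <- preprocess_fit(x[train, , drop = FALSE], age[train], sex[train])
  xs_train <- preprocess_apply(prep, x[train, , drop = FALSE], age[train], sex[train])
  sp <- spec
  sp$seed <- seed
  fit <- fit_classifier(xs_train, y[train], sp)
  list(prep = prep, fit = fit,
       train_probs = predict_prob(fit, xs_train))
}

predict_unimodal_fold <- function(fold_model, x, age, sex, rows) {
  xs <- preprocess_apply(fold_model$prep, x[rows, , drop = FALSE],
                         age[rows], sex[rows])
  predict_prob(fold_model$fit, xs)
}

#' Fit a classifier on training rows and score test rows
#'
#' Bare train/predict step (no confound or standardization preprocessing;
#' use [cross_validate_unimodal()] for the full per-fold pipeline).
#'
#' @param train_x,train_y Training features and binary labels.
#' @param test_x Test features with matching columns.
#' @param spec A [classifier_spec()].
#' @return Patient-class probability per test row.
#' @export
fit_predict_fold <- function(train_x, train_y, test_x, spec) {
  fit <- fit_classifier(train_x, train_y, spec)
  predict_prob(fit, test_x)
}

new_prediction_table <- function(subject, fold, source, algorithm, prob, truth) {
  predicted <- as.integer(prob > 0.5)  # tie at exactly 0.5 -> control
  structure(data.frame(subject = subject, fold = fold, source = source,
                       algorithm = algorithm, prob_patient = prob,
                       predicted = predicted, truth = as.integer(truth),
                       correct = as.integer(predicted == truth),
                       stringsAsFactors = FALSE),
            class = c("prediction_table", "data.frame"))
}

#' Combine prediction tables
#' @param ... `prediction_table` objects.
#' @return A single `prediction_table`.
#' @export
bind_predictions <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("prediction_table", "data.frame")
  out
}

check_foldplan <- function(cohort, foldplan) {
  if (length(foldplan$assignment) != n_subjects(cohort))
    stop_mmfuse("fold plan does not match cohort size", "mmfuse_config_error")
}

#' Cross-validated unimodal classification
#'
#' @param cohort A `multimodal_cohort`.
#' @param modality Modality name present in the cohort.
#' @param spec A [classifier_spec()].
#' @param foldplan A [make_folds()] plan for the cohort's subjects.
#' @return A `prediction_table` with one test prediction per subject
#'   (`source` = modality, `algorithm` = classifier family).
#' @export
cross_validate_unimodal <- function(cohort, modality, spec, foldplan) {
  if (!modality %in% names(cohort$data))
    stop_mmfuse(paste0("modality not in cohort: ", modality), "mmfuse_config_error")
  check_foldplan(cohort, foldplan)
  x <- cohort$data[[modality]]
  tables <- lapply(seq_len(foldplan$n_folds), function(k) {
    train <- foldplan$assignment != k
    test <- which(!train)
    fm <- fit_unimodal_fold(x, cohort$age, cohort$sex, cohort$labels, train,
                            spec, derive_seed(spec$seed, "unimodal", modality,
                                              spec$family, k))
    probs <- predict_unimodal_fold(fm, x, cohort$age, cohort$sex, test)
    new_prediction_table(cohort$subject_id[test], k, modality, spec$family,
                         probs, cohort$labels[test])
  })
  do.call(bind_predictions, tables)
}

#' Accuracy summary with bootstrap confidence interval
#'
#' Mean accuracy is the fraction of correctly classified subjects pooled
#' over all folds; the 95% interval is the percentile interval over
#' `n_boot` subject-level resamples; per-fold minimum and maximum
#' accuracies are also reported. Summaries are computed per
#' (source, algorithm) group in the table.
#'
#' @param table A `prediction_table`.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @return Data frame with columns `source`, `algorithm`, `n`, `accuracy`,
#'   `ci_lower`, `ci_upper`, `fold_min`, `fold_max`.
#' @export
accuracy_summary <- function(table, n_boot = 1000, seed = 1L) {
  if (nrow(table) == 0) stop_mmfuse("empty prediction table", "mmfuse_argument_error")
  groups <- split(as.data.frame(table), list(table$source, table$algorithm),
                  drop = TRUE)
  out <- lapply(groups, function(g) {
    correct <- g$correct
    n <- length(correct)
    set.seed(derive_seed(seed, "bootstrap", g$source[1], g$algorithm[1]))
    boot <- replicate(n_boot, mean(correct[sample.int(n, n, replace = TRUE)]))
    ci <- unname(stats::quantile(boot, c(0.025, 0.975), type = 7))
    fold_acc <- tapply(correct, g$fold, mean)
    data.frame(source = g$source[1], algorithm = g$algorithm[1], n = n,
               accuracy = mean(correct), ci_lower = ci[1], ci_upper = ci[2],
               fold_min = min(fold_acc), fold_max = max(fold_acc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write / read a prediction table as CSV
#'
#' Column schema: `subject, fold, source, algorithm, prob_patient,
#' predicted, truth, correct`.
#'
#' @param table A `prediction_table`.
#' @param path CSV path.
#' @return `path` (write) or a `prediction_table` (read).
#' @export
write_prediction_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prediction_table
#' @export
read_prediction_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("prediction_table", "data.frame")
  out
}
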