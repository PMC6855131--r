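# Cross-validation engine, prediction tables and accuracy summaries.

test_that("every subject gets exactly one test prediction per run", {
  co <- small_cohort(seed = 2, n_voxels = 60, signal = 12)
  fp <- make_folds(co$labels, 5, seed = 1)
  tab <- cross_validate_unimodal(co, "A", classifier_spec("ridge", seed = 4), fp)
  expect_s3_class(tab, "prediction_table")
  expect_equal(sort(tab$subject), sort(co$subject_id))
  expect_equal(nrow(tab), n_subjects(co))
  expect_true(all(tab$prob_patient >= 0 & tab$prob_patient <= 1))
  expect_equal(tab$correct, as.integer(tab$predicted == tab$truth))
})

test_that("all-zero features yield the training patient fraction", {
  co <- small_cohort(seed = 5, n_voxels = 20, signal = 4)
  for (mod in names(co$data)) co$data[[mod]][] <- 0
  co$age <- rep(40, n_subjects(co)) + rnorm(n_subjects(co), 0, 1)
  fp <- make_folds(co$labels, 4, seed = 2)
  tab <- cross_validate_unimodal(co, "A", classifier_spec("ridge", seed = 1), fp)
  for (k in 1:4) {
    train_frac <- mean(co$labels[fp$assignment != k])
    got <- tab$prob_patient[tab$fold == k]
    expect_equal(got, rep(train_frac, length(got)), tolerance = 1e-6)
  }
  # accuracy equals the majority-class rate
  expect_equal(mean(tab$correct), mean(co$labels == 0))
})

test_that("noiseless separable cohorts reach accuracy 1", {
  co <- generate_cohort(cohort_spec(
    n_controls = 20, n_patients = 16, n_voxels = 30,
    modality_names = c("A", "B"), signal_count = 10, effect_size = 5,
    pairwise_shared_fraction = matrix(c(1, 0, 0, 1), 2),
    noise_sd = 0.01, age_slope = 0, sex_offset = 0, seed = 3))
  fp <- make_folds(co$labels, 4, seed = 5)
  tab <- cross_validate_unimodal(co, "A", classifier_spec("ridge", seed = 1), fp)
  expect_equal(mean(tab$correct), 1)
})

test_that("strong signal at realistic scale is recovered well above chance", {
  co <- generate_cohort(cohort_spec(
    n_voxels = 1000, modality_names = "M", signal_count = 100,
    effect_size = 1.2, pairwise_shared_fraction = matrix(1, 1, 1), seed = 31))
  fp <- make_folds(co$labels, 5, seed = 8)
  tab <- cross_validate_unimodal(co, "M", classifier_spec("ridge", seed = 9), fp)
  expect_gt(mean(tab$correct), 0.75)
})

test_that("runs are reproducible and blind to test-set information", {
  co <- small_cohort(seed = 6, n_voxels = 50, signal = 10)
  fp <- make_folds(co$labels, 5, seed = 3)
  spec <- classifier_spec("ridge", seed = 12)
  t1 <- cross_validate_unimodal(co, "A", spec, fp)
  t2 <- cross_validate_unimodal(co, "A", spec, fp)
  expect_identical(t1, t2)

  # leakage canary: perturbing a fold's test rows never changes that fold's
  # training-derived quantities (confound model, penalty, training probs)
  test_rows <- which(fp$assignment == 2)
  train <- fp$assignment != 2
  x_pert <- co$data$A
  x_pert[test_rows, ] <- x_pert[test_rows, ] * 3 + 7
  seed_k <- derive_seed(spec$seed, "unimodal", "A", spec$family, 2)
  fm1 <- mmfuse:::fit_unimodal_fold(co$data$A, co$age, co$sex, co$labels,
                                    train, spec, seed_k)
  fm2 <- mmfuse:::fit_unimodal_fold(x_pert, co$age, co$sex, co$labels,
                                    train, spec, seed_k)
  expect_identical(fm1$prep, fm2$prep)
  expect_identical(fm1$fit$lambda, fm2$fit$lambda)
  expect_identical(fm1$train_probs, fm2$train_probs)
  expect_identical(classifier_scores(fm1$fit), classifier_scores(fm2$fit))

  # shuffled test labels change `correct` but never `prob_patient`
  co_shuf <- co
  co_shuf$labels[test_rows] <- rev(co_shuf$labels[test_rows])
  fp_same <- fp  # keep the identical partition
  t4 <- cross_validate_unimodal(co_shuf, "A", spec, fp_same)
  expect_identical(t1$prob_patient[t1$fold == 2], t4$prob_patient[t4$fold == 2])
})

test_that("accuracy_summary arithmetic and bootstrap determinism", {
  tab <- new_prediction_table_for_test(rep(c(1L, 0L), c(150, 61)))
  s <- accuracy_summary(tab, n_boot = 300, seed = 4)
  expect_equal(s$accuracy, 150 / 211, tolerance = 1e-12)
  expect_equal(s$n, 211)
  s2 <- accuracy_summary(tab, n_boot = 300, seed = 4)
  expect_identical(s, s2)
  expect_true(s$ci_lower <= s$accuracy && s$accuracy <= s$ci_upper)

  all_right <- new_prediction_table_for_test(rep(1L, 50))
  sa <- accuracy_summary(all_right, n_boot = 100, seed = 1)
  expect_equal(c(sa$accuracy, sa$ci_lower, sa$ci_upper, sa$fold_min, sa$fold_max),
               rep(1, 5))
  expect_error(accuracy_summary(all_right[0, ]), class = "mmfuse_argument_error")
})

test_that("prediction tables round-trip through CSV", {
  co <- small_cohort(seed = 8, n_voxels = 30, signal = 6)
  fp <- make_folds(co$labels, 4, seed = 1)
  tab <- cross_validate_unimodal(co, "B", classifier_spec("ridge", seed = 2), fp)
  p <- tempfile(fileext = ".csv")
  write_prediction_table(tab, p)
  back <- read_prediction_table(p)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
})
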