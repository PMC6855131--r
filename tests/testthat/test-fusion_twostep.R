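# Two-step sequential integration: selection rules, overlap statistics,
# merged refits.

fake_fit <- function(scores, family = "random_forest") {
  structure(list(family = family, model = list(importance = scores),
                 n_voxels = length(scores)),
            class = "mmfuse_fit")
}

test_that("selection rules keep the right voxels with deterministic ties", {
  # top 20% of 2000 -> exactly 400
  set.seed(15)
  f <- fake_fit(runif(2000))
  sel <- select_voxels(f, selection_rule("random_forest"))
  expect_length(sel$indices, 400)
  expect_equal(sel$indices, sort(sel$indices))
  # boundary ties resolved towards the lower voxel index
  scores <- c(5, 3, 3, 3, 1)
  sel2 <- select_voxels(fake_fit(scores), selection_rule("random_forest", fraction = 0.4))
  expect_equal(sel2$indices, c(1L, 2L))
  # ceil arithmetic: 0.2 * 11 -> 3
  sel3 <- select_voxels(fake_fit(rev(seq_len(11))),
                        selection_rule("random_forest", fraction = 0.2))
  expect_length(sel3$indices, 3)
  # nonzero mode
  sel4 <- select_voxels(fake_fit(c(0, 2, 0, 1)), selection_rule("gradient_boosting"))
  expect_equal(sel4$indices, c(2L, 4L))
  expect_warning(empty <- select_voxels(fake_fit(rep(0, 5)),
                                        selection_rule("gradient_boosting")),
                 "zero")
  expect_length(empty$indices, 0)
  expect_error(selection_rule("ridge", fraction = 0), class = "mmfuse_config_error")
})

test_that("lasso selection equals its nonzero coefficient support", {
  set.seed(16)
  n <- 80; v <- 60
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * v), n, v)
  x[, 1:5] <- x[, 1:5] + 1.5 * y
  fit <- fit_classifier(x, y, classifier_spec("lasso", seed = 2))
  sel <- select_voxels(fit, selection_rule("lasso"))
  expect_equal(sel$indices, which(classifier_scores(fit) != 0))
  expect_gt(length(sel$indices), 0)
})

test_that("ridge selection recovers most true signal voxels", {
  set.seed(17)
  co <- generate_cohort(cohort_spec(
    n_controls = 60, n_patients = 50, n_voxels = 300, modality_names = "A",
    signal_count = 30, effect_size = 1.5,
    pairwise_shared_fraction = matrix(1, 1, 1), seed = 41))
  x <- scale(co$data$A)
  fit <- fit_classifier(x, co$labels, classifier_spec("ridge", seed = 3))
  sel <- select_voxels(fit, selection_rule("ridge"))
  recovery <- length(intersect(sel$indices, co$truth_masks$A)) / 30
  expect_gt(recovery, 0.8)
})

test_that("selection_overlap reports both normalizations", {
  a <- 1:200; b <- c(1:79, 301:421)
  ov <- selection_overlap(a, b, 1000)
  expect_equal(ov$containment, 79 / 200)
  expect_equal(ov$joint_fraction, 0.079)
  same <- selection_overlap(1:200, 1:200, 1000)
  expect_equal(same$containment, 1)
  expect_equal(same$joint_fraction, 0.2)
  expect_true(is.na(selection_overlap(integer(0), 1:10, 100)$containment))
})

test_that("expected joint fraction under independent selection is q_a * q_b", {
  set.seed(18)
  v <- 10000
  draws <- replicate(300, {
    a <- sample.int(v, 2000); b <- sample.int(v, 2000)
    selection_overlap(a, b, v)$joint_fraction
  })
  expect_lt(abs(mean(draws) - 0.04), 0.005)
})

test_that("merge_and_refit with everything selected equals a plain refit", {
  co <- small_cohort(seed = 20, n_voxels = 40, signal = 8)
  fp <- make_folds(co$labels, 4, seed = 7)
  spec <- classifier_spec("ridge", seed = 5, lambda = 0.5)  # fixed penalty
  masks <- list(A = seq_len(40))
  probs <- merge_and_refit(co, masks, spec, fp, 1)
  train <- fp$assignment != 1
  prep <- mmfuse:::preprocess_fit(co$data$A[train, ], co$age[train], co$sex[train])
  xs_tr <- mmfuse:::preprocess_apply(prep, co$data$A[train, ], co$age[train], co$sex[train])
  xs_te <- mmfuse:::preprocess_apply(prep, co$data$A[!train, ], co$age[!train], co$sex[!train])
  sp <- spec; sp$seed <- derive_seed(spec$seed, "twostep-refit", spec$family, 1)
  ref <- predict_prob(fit_classifier(xs_tr, co$labels[train], sp), xs_te)
  expect_equal(unname(probs), unname(ref), tolerance = 1e-10)
  expect_error(merge_and_refit(co, list(A = integer(0)), spec, fp, 1),
               class = "mmfuse_config_error")
})

test_that("cross-validated two-step runs end to end with per-fold selections", {
  co <- small_cohort(seed = 21, n_voxels = 60, signal = 12)
  fp <- make_folds(co$labels, 4, seed = 9)
  out <- cross_validate_twostep(co, classifier_spec("ridge", seed = 8), fp)
  expect_equal(nrow(out$table), n_subjects(co))
  expect_equal(unique(out$table$source), "twostep")
  expect_length(out$selections, 4)
  # per-fold ridge selections are exactly ceil(0.2 * V) per modality
  for (k in 1:4) for (mod in c("A", "B"))
    expect_length(out$selections[[k]][[mod]], ceiling(0.2 * 60))
  expect_equal(nrow(out$overlap), 4)  # one A-B row per fold
  expect_true(all(out$overlap$containment >= 0 & out$overlap$containment <= 1))
  ms <- summarize_overlap(out$overlap)
  expect_equal(nrow(ms), 1)
  # selections are a function of training rows only
  co_pert <- co
  test_rows <- which(fp$assignment == 3)
  co_pert$data$A[test_rows, ] <- 0
  out2 <- cross_validate_twostep(co_pert, classifier_spec("ridge", seed = 8), fp)
  expect_identical(out$selections[[3]], out2$selections[[3]])
})
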