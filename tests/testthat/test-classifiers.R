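# Classifier families and the in-package tree engine.

test_that("tree engine root split matches a brute-force oracle", {
  set.seed(14)
  for (rep in 1:5) {
    n <- 40; p <- 6
    x <- matrix(rnorm(n * p), n, p)
    y <- as.double(rbinom(n, 1, plogis(x[, 3] * 2)))
    r <- y - mean(y)
    # depth-1 boosted tree with shrinkage 1: its root split must maximize
    # the SSE reduction of the residuals
    fit <- mmfuse:::gbm_fit_cpp(x, y, 1L, 1L, 1.0, 1L)
    root <- fit$trees[[1]][1, ]
    best <- list(gain = -Inf)
    for (f in 1:p) {
      xs <- sort(unique(x[, f]))
      for (t in seq_len(length(xs) - 1)) {
        thr <- (xs[t] + xs[t + 1]) / 2
        l <- r[x[, f] <= thr]; rr <- r[x[, f] > thr]
        gain <- sum(l)^2 / length(l) + sum(rr)^2 / length(rr) - sum(r)^2 / n
        if (gain > best$gain + 1e-12) best <- list(gain = gain, f = f, thr = thr)
      }
    }
    expect_equal(root[["feature"]] + 1, best$f)
    expect_equal(root[["threshold"]], best$thr, tolerance = 1e-12)
  }
})

test_that("all four families separate noiseless-signal data perfectly", {
  set.seed(6)
  n <- 60
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 8, sd = 0.1), n, 8)
  x[, 1] <- x[, 1] + 4 * y          # wide margin on feature 1
  train <- seq_len(n) %% 2 == 0
  specs <- list(
    classifier_spec("ridge", seed = 1),
    classifier_spec("lasso", seed = 1),
    classifier_spec("random_forest", seed = 1, n_trees = 100),
    classifier_spec("gradient_boosting", seed = 1, n_trees_max = 40,
                    depth_grid = 1, shrinkage_grid = 0.1))
  for (spec in specs) {
    probs <- fit_predict_fold(x[train, ], y[train], x[!train, ], spec)
    expect_true(all(probs >= 0 & probs <= 1))
    expect_equal(as.integer(probs > 0.5), y[!train],
                 info = spec$family)
  }
})

test_that("infinite ridge penalty collapses to the intercept-only model", {
  set.seed(9)
  n <- 80
  y <- rbinom(n, 1, 0.45)
  if (sum(y) %in% c(0, n)) y[1:2] <- 0:1
  x <- matrix(rnorm(n * 10), n, 10)
  fit <- fit_classifier(x, y, classifier_spec("ridge", seed = 1, lambda = 1e9))
  probs <- predict_prob(fit, x)
  expect_lt(max(probs) - min(probs), 1e-4)
  expect_equal(mean(probs), mean(y), tolerance = 1e-3)
  # constant prediction at the training patient fraction -> majority class
  expect_equal(unique(as.integer(probs > 0.5)), as.integer(mean(y) > 0.5))
})

test_that("stochastic families are reproducible from the spec seed", {
  set.seed(10)
  x <- matrix(rnorm(50 * 12), 50, 12)
  y <- rbinom(50, 1, 0.5); y[1:2] <- 0:1
  for (fam in c("random_forest", "gradient_boosting")) {
    spec <- if (fam == "random_forest")
      classifier_spec(fam, seed = 33, n_trees = 50)
    else classifier_spec(fam, seed = 33, n_trees_max = 30, depth_grid = 1:2,
                         shrinkage_grid = 0.1)
    p1 <- predict_prob(fit_classifier(x, y, spec), x)
    p2 <- predict_prob(fit_classifier(x, y, spec), x)
    expect_identical(p1, p2, info = fam)
  }
})

test_that("classifier scores expose coefficients and importances", {
  set.seed(11)
  n <- 80
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 10), n, 10)
  x[, 4] <- x[, 4] + 2.5 * y
  ridge <- fit_classifier(x, y, classifier_spec("ridge", seed = 1))
  sc <- classifier_scores(ridge)
  expect_length(sc, 10)
  expect_equal(which.max(abs(sc)), 4)
  rf <- fit_classifier(x, y, classifier_spec("random_forest", seed = 1, n_trees = 100))
  imp <- classifier_scores(rf)
  expect_true(all(imp >= 0))
  expect_equal(which.max(imp), 4)
  gb <- fit_classifier(x, y, classifier_spec("gradient_boosting", seed = 1,
                                             n_trees_max = 30, depth_grid = 1,
                                             shrinkage_grid = 0.1))
  expect_equal(which.max(classifier_scores(gb)), 4)
})

test_that("degenerate inputs raise explicit errors", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_classifier(x, rep(1, 10), classifier_spec("ridge")),
               class = "mmfuse_single_class_error")
  fit <- suppressWarnings(
    fit_classifier(x, rep(0:1, 5), classifier_spec("ridge", lambda = 0.1)))
  expect_error(predict_prob(fit, matrix(0, 2, 5)),
               class = "mmfuse_incompatible_data_error")
  expect_error(classifier_spec("ridge", bogus = 1), class = "mmfuse_config_error")
})
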