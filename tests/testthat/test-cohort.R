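# Synthetic cohort generator: reproducibility, overlap construction,
# signal calibration and demographic structure.

test_that("cohorts are bit-identical under the same seed", {
  a <- small_cohort(seed = 3)
  b <- small_cohort(seed = 3)
  expect_identical(a, b)
  expect_false(identical(a$data$A, small_cohort(seed = 4)$data$A))
})

test_that("realized overlap honours the requested pairwise fractions", {
  # identical masks
  co1 <- small_cohort(shared = 1)
  expect_identical(co1$truth_masks$A, co1$truth_masks$B)
  expect_equal(realized_overlap(co1, "A", "B"), 1)

  # disjoint masks
  co0 <- small_cohort(shared = 0)
  expect_equal(realized_overlap(co0, "A", "B"), 0)

  # masks of sizes 100 and 50 sharing 25 -> 0.5
  sp <- cohort_spec(n_controls = 10, n_patients = 10, n_voxels = 400,
                    modality_names = c("A", "B"), signal_count = c(100, 50),
                    effect_size = 1,
                    pairwise_shared_fraction = matrix(c(1, .5, .5, 1), 2),
                    seed = 2)
  co <- generate_cohort(sp)
  expect_length(co$truth_masks$A, 100)
  expect_length(co$truth_masks$B, 50)
  expect_length(intersect(co$truth_masks$A, co$truth_masks$B), 25)
  expect_equal(realized_overlap(co, "A", "B"), 0.5)

  # arbitrary sweep values land within rounding of the target
  for (f in c(0.25, 0.75)) {
    co <- generate_cohort(cohort_spec(
      n_controls = 5, n_patients = 5, n_voxels = 300,
      modality_names = c("A", "B"), signal_count = 40, effect_size = 1,
      pairwise_shared_fraction = matrix(c(1, f, f, 1), 2), seed = 5))
    expect_equal(realized_overlap(co, "A", "B"), f, tolerance = 1 / 40)
  }

  expect_error(realized_overlap(structure(list(truth_masks = NULL),
                                          class = "multimodal_cohort"), "A", "B"),
               class = "mmfuse_unsupported_input_error")
})

test_that("infeasible overlap requests raise a configuration error", {
  psf <- matrix(0.9, 3, 3); diag(psf) <- 1
  expect_error(generate_cohort(cohort_spec(
    n_controls = 5, n_patients = 5, n_voxels = 500,
    modality_names = c("A", "B", "C"), signal_count = 10, effect_size = 1,
    pairwise_shared_fraction = psf, seed = 1)),
    class = "mmfuse_config_error")
  # demand exceeding the voxel space
  expect_error(cohort_spec(n_voxels = 100, signal_count = 150),
               class = "mmfuse_config_error")
  # asymmetric matrix
  bad <- matrix(c(1, .2, .3, 1), 2)
  expect_error(cohort_spec(modality_names = c("A", "B"), effect_size = 1,
                           pairwise_shared_fraction = bad),
               class = "mmfuse_config_error")
})

test_that("signal voxels carry the requested effect size", {
  d <- 0.8
  co <- generate_cohort(cohort_spec(
    n_controls = 1000, n_patients = 1000, n_voxels = 50,
    modality_names = "A", signal_count = 20, effect_size = d,
    pairwise_shared_fraction = matrix(1, 1, 1),
    age_slope = 0, sex_offset = 0, seed = 9))
  sig <- co$truth_masks$A
  diff <- colMeans(co$data$A[co$labels == 1, sig]) -
    colMeans(co$data$A[co$labels == 0, sig])
  # grand mean difference within 3 standard errors of d (noise_sd = 1)
  se <- sqrt(2 / 1000 / length(sig))
  expect_lt(abs(mean(diff) - d), 3 * se)
})

test_that("voxels outside the truth masks show no label association", {
  co <- generate_cohort(cohort_spec(
    n_controls = 115, n_patients = 96, n_voxels = 10000,
    modality_names = "A", signal_count = 0, effect_size = 0,
    pairwise_shared_fraction = matrix(1, 1, 1), seed = 21))
  x <- co$data$A
  g1 <- co$labels == 1
  n1 <- sum(g1); n0 <- sum(!g1)
  m1 <- colMeans(x[g1, ]); m0 <- colMeans(x[!g1, ])
  v1 <- apply(x[g1, ], 2, var); v0 <- apply(x[!g1, ], 2, var)
  tstat <- (m1 - m0) / sqrt(v1 / n1 + v0 / n0)
  frac <- mean(abs(tstat) > 1.96)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("demographics match the spec and are balanced across groups", {
  co <- generate_cohort(cohort_spec(n_voxels = 10, signal_count = 2, seed = 13))
  expect_equal(length(co$labels), 211)
  expect_equal(sum(co$labels), 96)
  expect_true(all(co$age >= 16 & co$age <= 65))
  expect_true(all(co$sex %in% 0:1))
  # same generating distribution in both groups: means not far apart
  expect_lt(abs(mean(co$age[co$labels == 1]) - mean(co$age[co$labels == 0])), 5)
})

test_that("cohorts round-trip through a directory (CSV)", {
  co <- small_cohort(seed = 12, n_voxels = 30, signal = 6)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("subjects.csv", "A.csv", "B.csv",
                                               "truth_masks.json", "spec.yaml")))))
  back <- read_cohort(dir)
  expect_equal(back$labels, co$labels)
  expect_equal(back$age, co$age, tolerance = 1e-8)
  expect_equal(unname(back$data$A), unname(co$data$A), tolerance = 1e-8)
  expect_equal(sort(back$truth_masks$B), sort(co$truth_masks$B))
  # NIfTI stack format writes volumes + mask
  dir2 <- file.path(tempdir(), "cohort_nii")
  write_cohort(co, dir2, format = "nifti")
  img <- read_nifti(file.path(dir2, "A.nii.gz"))
  expect_equal(dim(img$data), c(30L, 1L, 1L, 74L))
  expect_equal(as.numeric(img$data[, 1, 1, 5]), unname(co$data$A[5, ]))
})
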