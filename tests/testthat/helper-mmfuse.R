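# Shared fixtures: all synthetic, generated in code at test time.

# Small two-modality cohort with strong signal, fast enough for per-fold
# classifier fits in unit tests.
small_cohort <- function(seed = 7, n_voxels = 120, effect = c(1.2, 1.0),
                         shared = 0.5, n_controls = 40, n_patients = 34,
                         signal = 24, noise_sd = 1) {
  generate_cohort(cohort_spec(
    n_controls = n_controls, n_patients = n_patients, n_voxels = n_voxels,
    modality_names = c("A", "B"), signal_count = signal,
    effect_size = effect,
    pairwise_shared_fraction = matrix(c(1, shared, shared, 1), 2),
    seed = seed))
}

# Null cohort: no group signal anywhere.
null_cohort <- function(seed = 11, n_voxels = 100, modalities = c("A", "B"),
                        n_controls = 115, n_patients = 96) {
  generate_cohort(cohort_spec(
    n_controls = n_controls, n_patients = n_patients, n_voxels = n_voxels,
    modality_names = modalities, signal_count = 10,
    effect_size = rep(0, length(modalities)),
    pairwise_shared_fraction = diag(length(modalities)) * 0 + 0.5 +
      diag(length(modalities)) * 0.5,
    seed = seed))
}

# Toy 3-D mask with a given number of in-mask voxels on a fixed grid.
toy_mask <- function(true_idx, dims = c(5, 5, 5)) {
  g <- array(FALSE, dims)
  g[true_idx] <- TRUE
  voxel_mask(g)
}

# Prediction table with a prescribed correctness vector (truth all patient).
new_prediction_table_for_test <- function(correct, source = "X", algorithm = "ridge") {
  n <- length(correct)
  mmfuse:::new_prediction_table(
    subject = sprintf("S%04d", seq_len(n)),
    fold = rep_len(1:10, n),
    source = source, algorithm = algorithm,
    prob = ifelse(correct == 1, 0.9, 0.1),
    truth = rep(1L, n))
}

# Independent brute-force RSC oracle: enumerate the 2x2 contingency table
# directly from the paired indicators.
oracle_rsc <- function(c1, c2) {
  n11 <- sum(c1 == 1 & c2 == 1); n10 <- sum(c1 == 1 & c2 == 0)
  n01 <- sum(c1 == 0 & c2 == 1); n00 <- sum(c1 == 0 & c2 == 0)
  p2 <- (n11 + n01) / (n11 + n10 + n01 + n00)
  pc <- n11 / (n11 + n10)
  (pc - p2) / (1 - p2)
}
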