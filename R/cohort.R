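# Synthetic multimodal cohort generator. Emulates the input of the real
# study -- five voxelwise brain maps per subject, two diagnostic groups
# matched for age and sex -- with known discriminative structure: each
# modality carries a group difference confined to a designated voxel set,
# and the voxel sets of different modalities share a controllable fraction
# of voxels (the dial for redundancy between map types).

DEFAULT_MODALITIES <- c("GMVBM", "1back", "2back", "ALFF", "GBC")

#' Specification of a synthetic multimodal cohort
#'
#' Demographic defaults follow the reference clinical sample (115 controls,
#' 96 patients, 67% male, age mean 36.5 y, SD 10.6 y, range 16-65 y). The
#' signal structure (which voxels differ between groups, by how much, and
#' how much of it is shared between modalities) is synthetic by design.
#'
#' @param n_controls,n_patients Group sizes.
#' @param male_fraction Proportion of males in both groups.
#' @param age_mean,age_sd,age_range Age distribution (normal truncated to
#'   `age_range`), identical in both groups.
#' @param n_voxels Voxels per modality (shared voxel space).
#' @param modality_names Modality identifiers.
#' @param signal_count Signal voxels per modality (scalar or named/ordered
#'   vector, one per modality).
#' @param effect_size Standardized mean group difference d (patients minus
#'   controls, in units of `noise_sd`) at signal voxels, per modality.
#' @param pairwise_shared_fraction Symmetric matrix with unit diagonal;
#'   entry (a, b) is the target `|mask_a . mask_b| / min(|mask_a|, |mask_b|)`.
#'   A scalar is expanded to all off-diagonal entries.
#' @param age_slope Map units per year added to every voxel.
#' @param sex_offset Map units added to every voxel for males.
#' @param noise_sd SD of the additive Gaussian voxel noise.
#' @param smooth_radius Optional running-mean radius (in voxel-index units)
#'   applied to the noise; 0 (default) keeps voxels independent.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 115, n_patients = 96,
                        male_fraction = 0.67,
                        age_mean = 36.5, age_sd = 10.6, age_range = c(16, 65),
                        n_voxels = 2000,
                        modality_names = DEFAULT_MODALITIES,
                        signal_count = 200,
                        effect_size = NULL,
                        pairwise_shared_fraction = NULL,
                        age_slope = 0.02, sex_offset = 0.2, noise_sd = 1,
                        smooth_radius = 0, seed = 1L) {
  m <- length(modality_names)
  if (m < 1 || anyDuplicated(modality_names))
    stop_mmfuse("modality names must be unique and non-empty", "mmfuse_config_error")
  expand <- function(x, what) {
    if (length(x) == 1) x <- rep(x, m)
    if (length(x) != m)
      stop_mmfuse(paste0(what, " must have length 1 or one per modality"),
                  "mmfuse_config_error")
    stats::setNames(as.double(x), modality_names)
  }
  signal_count <- expand(signal_count, "signal_count")
  if (is.null(effect_size)) {
    # defaults mirror the reported unimodal accuracy ordering (2back strongest)
    lut <- c(GMVBM = 0.8, `1back` = 0.6, `2back` = 1.2, ALFF = 0.75, GBC = 0.45)
    effect_size <- ifelse(modality_names %in% names(lut),
                          lut[modality_names], 0.8)
  }
  effect_size <- expand(effect_size, "effect_size")
  if (is.null(pairwise_shared_fraction)) {
    psf <- matrix(0.1, m, m)
    within <- list(c("1back", "2back"), c("ALFF", "GBC"))
    rownames(psf) <- colnames(psf) <- modality_names
    for (pr in within) if (all(pr %in% modality_names)) {
      f <- if (identical(pr[1], "1back")) 0.5 else 0.4
      psf[pr[1], pr[2]] <- psf[pr[2], pr[1]] <- f
    }
    diag(psf) <- 1
  } else if (length(pairwise_shared_fraction) == 1) {
    psf <- matrix(pairwise_shared_fraction, m, m)
    diag(psf) <- 1
    rownames(psf) <- colnames(psf) <- modality_names
  } else {
    psf <- as.matrix(pairwise_shared_fraction)
    if (is.null(rownames(psf))) rownames(psf) <- colnames(psf) <- modality_names
  }
  spec <- structure(list(
    n_controls = as.integer(n_controls), n_patients = as.integer(n_patients),
    male_fraction = male_fraction, age_mean = age_mean, age_sd = age_sd,
    age_range = as.double(age_range), n_voxels = as.integer(n_voxels),
    modality_names = modality_names, signal_count = signal_count,
    effect_size = effect_size, pairwise_shared_fraction = psf,
    age_slope = age_slope, sex_offset = sex_offset, noise_sd = noise_sd,
    smooth_radius = smooth_radius, seed = as.integer(seed)), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_controls < 1 || n_patients < 1 || n_voxels < 1)
      stop_mmfuse("counts must be positive", "mmfuse_config_error")
    if (male_fraction < 0 || male_fraction > 1)
      stop_mmfuse("male_fraction must be in [0,1]", "mmfuse_config_error")
    if (any(signal_count < 0) || any(signal_count > n_voxels))
      stop_mmfuse("signal_count must be in [0, n_voxels]", "mmfuse_config_error")
    psf <- pairwise_shared_fraction
    m <- length(modality_names)
    if (!identical(dim(psf), c(m, m)) ||
        any(psf < 0 | psf > 1) ||
        max(abs(psf - t(psf))) > 1e-12 ||
        any(abs(diag(psf) - 1) > 1e-12))
      stop_mmfuse("pairwise_shared_fraction must be a symmetric [0,1] matrix with unit diagonal",
                  "mmfuse_config_error")
    if (noise_sd < 0) stop_mmfuse("noise_sd must be >= 0", "mmfuse_config_error")
    if (length(age_range) != 2 || age_range[1] >= age_range[2])
      stop_mmfuse("age_range must be an increasing pair", "mmfuse_config_error")
  })
  invisible(spec)
}

# Build per-modality signal-voxel sets realizing the pairwise shared
# fractions. Modalities linked by fraction 1 are merged into clusters with
# identical masks; remaining sharing is realized through disjoint per-pair
# pools (no triple-shared voxels), so each pairwise intersection is exact.
build_truth_masks <- function(spec) {
  m <- length(spec$modality_names)
  counts <- round(spec$signal_count)
  psf <- spec$pairwise_shared_fraction
  # union-find over fraction-1 pairs
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(m)) for (b in seq_len(m)) if (a < b && psf[a, b] >= 1 - 1e-12) {
    if (abs(counts[a] - counts[b]) > 0)
      stop_mmfuse("pairwise_shared_fraction of 1 requires equal signal counts",
                  "mmfuse_config_error")
    parent[find(b)] <- find(a)
  }
  cluster <- vapply(seq_len(m), find, integer(1))
  reps <- unique(cluster)
  k <- length(reps)
  ccount <- counts[reps]
  # cluster-level shared-pool sizes
  need <- matrix(0L, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
    members_i <- which(cluster == reps[i]); members_j <- which(cluster == reps[j])
    fr <- psf[members_i, members_j, drop = FALSE]
    if (max(fr) - min(fr) > 1e-12)
      stop_mmfuse("inconsistent shared fractions across fully shared modalities",
                  "mmfuse_config_error")
    need[i, j] <- as.integer(round(fr[1] * min(ccount[i], ccount[j])))
  }
  for (i in seq_len(k)) {
    tot_shared <- sum(need[i, ]) + sum(need[, i])
    if (tot_shared > ccount[i])
      stop_mmfuse(sprintf(
        "infeasible overlap matrix: modality '%s' needs %d shared voxels but has only %d signal voxels",
        spec$modality_names[reps[i]], tot_shared, ccount[i]), "mmfuse_config_error")
  }
  total <- sum(ccount) - sum(need)
  if (total > spec$n_voxels)
    stop_mmfuse("signal voxel demand exceeds n_voxels", "mmfuse_config_error")
  pool <- sample.int(spec$n_voxels, total)
  pos <- 1L
  take <- function(n) {
    if (n == 0) return(integer(0))
    out <- pool[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  shared <- vector("list", k * k)
  dim(shared) <- c(k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j && need[i, j] > 0)
    shared[[i, j]] <- take(need[i, j])
  masks_k <- vector("list", k)
  for (i in seq_len(k)) {
    sh <- integer(0)
    for (j in seq_len(k)) {
      if (i < j && need[i, j] > 0) sh <- c(sh, shared[[i, j]])
      if (j < i && need[j, i] > 0) sh <- c(sh, shared[[j, i]])
    }
    masks_k[[i]] <- sort(c(sh, take(ccount[i] - length(sh))))
  }
  masks <- lapply(seq_len(m), function(a) masks_k[[match(cluster[a], reps)]])
  names(masks) <- spec$modality_names
  # record which modalities share which voxels so that shared signal voxels
  # can carry shared values (redundant predictive information, not merely
  # co-located signal)
  pools <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j && need[i, j] > 0)
    pools[[length(pools) + 1]] <- list(
      members = spec$modality_names[cluster %in% reps[c(i, j)]],
      voxels = shared[[i, j]])
  for (i in seq_len(k)) {
    members <- spec$modality_names[cluster == reps[i]]
    if (length(members) > 1) {
      shared_ij <- unlist(lapply(pools, function(p)
        if (all(members %in% p$members)) p$voxels))
      uniq <- setdiff(masks_k[[i]], shared_ij)
      if (length(uniq) > 0)
        pools[[length(pools) + 1]] <- list(members = members, voxels = uniq)
    }
  }
  list(masks = masks, pools = pools)
}

#' Generate a synthetic multimodal cohort
#'
#' The value of modality m at voxel v for subject i is
#' `age_slope*age_i + sex_offset*sex_i + d_m*noise_sd*label_i*[v in mask_m]
#' + N(0, noise_sd^2)`. At signal voxels shared between modalities the
#' noise realization is shared too (identical values up to the modality's
#' effect shift): shared predictive information requires dependence between
#' the maps, not merely co-located signal, and this is what makes the
#' pairwise sharing fraction an effective redundancy dial. Age and sex are
#' drawn from the same distribution in both groups (matched by
#' construction); the whole cohort is reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `multimodal_cohort`: named list of
#'   subject x voxel matrices in `$data`, plus `$labels` (1 = patient),
#'   `$age`, `$sex` (1 = male), `$subject_id`, `$truth_masks` (per-modality
#'   signal voxel indices) and `$spec`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_controls + spec$n_patients
  labels <- c(rep(0L, spec$n_controls), rep(1L, spec$n_patients))
  age <- truncnorm::rtruncnorm(n, a = spec$age_range[1], b = spec$age_range[2],
                               mean = spec$age_mean, sd = spec$age_sd)
  sex <- stats::rbinom(n, 1L, spec$male_fraction)
  mt <- build_truth_masks(spec)
  masks <- mt$masks
  v <- spec$n_voxels
  covar <- spec$age_slope * age + spec$sex_offset * sex
  noise <- lapply(spec$modality_names, function(mod) {
    e <- matrix(stats::rnorm(n * v, 0, spec$noise_sd), n, v)
    if (spec$smooth_radius > 0) {
      w <- 2L * as.integer(spec$smooth_radius) + 1L
      kern <- rep(1 / w, w)
      e <- t(apply(e, 1, function(row)
        as.numeric(stats::filter(row, kern, sides = 2, circular = TRUE)) * sqrt(w)))
    }
    e
  })
  names(noise) <- spec$modality_names
  # shared signal pools: one realization reused by every member modality
  for (pool in mt$pools) {
    shared <- matrix(stats::rnorm(n * length(pool$voxels), 0, spec$noise_sd), n)
    for (mod in pool$members) noise[[mod]][, pool$voxels] <- shared
  }
  data <- lapply(spec$modality_names, function(mod) {
    x <- noise[[mod]] + covar
    sig <- masks[[mod]]
    if (length(sig) > 0 && spec$effect_size[mod] != 0) {
      shift <- spec$effect_size[mod] * spec$noise_sd
      x[labels == 1L, sig] <- x[labels == 1L, sig] + shift
    }
    colnames(x) <- paste0("v", seq_len(v))
    x
  })
  names(data) <- spec$modality_names
  structure(list(data = data, labels = labels, age = age, sex = sex,
                 subject_id = sprintf("S%04d", seq_len(n)),
                 truth_masks = masks, spec = spec),
            class = "multimodal_cohort")
}

#' @export
print.multimodal_cohort <- function(x, ...) {
  cat(sprintf("multimodal_cohort: %d subjects (%d patients / %d controls), %d modalities x %d voxels\n",
              length(x$labels), sum(x$labels == 1), sum(x$labels == 0),
              length(x$data), ncol(x$data[[1]])))
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort A `multimodal_cohort`.
#' @return Integer.
#' @export
n_subjects <- function(cohort) length(cohort$labels)

#' Realized signal-mask overlap between two modalities
#'
#' @param cohort A `multimodal_cohort` with ground-truth masks.
#' @param m1,m2 Modality names.
#' @return `|mask_1 . mask_2| / min(|mask_1|, |mask_2|)`.
#' @export
realized_overlap <- function(cohort, m1, m2) {
  if (is.null(cohort$truth_masks))
    stop_mmfuse("cohort has no ground-truth masks", "mmfuse_unsupported_input_error")
  a <- cohort$truth_masks[[m1]]; b <- cohort$truth_masks[[m2]]
  if (is.null(a) || is.null(b))
    stop_mmfuse("unknown modality name", "mmfuse_unsupported_input_error")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Write a cohort to a directory
#'
#' Writes one subject x voxel CSV per modality (or a 4-D NIfTI stack plus a
#' mask volume), `subjects.csv` (id, label, age, sex), `truth_masks.json`,
#' and the generating spec as `spec.yaml`.
#'
#' @param cohort A `multimodal_cohort`.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` (default) or `"nifti"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "nifti")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- data.frame(id = cohort$subject_id, label = cohort$labels,
                         age = cohort$age, sex = cohort$sex)
  utils::write.csv(subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  if (!is.null(cohort$truth_masks))
    jsonlite::write_json(cohort$truth_masks, file.path(dir, "truth_masks.json"))
  if (!is.null(cohort$spec)) {
    sp <- unclass(cohort$spec)
    sp$pairwise_shared_fraction <- as.list(as.data.frame(sp$pairwise_shared_fraction))
    yaml::write_yaml(sp, file.path(dir, "spec.yaml"))
  }
  v <- ncol(cohort$data[[1]])
  for (mod in names(cohort$data)) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", mod)
    if (format == "csv") {
      write_flat_matrix(cohort$data[[mod]], file.path(dir, paste0(safe, ".csv")))
    } else {
      # synthetic cohorts live in flat voxel-index space: use a V x 1 x 1 grid
      n <- nrow(cohort$data[[mod]])
      stack <- array(t(cohort$data[[mod]]), dim = c(v, 1, 1, n))
      write_nifti(stack, file.path(dir, paste0(safe, ".nii.gz")), datatype = "float64")
      write_mask_volume(voxel_mask(array(TRUE, c(v, 1, 1))),
                        file.path(dir, "mask.nii.gz"))
    }
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()] (CSV format)
#'
#' @param dir Directory containing `subjects.csv` and one CSV per modality.
#' @param modality_names Optional modality subset/order; defaults to all
#'   CSV files other than `subjects.csv`, alphabetical.
#' @return A `multimodal_cohort` (without spec; truth masks if present).
#' @export
read_cohort <- function(dir, modality_names = NULL) {
  subj_path <- file.path(dir, "subjects.csv")
  if (!file.exists(subj_path))
    stop_mmfuse(paste0("missing subjects.csv in ", dir), "mmfuse_io_error")
  subjects <- utils::read.csv(subj_path)
  if (is.null(modality_names)) {
    files <- setdiff(list.files(dir, pattern = "\\.csv$"), "subjects.csv")
    modality_names <- sub("\\.csv$", "", sort(files))
  }
  data <- lapply(modality_names, function(mod) {
    p <- file.path(dir, paste0(mod, ".csv"))
    if (!file.exists(p)) stop_mmfuse(paste0("missing modality file: ", p), "mmfuse_io_error")
    read_flat_matrix(p)
  })
  names(data) <- modality_names
  tm_path <- file.path(dir, "truth_masks.json")
  masks <- if (file.exists(tm_path))
    lapply(jsonlite::read_json(tm_path, simplifyVector = TRUE), as.integer)
  structure(list(data = data, labels = as.integer(subjects$label),
                 age = as.double(subjects$age), sex = as.integer(subjects$sex),
                 subject_id = as.character(subjects$id),
                 truth_masks = masks, spec = NULL),
            class = "multimodal_cohort")
}
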