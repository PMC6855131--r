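# Train-only confound residualization. Per-voxel linear models of map value
# on age and sex are fitted on the training subjects of a fold and their
# coefficients are applied, unchanged, to the corresponding test subjects.
# The diagnosis label never enters the design matrix.

#' Fit per-voxel age/sex confound models
#'
#' Ordinary least squares of each voxel column on `[1, age, sex]`, fitted
#' jointly for all voxels. If a covariate is constant in the training rows
#' (rank-deficient design) it is dropped with a warning and its coefficient
#' is fixed at 0.
#'
#' @param train_matrix Training subject x voxel matrix.
#' @param age Age (years) per training row.
#' @param sex Sex per training row, coded 1 = male, 0 = female.
#' @return An object of class `confound_model` with per-voxel `intercept`,
#'   `age_coef`, `sex_coef` and the covariate `coding` record.
#' @export
fit_confounds <- function(train_matrix, age, sex) {
  train_matrix <- as.matrix(train_matrix)
  n <- nrow(train_matrix)
  if (n < 3) stop_mmfuse("need at least 3 training subjects", "mmfuse_argument_error")
  if (length(age) != n || length(sex) != n)
    stop_mmfuse("covariate length does not match rows", "mmfuse_incompatible_data_error")
  use_age <- stats::var(age) > 0
  use_sex <- stats::var(sex) > 0
  if (!use_age && !use_sex)
    stop_mmfuse("age and sex are both constant in the training sample",
                "mmfuse_argument_error")
  if (!use_age) warning("age constant in training sample; fitting sex only")
  if (!use_sex) warning("sex constant in training sample; fitting age only")
  x <- cbind(intercept = 1, age = if (use_age) age, sex = if (use_sex) sex)
  beta <- solve(crossprod(x), crossprod(x, train_matrix))
  v <- ncol(train_matrix)
  zero <- rep(0, v)
  structure(list(
    intercept = beta["intercept", ],
    age_coef = if (use_age) beta["age", ] else zero,
    sex_coef = if (use_sex) beta["sex", ] else zero,
    n_voxels = v,
    coding = list(sex = "1 = male, 0 = female", age = "years")),
    class = "confound_model")
}

#' Remove fitted confound effects from a matrix
#'
#' Subtracts `intercept + age*age_coef + sex*sex_coef` voxelwise. Applied to
#' the rows the model was fitted on, this returns classical OLS residuals
#' (orthogonal to age and sex); applied to test rows it uses the training
#' coefficients unchanged.
#'
#' @param model A `confound_model`.
#' @param matrix Subject x voxel matrix.
#' @param age,sex Covariates for every row of `matrix`.
#' @return Residual matrix of the same shape.
#' @export
remove_confounds <- function(model, matrix, age, sex) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != model$n_voxels)
    stop_mmfuse("voxel count does not match confound model", "mmfuse_incompatible_data_error")
  if (length(age) != nrow(matrix) || length(sex) != nrow(matrix))
    stop_mmfuse("covariate length does not match rows", "mmfuse_incompatible_data_error")
  fitted <- outer(rep(1, nrow(matrix)), model$intercept) +
    outer(age, model$age_coef) + outer(sex, model$sex_coef)
  matrix - fitted
}

#' Serialize a confound model to JSON
#' @param model A `confound_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_confound_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
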