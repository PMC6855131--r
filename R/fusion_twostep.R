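# Strategy 2: two-step sequential integration. Step 1 fits each modality's
# unimodal classifier on the fold's training rows and keeps its "most
# relevant" voxels (top 20% |coefficient| for ridge, non-null coefficients
# for lasso, top 20% importance for random forests, non-zero importance for
# gradient boosting). Step 2 refits the same family on the merged selected
# features. Selection is redone inside every fold; anatomical overlap
# between the per-modality selections is reported per fold under both
# normalizations (joint fraction of all voxels, and containment).

#' Voxel-selection rule for the two-step strategy
#'
#' @param family Classifier family the rule applies to.
#' @param mode `"top_fraction"` or `"nonzero"`; defaults to the family's
#'   convention (ridge/random_forest: top fraction; lasso/gradient_boosting:
#'   nonzero scores).
#' @param fraction Fraction kept under `top_fraction` (default 0.2).
#' @return A `selection_rule`.
#' @export
selection_rule <- function(family, mode = NULL, fraction = 0.2) {
  default_mode <- switch(family,
    ridge = "top_fraction", lasso = "nonzero",
    random_forest = "top_fraction", gradient_boosting = "nonzero",
    stop_mmfuse(paste0("unknown family: ", family), "mmfuse_config_error"))
  mode <- mode %||% default_mode
  if (!mode %in% c("top_fraction", "nonzero"))
    stop_mmfuse("mode must be top_fraction or nonzero", "mmfuse_config_error")
  if (fraction <= 0 || fraction > 1)
    stop_mmfuse("fraction must be in (0, 1]", "mmfuse_config_error")
  structure(list(family = family, mode = mode, fraction = fraction,
                 basis = if (family %in% c("ridge", "lasso"))
                   "|coefficient|" else "importance"),
            class = "selection_rule")
}

#' Select relevant voxels from a fitted unimodal classifier
#'
#' @param fit An `mmfuse_fit` from step 1.
#' @param rule A [selection_rule()].
#' @return A `selection_mask`: list with sorted `indices`, their `scores`,
#'   and the rule. Under `top_fraction` exactly `ceiling(fraction * V)`
#'   voxels are kept, score ties at the boundary broken towards the lower
#'   voxel index; under `nonzero`, all voxels with nonzero score (an empty
#'   result warns).
#' @export
select_voxels <- function(fit, rule) {
  scores <- abs(classifier_scores(fit))
  v <- length(scores)
  if (rule$mode == "top_fraction") {
    k <- ceiling(rule$fraction * v)
    ord <- order(-scores, seq_len(v))  # deterministic tie-break: lower index
    idx <- sort(ord[seq_len(k)])
  } else {
    idx <- which(scores != 0)
    if (length(idx) == 0)
      warning("all selection scores are zero; empty selection mask")
  }
  structure(list(indices = idx, scores = scores[idx], rule = rule,
                 n_voxels = v), class = "selection_mask")
}

#' Overlap statistics between two selection masks
#'
#' Both normalizations behind reported overlap percentages are returned:
#' `joint_fraction` = intersection size over the full voxel count (chance
#' level `q_a * q_b` for independent fractions), and `containment` =
#' intersection over the smaller selection (undefined for an empty mask).
#'
#' @param mask_a,mask_b `selection_mask` objects or integer index vectors.
#' @param n_voxels Total voxels in the common space.
#' @return List with `joint_fraction` and `containment` (`NA` when a mask
#'   is empty).
#' @export
selection_overlap <- function(mask_a, mask_b, n_voxels) {
  a <- if (inherits(mask_a, "selection_mask")) mask_a$indices else as.integer(mask_a)
  b <- if (inherits(mask_b, "selection_mask")) mask_b$indices else as.integer(mask_b)
  inter <- length(intersect(a, b))
  list(joint_fraction = inter / n_voxels,
       containment = if (length(a) == 0 || length(b) == 0) NA_real_
                     else inter / min(length(a), length(b)))
}

# Merged, residualized, training-standardized feature matrix for given rows
build_merged <- function(fold_models, masks, cohort, rows) {
  blocks <- lapply(names(masks), function(mod) {
    idx <- if (inherits(masks[[mod]], "selection_mask"))
      masks[[mod]]$indices else as.integer(masks[[mod]])
    if (length(idx) == 0) return(NULL)
    xs <- preprocess_apply(fold_models[[mod]]$prep,
                           cohort$data[[mod]][rows, , drop = FALSE],
                           cohort$age[rows], cohort$sex[rows])
    block <- xs[, idx, drop = FALSE]
    colnames(block) <- paste0(mod, ".v", idx)
    block
  })
  blocks <- Filter(Negate(is.null), blocks)
  if (length(blocks) == 0)
    stop_mmfuse("all selection masks are empty", "mmfuse_config_error")
  do.call(cbind, blocks)
}

#' Merge selected voxels across modalities and refit for one fold
#'
#' @param cohort A `multimodal_cohort`.
#' @param masks Named list (modality -> `selection_mask` or voxel indices)
#'   produced on this fold's training rows.
#' @param spec A [classifier_spec()] for the final (step 2) model.
#' @param foldplan The shared [make_folds()] plan.
#' @param fold Fold id whose held-out subjects are scored.
#' @param fold_models Optional list of per-modality step-1 fold fits (reused
#'   when available; refitted confound/scaling models otherwise).
#' @return Patient probabilities for the fold's test rows.
#' @export
merge_and_refit <- function(cohort, masks, spec, foldplan, fold,
                            fold_models = NULL) {
  check_foldplan(cohort, foldplan)
  train <- foldplan$assignment != fold
  test <- which(!train)
  if (is.null(fold_models)) {
    fold_models <- lapply(names(masks), function(mod) {
      prep <- preprocess_fit(cohort$data[[mod]][train, , drop = FALSE],
                             cohort$age[train], cohort$sex[train])
      list(prep = prep)
    })
    names(fold_models) <- names(masks)
  }
  x_train <- build_merged(fold_models, masks, cohort, which(train))
  x_test <- build_merged(fold_models, masks, cohort, test)
  sp <- spec
  sp$seed <- derive_seed(spec$seed, "twostep-refit", spec$family, fold)
  if (spec$family == "random_forest" && is.null(sp$mtry))
    sp$mtry <- max(1L, floor(sqrt(ncol(x_train))))
  fit <- fit_classifier(x_train, cohort$labels[train], sp)
  predict_prob(fit, x_test)
}

#' Cross-validated two-step sequential integration
#'
#' @param cohort A `multimodal_cohort`.
#' @param spec A [classifier_spec()]; the same family is used for step 1
#'   (per-modality selection) and step 2 (merged refit).
#' @param foldplan The shared [make_folds()] plan.
#' @param modalities Modalities to integrate (default all).
#' @param rule A [selection_rule()]; defaults to the family's convention.
#' @return List with `table` (a `prediction_table`, source `"twostep"`),
#'   `selections` (per fold, per modality voxel indices) and `overlap`
#'   (per fold, per modality pair: `joint_fraction`, `containment`).
#' @export
cross_validate_twostep <- function(cohort, spec, foldplan,
                                   modalities = names(cohort$data),
                                   rule = NULL) {
  check_foldplan(cohort, foldplan)
  rule <- rule %||% selection_rule(spec$family)
  v <- ncol(cohort$data[[modalities[1]]])
  tables <- list(); selections <- list(); overlaps <- list()
  for (k in seq_len(foldplan$n_folds)) {
    train <- foldplan$assignment != k
    test <- which(!train)
    fold_models <- lapply(modalities, function(mod)
      fit_unimodal_fold(cohort$data[[mod]], cohort$age, cohort$sex,
                        cohort$labels, train, spec,
                        derive_seed(spec$seed, "unimodal", mod, spec$family, k)))
    names(fold_models) <- modalities
    masks <- lapply(fold_models, function(fm) select_voxels(fm$fit, rule))
    empties <- vapply(masks, function(m) length(m$indices) == 0, logical(1))
    if (any(empties))
      message("fold ", k, ": empty selection for ",
              paste(modalities[empties], collapse = ", "))
    probs <- merge_and_refit(cohort, masks, spec, foldplan, k, fold_models)
    tables[[k]] <- new_prediction_table(cohort$subject_id[test], k, "twostep",
                                        spec$family, probs, cohort$labels[test])
    selections[[k]] <- lapply(masks, function(m) m$indices)
    if (length(modalities) > 1) {
      prs <- utils::combn(modalities, 2)
      overlaps[[k]] <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
        ov <- selection_overlap(masks[[prs[1, j]]], masks[[prs[2, j]]], v)
        data.frame(fold = k, m1 = prs[1, j], m2 = prs[2, j],
                   joint_fraction = ov$joint_fraction,
                   containment = ov$containment, stringsAsFactors = FALSE)
      }))
    }
  }
  list(table = do.call(bind_predictions, tables),
       selections = selections,
       overlap = if (length(overlaps)) do.call(rbind, overlaps))
}

#' Average per-fold overlap statistics over folds
#' @param overlap Overlap data frame from [cross_validate_twostep()].
#' @return Data frame per modality pair with mean `joint_fraction` and mean
#'   `containment`.
#' @export
summarize_overlap <- function(overlap) {
  agg <- stats::aggregate(cbind(joint_fraction, containment) ~ m1 + m2,
                          data = overlap, FUN = mean, na.action = stats::na.omit)
  agg[order(agg$m1, agg$m2), ]
}

#' Write per-fold selection masks to JSON
#' @param selections Selections from [cross_validate_twostep()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_selections <- function(selections, path) {
  jsonlite::write_json(selections, path)
  invisible(path)
}
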