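#' Build a fixed cross-validation fold plan
#'
#' Subjects are partitioned into `n_folds` folds, by default stratified by
#' class so that per-fold class proportions differ from the global ones by
#' at most one subject. The same plan object is reused verbatim by every
#' unimodal and multimodal analysis so that test predictions are comparable
#' subject by subject.
#'
#' @param labels Binary class labels (1 = patient, 0 = control).
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed; the assignment is deterministic given it.
#' @param stratified Stratify by class (default `TRUE`).
#' @return An object of class `fold_plan` with `assignment` (fold id per
#'   subject), `n_folds`, `stratified`, `seed`.
#' @export
make_folds <- function(labels, n_folds = 10, seed = 1L, stratified = TRUE) {
  n <- length(labels)
  if (n_folds < 2 || n_folds > n)
    stop_mmfuse("n_folds must be in [2, n_subjects]", "mmfuse_config_error")
  assignment <- integer(n)
  set.seed(seed)
  if (stratified) {
    # deal each class round-robin, starting from the currently least-filled
    # folds so that total fold sizes also stay within one subject
    counts <- integer(n_folds)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < n_folds)
        stop_mmfuse(sprintf("class %s has %d subjects, fewer than %d folds",
                            cl, length(idx), n_folds), "mmfuse_config_error")
      idx <- idx[sample.int(length(idx))]
      fold_order <- order(counts, seq_len(n_folds))
      a <- rep_len(fold_order, length(idx))
      assignment[idx] <- a
      counts <- counts + tabulate(a, n_folds)
    }
  } else {
    assignment <- rep_len(seq_len(n_folds), n)[sample.int(n)]
  }
  structure(list(assignment = assignment, n_folds = as.integer(n_folds),
                 stratified = stratified, seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: %d folds over %d subjects (%s, seed %d)\n",
              x$n_folds, length(x$assignment),
              if (x$stratified) "stratified" else "unstratified", x$seed))
  invisible(x)
}
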