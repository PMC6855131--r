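# Redundancy analysis: how much of the predictive information of one map
# type is already contained in another, estimated from test-set correctness
# indicators pooled over all cross-validation folds. For maps M1 and M2
# with marginal success probabilities P(M1), P(M2) and conditional success
# P(M2|M1), the redundancy score is
#
#     RSC(M2|M1) = (P(M2|M1) - P(M2)) / (1 - P(M2)),
#
# which is 1 under total redundancy (every M1 success is an M2 success) and
# 0 under complete independence. The score is asymmetric in its arguments.

check_correct_pair <- function(correct_1, correct_2) {
  if (length(correct_1) != length(correct_2))
    stop_mmfuse("correctness vectors differ in length", "mmfuse_incompatible_data_error")
  if (!all(correct_1 %in% 0:1) || !all(correct_2 %in% 0:1))
    stop_mmfuse("correctness vectors must be binary", "mmfuse_argument_error")
}

#' Conditional classification-success probability
#'
#' Estimates `P(M2 correct | M1 correct)` from paired correctness
#' indicators: the number of subjects both maps classify correctly divided
#' by the number map 1 classifies correctly.
#'
#' @param correct_1,correct_2 Binary vectors (1 = correctly classified),
#'   aligned subject by subject.
#' @return A probability in `[0, 1]`.
#' @export
conditional_probability <- function(correct_1, correct_2) {
  check_correct_pair(correct_1, correct_2)
  n1 <- sum(correct_1 == 1)
  if (n1 == 0)
    stop_mmfuse("conditional probability undefined: map 1 never classifies correctly",
                "mmfuse_undefined_conditional_error")
  sum(correct_1 == 1 & correct_2 == 1) / n1
}

#' Redundancy score between two maps' correctness indicators
#'
#' @inheritParams conditional_probability
#' @return A list of class `redundancy_result`: contingency counts `n_11`,
#'   `n_10`, `n_01`, `n_00`, the marginal `p_m2`, the conditional
#'   `p_m2_given_m1`, the score `rsc` and a logical `anti_redundant` flag
#'   (negative finite-sample estimates are reported unclipped).
#' @export
redundancy_score <- function(correct_1, correct_2) {
  check_correct_pair(correct_1, correct_2)
  n_11 <- sum(correct_1 == 1 & correct_2 == 1)
  n_10 <- sum(correct_1 == 1 & correct_2 == 0)
  n_01 <- sum(correct_1 == 0 & correct_2 == 1)
  n_00 <- sum(correct_1 == 0 & correct_2 == 0)
  if (n_11 + n_10 == 0)
    stop_mmfuse("conditional probability undefined: map 1 never classifies correctly",
                "mmfuse_undefined_conditional_error")
  p_m2 <- (n_11 + n_01) / (n_11 + n_10 + n_01 + n_00)
  p_cond <- n_11 / (n_11 + n_10)
  if (p_m2 >= 1)
    stop_mmfuse("redundancy score undefined: map 2 always classifies correctly (P = 1)",
                "mmfuse_undefined_score_error")
  rsc <- (p_cond - p_m2) / (1 - p_m2)
  structure(list(n_11 = n_11, n_10 = n_10, n_01 = n_01, n_00 = n_00,
                 p_m2 = p_m2, p_m2_given_m1 = p_cond, rsc = rsc,
                 anti_redundant = rsc < 0),
            class = "redundancy_result")
}

#' @export
print.redundancy_result <- function(x, ...) {
  cat(sprintf("RSC = %.4f  (P(M2|M1) = %.4f, P(M2) = %.4f; counts %d/%d/%d/%d)%s\n",
              x$rsc, x$p_m2_given_m1, x$p_m2, x$n_11, x$n_10, x$n_01, x$n_00,
              if (x$anti_redundant) "  [anti-redundant]" else ""))
  invisible(x)
}

#' Redundancy matrix over all ordered source pairs
#'
#' For every ordered pair of sources (modalities or strategies) sharing the
#' same subject set in the prediction table, estimates the conditional
#' success probability and RSC from pooled test correctness. Undefined
#' pairs (no M1 success, or P(M2) = 1) are reported as `NA` with a reason,
#' never silently as zero. Row convention: `m1` is the conditioning map.
#'
#' @param table A `prediction_table` containing at least two sources for
#'   `algorithm`.
#' @param algorithm Classifier family to extract.
#' @return Data frame in ordered-pair long format: `m1`, `m2`, the four
#'   contingency counts, `p_m2`, `p_m2_given_m1`, `rsc`, `anti_redundant`,
#'   `undefined_reason`.
#' @export
redundancy_matrix <- function(table, algorithm) {
  tab <- as.data.frame(table)[as.data.frame(table)$algorithm == algorithm, ]
  sources <- unique(tab$source)
  if (length(sources) < 2)
    stop_mmfuse("need at least two sources for a redundancy matrix",
                "mmfuse_config_error")
  ref <- sort(tab$subject[tab$source == sources[1]])
  vecs <- lapply(sources, function(s) {
    g <- tab[tab$source == s, ]
    if (!identical(sort(g$subject), ref))
      stop_mmfuse("subject sets differ across sources", "mmfuse_alignment_error")
    g$correct[order(g$subject)]
  })
  names(vecs) <- sources
  pairs <- expand.grid(m1 = sources, m2 = sources, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$m1 != pairs$m2, ]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    c1 <- vecs[[pairs$m1[i]]]
    c2 <- vecs[[pairs$m2[i]]]
    res <- tryCatch(redundancy_score(c1, c2), mmfuse_error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(m1 = pairs$m1[i], m2 = pairs$m2[i],
                 n_11 = NA, n_10 = NA, n_01 = NA, n_00 = NA,
                 p_m2 = NA, p_m2_given_m1 = NA, rsc = NA,
                 anti_redundant = NA,
                 undefined_reason = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(m1 = pairs$m1[i], m2 = pairs$m2[i],
                 n_11 = res$n_11, n_10 = res$n_10, n_01 = res$n_01,
                 n_00 = res$n_00, p_m2 = res$p_m2,
                 p_m2_given_m1 = res$p_m2_given_m1, rsc = res$rsc,
                 anti_redundant = res$anti_redundant,
                 undefined_reason = NA_character_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean redundancy score over all defined ordered pairs
#' @param matrix_df Output of [redundancy_matrix()].
#' @return Mean of the defined `rsc` values.
#' @export
mean_rsc <- function(matrix_df) mean(matrix_df$rsc, na.rm = TRUE)
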