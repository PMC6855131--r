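#' Derive a reproducible component seed from a global seed
#'
#' A single experiment seed is expanded into per-component seeds by hashing
#' the component labels (FNV-1a, 32-bit) and folding the result into the
#' global seed. The result is always a strictly positive value below 2^31,
#' valid for [set.seed()].
#'
#' @param seed Integer global seed.
#' @param ... Character or numeric labels identifying the component (e.g.
#'   `"unimodal"`, a modality name, a fold id).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  label <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                        character(1)), collapse = "/")
  # FNV-1a over the label bytes, arithmetic kept in doubles (< 2^53 safe)
  h <- 2166136261
  for (b in utf8ToInt(label)) {
    h <- bitwXor64(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  out <- (abs(seed) * 2654435761 + h) %% 2147483647
  as.integer(out) + 1L
}

# xor of two non-negative doubles < 2^32 without 32-bit integer overflow
bitwXor64 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mmfuse <- function(msg, class) {
  stop(structure(class = c(class, "mmfuse_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
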