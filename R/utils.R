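# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible 32-bit substream seed from a root seed and a label.
# Stages of the pipeline each draw their own substream so that inserting a
# stage never perturbs the randomness of the others.
#' @noRd
substream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_that <- function(cond, fmt, ...) if (!isTRUE(cond)) stopf(fmt, ...)

# Stratified k-fold assignment: each class is shuffled and dealt round-robin.
#' @noRd
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
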