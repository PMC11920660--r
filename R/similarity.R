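#' Levenshtein distance
#'
#' Minimum number of single-character insertions, deletions and substitutions
#' transforming one string into the other, counted in characters (not bytes),
#' so multibyte Japanese text is handled correctly.
#'
#' @param w1,w2 Character vectors (recycled to common length).
#' @return Integer vector of edit distances.
#' @export
#' @examples
#' levenshtein("頭痛", "偏頭痛")
levenshtein <- function(w1, w2) {
  d <- utils::adist(w1, w2, costs = 1L, useBytes = FALSE)
  if (length(w1) == length(w2)) as.integer(diag_or_vec(d)) else as.integer(d)
}

diag_or_vec <- function(m) {
  if (nrow(m) == ncol(m)) diag(m) else as.vector(m)
}

#' Surface similarity between two strings
#'
#' The normalized Levenshtein similarity used for partial-match scoring:
#' \deqn{similarity(W_1, W_2) = \frac{\max(|W_1|,|W_2|) - LD(W_1, W_2)}{\max(|W_1|,|W_2|)}}
#' where \eqn{|W|} is the character length and LD the Levenshtein distance.
#' Values lie in \[0, 1\]; 1 means the strings are identical, 0 means they
#' share nothing.  The full-width asterisk used for unknown-character masking
#' is treated as an ordinary character.
#'
#' @param w1,w2 Character scalars or vectors (recycled).
#' @return A tibble with columns `value`, `max_len`, `distance`.
#' @export
#' @examples
#' similarity("ふらつき", "ふらふら")
similarity <- function(w1, w2) {
  n <- max(length(w1), length(w2))
  w1 <- rep_len(w1, n); w2 <- rep_len(w2, n)
  l1 <- chr_len(w1); l2 <- chr_len(w2)
  ml <- pmax(l1, l2)
  if (any(ml == 0)) abort_bad_arg("similarity is undefined when both strings are empty")
  d <- levenshtein(w1, w2)
  tibble::tibble(value = (ml - d) / ml, max_len = as.integer(ml),
                 distance = as.integer(d))
}

# Scalar similarity value (internal fast path).
similarity_value <- function(w1, w2) {
  ml <- pmax(chr_len(w1), chr_len(w2))
  (ml - levenshtein(w1, w2)) / ml
}

#' Mask out-of-vocabulary characters
#'
#' Replaces every character not in `vocab` with the full-width asterisk
#' `"＊"`, mirroring the unknown-token masking applied before surface
#' similarity is computed (the tagger emits the same placeholder for
#' characters it has never seen in training).
#'
#' @param x Character vector.
#' @param vocab Character vector of known characters, or `NULL` for no
#'   masking.
#' @return `x` with unknown characters replaced.
#' @export
mask_unknown <- function(x, vocab) {
  if (is.null(vocab)) return(x)
  vapply(x, function(s) {
    chars <- stringr::str_split(s, "")[[1]]
    chars[!chars %in% vocab] <- "＊"
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
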