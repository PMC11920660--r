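#' Character-window feature configuration
#'
#' The tagger scores each character position from sparse features of a small
#' window around it: character n-grams keyed by their relative offset, plus
#' coarse character-class features (kanji / kana / latin / digit / symbol).
#' These features stand behind the emission contract of the tagger; a dense
#' encoder can replace them without touching training or decoding.
#'
#' @param window_radius Window half-width in characters (0-5, default 2).
#' @param ngram_orders Integer vector of n-gram orders (default `c(1, 2)`).
#' @param use_char_class Include character-class features?
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(window_radius = 2L, ngram_orders = c(1L, 2L),
                           use_char_class = TRUE) {
  stopifnot(window_radius >= 0, window_radius <= 5, all(ngram_orders >= 1))
  structure(list(window_radius = as.integer(window_radius),
                 ngram_orders = sort(unique(as.integer(ngram_orders))),
                 use_char_class = isTRUE(use_char_class)),
            class = "feature_config")
}

# Coarse character class used both as a feature and as the only information
# retained about out-of-vocabulary characters.
char_class <- function(chars) {
  dplyr::case_when(
    chars >= "一" & chars <= "鿿" ~ "kanji",
    (chars >= "぀" & chars <= "ヿ") | chars == "ー" ~ "kana",
    (chars >= "ａ" & chars <= "ｚ") | (chars >= "Ａ" & chars <= "Ｚ") |
      (chars >= "a" & chars <= "z") | (chars >= "A" & chars <= "Z") ~ "latin",
    (chars >= "０" & chars <= "９") | (chars >= "0" & chars <= "9") ~ "digit",
    TRUE ~ "symbol")
}

#' Extract per-position features for a sentence
#'
#' Deterministically maps each character position to a set of feature
#' strings: for every offset `o` in `-r..r` and order `n` in `ngram_orders`,
#' the n-gram starting at position `t + o` (when fully inside the sentence),
#' keyed as `"o:n:gram"`, plus one class feature `"c:o:class"` per in-bounds
#' offset.  Features containing characters never seen in training simply do
#' not match any model feature, so an out-of-vocabulary character contributes
#' its class features only.
#'
#' @param text Character scalar (a normalized sentence).
#' @param config A [feature_config()].
#' @return A list of length `nchar(text)`; element `t` is the character
#'   vector of feature strings active at position `t`.
#' @export
featurize <- function(text, config = feature_config()) {
  stopifnot(length(text) == 1L)
  T_ <- chr_len(text)
  if (T_ == 0) return(list())
  r <- config$window_radius
  pos <- seq_len(T_)
  slots <- list()
  for (o in -r:r) {
    for (n in config$ngram_orders) {
      from <- pos + o
      to <- from + n - 1L
      gram <- ifelse(from >= 1L & to <= T_,
                     stringr::str_sub(text, from, to), NA_character_)
      slots[[length(slots) + 1L]] <-
        ifelse(is.na(gram), NA_character_, paste0(o, ":", n, ":", gram))
    }
    if (config$use_char_class) {
      from <- pos + o
      cls <- ifelse(from >= 1L & from <= T_,
                    char_class(stringr::str_sub(text, from, from)),
                    NA_character_)
      slots[[length(slots) + 1L]] <-
        ifelse(is.na(cls), NA_character_, paste0("c:", o, ":", cls))
    }
  }
  m <- do.call(rbind, slots)  # n_slots x T
  lapply(seq_len(T_), function(t) {
    f <- m[, t]
    f[!is.na(f)]
  })
}
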