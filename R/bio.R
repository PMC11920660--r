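#' BIO label set for joint span and polarity tagging
#'
#' The tagger folds the affirmed/denied decision into the span labels, so
#' extraction and positive-negative classification are a single sequence
#' labeling task.  Tag order is `O`, `B-POS`, `I-POS`, `B-NEG`, `I-NEG`;
#' `O` comes first and is the tie-break default.
#'
#' @return Character vector of the five tags, in canonical order.
#' @export
bio_labels <- function() c("O", "B-POS", "I-POS", "B-NEG", "I-NEG")

polarity_of_tag <- function(tag) {
  ifelse(grepl("POS$", tag), "positive",
         ifelse(grepl("NEG$", tag), "negative", NA_character_))
}

tag_for <- function(kind, polarity) {
  paste0(kind, "-", ifelse(polarity == "positive", "POS", "NEG"))
}

#' Convert between a corpus and a character-level BIO table
#'
#' `to_bio()` expands each sentence to one row per character with its BIO
#' polarity tag; `from_bio()` is the inverse and reconstructs spans (with
#' surfaces) from the tags.  The two functions are a bijection on corpora
#' whose entities do not overlap.  `from_bio()` rejects an illegal tag
#' transition (`I-x` not preceded by `B-x` or `I-x`) and reports its row.
#'
#' @param corpus An [ann_corpus].
#' @param bio A tibble as produced by `to_bio()`: columns `record_id`,
#'   `index`, `pos` (0-based character position), `char`, `tag`.
#' @return `to_bio()`: the character-tag tibble. `from_bio()`: an
#'   [ann_corpus].
#' @export
#' @examples
#' s <- tibble::tibble(record_id = "r1", index = 0L, text = "頭痛なし")
#' e <- tibble::tibble(record_id = "r1", index = 0L, start = 0L, end = 2L,
#'                     surface = "頭痛", polarity = "negative")
#' to_bio(ann_corpus(s, e))
to_bio <- function(corpus) {
  stopifnot(inherits(corpus, "ann_corpus"))
  s <- corpus$sentences
  tags <- gold_tags(corpus)
  purrr::map_dfr(seq_len(nrow(s)), function(i) {
    chars <- stringr::str_split(s$text[i], "")[[1]]
    tibble::tibble(record_id = s$record_id[i], index = s$index[i],
                   pos = seq_along(chars) - 1L, char = chars,
                   tag = tags[[i]])
  })
}

# Per-sentence gold tag sequences (list aligned with corpus$sentences rows).
gold_tags <- function(corpus) {
  s <- corpus$sentences
  e <- corpus$entities
  skey <- sentence_key(s$record_id, s$index)
  ekey <- sentence_key(e$record_id, e$index)
  lapply(seq_len(nrow(s)), function(i) {
    n <- chr_len(s$text[i])
    tags <- rep("O", n)
    for (j in which(ekey == skey[i])) {
      rng <- (e$start[j] + 1L):e$end[j]
      tags[rng] <- tag_for("I", e$polarity[j])
      tags[rng[1]] <- tag_for("B", e$polarity[j])
    }
    tags
  })
}

#' @rdname to_bio
#' @export
from_bio <- function(bio) {
  bio <- tibble::as_tibble(bio)
  stopifnot(all(c("record_id", "index", "pos", "char", "tag") %in% names(bio)))
  if (!all(bio$tag %in% bio_labels())) {
    abort_bad_arg("unknown tag at row %d", which(!bio$tag %in% bio_labels())[1])
  }
  key <- sentence_key(bio$record_id, bio$index)
  # validate transitions within sentences, in row order
  prev_key <- c("", key[-length(key)])
  prev_tag <- c("O", bio$tag[-length(bio$tag)])
  prev_tag[key != prev_key] <- "O"
  is_i <- grepl("^I-", bio$tag)
  need <- sub("^I", "", bio$tag)
  ok <- !is_i | prev_tag == paste0("B", need) | prev_tag == paste0("I", need)
  if (!all(ok)) {
    abort_bad_arg("illegal tag transition %s -> %s at row %d",
                  prev_tag[!ok][1], bio$tag[!ok][1], which(!ok)[1])
  }
  grp <- split(seq_len(nrow(bio)), factor(key, levels = unique(key)))
  sent <- purrr::map_dfr(grp, function(rows) {
    rows <- rows[order(bio$pos[rows])]
    tibble::tibble(record_id = bio$record_id[rows[1]],
                   index = bio$index[rows[1]],
                   text = paste(bio$char[rows], collapse = ""))
  })
  ents <- purrr::map_dfr(grp, function(rows) {
    rows <- rows[order(bio$pos[rows])]
    spans_from_tags(bio$tag[rows],
                    paste(bio$char[rows], collapse = ""),
                    bio$record_id[rows[1]], bio$index[rows[1]])
  })
  if (nrow(ents) == 0) ents <- empty_entities()
  ann_corpus(sent, ents)
}

# Decode maximal B-x (I-x)* runs into an entity tibble. Orphan I-x (only
# possible when decoding model output) is promoted to B-x.
spans_from_tags <- function(tags, text, record_id, index) {
  n <- length(tags)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (tags[i] == "O") { i <- i + 1L; next }
    pol <- polarity_of_tag(tags[i])
    start <- i - 1L
    i <- i + 1L
    while (i <= n && tags[i] == tag_for("I", pol)) i <- i + 1L
    out[[length(out) + 1L]] <- tibble::tibble(
      record_id = record_id, index = index,
      start = start, end = i - 1L,
      surface = substr0(text, start, i - 1L), polarity = pol)
  }
  if (!length(out)) return(empty_entities())
  dplyr::bind_rows(out)
}

#' Write a BIO table as CoNLL-style TSV
#'
#' Two tab-separated columns (character, tag), with a blank line between
#' sentences.
#'
#' @param bio A BIO tibble from [to_bio()].
#' @param path Output file path.
#' @export
write_bio_tsv <- function(bio, path) {
  key <- sentence_key(bio$record_id, bio$index)
  grp <- split(seq_len(nrow(bio)), factor(key, levels = unique(key)))
  blocks <- purrr::map_chr(grp, function(rows) {
    rows <- rows[order(bio$pos[rows])]
    paste(paste0(bio$char[rows], "\t", bio$tag[rows]), collapse = "\n")
  })
  writeLines(enc2utf8(paste(blocks, collapse = "\n\n")), path, useBytes = TRUE)
  invisible(bio)
}
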