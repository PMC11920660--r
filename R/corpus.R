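#' Annotated corpus of sentences and entity spans
#'
#' The central container of the pipeline: a set of normalized sentences plus
#' standoff entity annotations.  `sentences` is a tibble with columns
#' `record_id`, `index` (0-based position within the record) and `text`;
#' `entities` is a tibble with columns `record_id`, `index`, `start`, `end`
#' (0-based, half-open character offsets into the sentence), `surface` (the
#' annotated substring) and `polarity` (`"positive"` = affirmed,
#' `"negative"` = denied).
#'
#' Invariants enforced at construction: sentences are non-empty, contain no
#' line breaks and no `"_X000D_"` marker, and are unique per
#' (`record_id`, `index`); every entity resolves to an existing sentence;
#' `0 <= start < end <= nchar(text)`; `surface` equals the sentence substring;
#' entities within one sentence do not overlap.
#'
#' @param sentences Tibble of sentences (see Details).
#' @param entities Tibble of entity spans; defaults to none.
#' @return An object of class `ann_corpus` (a list of the two tibbles).
#' @export
#' @examples
#' s <- tibble::tibble(record_id = "r1", index = 0L, text = "頭痛なし")
#' e <- tibble::tibble(record_id = "r1", index = 0L, start = 0L, end = 2L,
#'                     surface = "頭痛", polarity = "negative")
#' ann_corpus(s, e)
ann_corpus <- function(sentences, entities = empty_entities()) {
  sentences <- tibble::as_tibble(sentences)[, c("record_id", "index", "text")]
  sentences$record_id <- as.character(sentences$record_id)
  sentences$index <- as.integer(sentences$index)
  entities <- tibble::as_tibble(entities)[, c("record_id", "index", "start",
                                              "end", "surface", "polarity")]
  entities$record_id <- as.character(entities$record_id)
  entities$index <- as.integer(entities$index)
  entities$start <- as.integer(entities$start)
  entities$end <- as.integer(entities$end)
  obj <- structure(list(sentences = sentences, entities = entities),
                   class = "ann_corpus")
  validate_corpus(obj)
  obj
}

#' @rdname ann_corpus
#' @export
empty_entities <- function() {
  tibble::tibble(record_id = character(), index = integer(),
                 start = integer(), end = integer(),
                 surface = character(), polarity = character())
}

sentence_key <- function(record_id, index) paste0(record_id, "#", index)

validate_corpus <- function(corpus) {
  s <- corpus$sentences
  e <- corpus$entities
  if (anyDuplicated(sentence_key(s$record_id, s$index))) {
    abort_bad_arg("duplicate (record_id, index) in sentences")
  }
  bad <- which(is.na(s$text) | s$text == "" |
                 stringr::str_detect(s$text, "[\r\n]") |
                 stringr::str_detect(s$text, stringr::fixed("_X000D_")))
  if (length(bad)) {
    abort_bad_arg("invalid sentence text at row %d (empty, line break, or _X000D_)",
                  bad[1])
  }
  if (nrow(e) == 0) return(invisible(corpus))
  if (!all(e$polarity %in% c("positive", "negative"))) {
    abort_bad_arg("entity polarity must be \"positive\" or \"negative\"")
  }
  skey <- sentence_key(s$record_id, s$index)
  ekey <- sentence_key(e$record_id, e$index)
  miss <- which(!ekey %in% skey)
  if (length(miss)) {
    abort_bad_arg("entity %d refers to unknown sentence %s", miss[1], ekey[miss[1]])
  }
  txt <- s$text[match(ekey, skey)]
  len <- chr_len(txt)
  bad <- which(e$start < 0L | e$end <= e$start | e$end > len)
  if (length(bad)) {
    abort_bad_arg("entity %d has invalid offsets [%d,%d) in sentence of length %d",
                  bad[1], e$start[bad[1]], e$end[bad[1]], len[bad[1]])
  }
  slice <- substr0(txt, e$start, e$end)
  bad <- which(slice != e$surface)
  if (length(bad)) {
    abort_bad_arg(
      "entity %d surface %s does not match sentence substring %s",
      bad[1], dQuote(e$surface[bad[1]], FALSE), dQuote(slice[bad[1]], FALSE))
  }
  # non-overlap within a sentence
  ord <- order(ekey, e$start)
  ek <- ekey[ord]; st <- e$start[ord]; en <- e$end[ord]
  n <- length(ek)
  if (n > 1) {
    same <- ek[-1] == ek[-n]
    ovl <- which(same & st[-1] < en[-n])
    if (length(ovl)) {
      abort_bad_arg("overlapping entities in sentence %s", ek[ovl[1] + 1])
    }
  }
  invisible(corpus)
}

#' @export
print.ann_corpus <- function(x, ...) {
  st <- corpus_stats(x)
  cat(sprintf(
    "<ann_corpus> %d records, %d sentences, %d entities (%d affirmed / %d denied)\n",
    st$n_records, st$n_sentences, st$n_affirmed + st$n_denied,
    st$n_affirmed, st$n_denied))
  invisible(x)
}

#' @export
as_tibble.ann_corpus <- function(x, ...) {
  dplyr::left_join(
    x$sentences,
    tidyr::nest(x$entities, entities = c("start", "end", "surface", "polarity")),
    by = c("record_id", "index"))
}

#' Corpus summary statistics
#'
#' Counts records, sentences and entities by polarity, the shape statistics
#' used to describe a training corpus (e.g. 12,004 records / 43,553 sentences
#' with 12,287 affirmed and 8,822 denied mentions for a year of pharmaceutical
#' care records).
#'
#' @param corpus An [ann_corpus].
#' @return A one-row tibble with columns `n_records`, `n_sentences`,
#'   `n_entities`, `n_affirmed`, `n_denied`.
#' @export
corpus_stats <- function(corpus) {
  stopifnot(inherits(corpus, "ann_corpus"))
  tibble::tibble(
    n_records = dplyr::n_distinct(corpus$sentences$record_id),
    n_sentences = nrow(corpus$sentences),
    n_entities = nrow(corpus$entities),
    n_affirmed = sum(corpus$entities$polarity == "positive"),
    n_denied = sum(corpus$entities$polarity == "negative"))
}

#' Read and write corpora as standoff JSON Lines
#'
#' The interchange format is UTF-8 JSON Lines with one object per sentence:
#' `{"record_id": str, "index": int, "text": str, "entities":
#' [{"start": int, "end": int, "surface": str, "polarity": str}]}`.
#' `read_corpus()` validates every span against the sentence text and reports
#' the offending line on failure; `write_corpus()` is its inverse, so a
#' round trip reproduces the corpus exactly.
#'
#' @param path File path.
#' @param corpus An [ann_corpus].
#' @return `read_corpus()` returns an [ann_corpus]; `write_corpus()` returns
#'   `corpus` invisibly.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  parsed <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(obj) || is.null(obj$record_id) || is.null(obj$index) ||
        is.null(obj$text)) {
      abort_bad_arg("malformed corpus JSONL at line %d of %s", i, path)
    }
    parsed[[i]] <- obj
  }
  sent <- tibble::tibble(
    record_id = purrr::map_chr(parsed, ~ as.character(.x$record_id)),
    index = purrr::map_int(parsed, ~ as.integer(.x$index)),
    text = purrr::map_chr(parsed, ~ as.character(.x$text)))
  ent <- purrr::map2_dfr(parsed, seq_along(parsed), function(obj, i) {
    es <- obj$entities
    if (is.null(es) || length(es) == 0) return(empty_entities())
    tibble::tibble(
      record_id = as.character(obj$record_id),
      index = as.integer(obj$index),
      start = purrr::map_int(es, ~ as.integer(.x$start)),
      end = purrr::map_int(es, ~ as.integer(.x$end)),
      surface = purrr::map_chr(es, ~ as.character(.x$surface)),
      polarity = purrr::map_chr(es, ~ as.character(.x$polarity)))
  })
  if (nrow(ent) == 0) ent <- empty_entities()
  ann_corpus(sent, ent)
}

#' @rdname read_corpus
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "ann_corpus"))
  s <- corpus$sentences
  e <- corpus$entities
  ekey <- sentence_key(e$record_id, e$index)
  skey <- sentence_key(s$record_id, s$index)
  lines <- character(nrow(s))
  for (i in seq_len(nrow(s))) {
    rows <- which(ekey == skey[i])
    rows <- rows[order(e$start[rows])]
    ents <- lapply(rows, function(j) {
      list(start = e$start[j], end = e$end[j],
           surface = e$surface[j], polarity = e$polarity[j])
    })
    lines[i] <- jsonlite::toJSON(
      list(record_id = s$record_id[i], index = s$index[i], text = s$text[i],
           entities = ents),
      auto_unbox = TRUE)
  }
  writeLines(enc2utf8(lines), path, useBytes = TRUE)
  invisible(corpus)
}

# Subset a corpus to a set of sentence keys (character vector record_id#index).
corpus_subset <- function(corpus, keys) {
  s <- corpus$sentences
  e <- corpus$entities
  keep_s <- sentence_key(s$record_id, s$index) %in% keys
  keep_e <- sentence_key(e$record_id, e$index) %in% keys
  structure(list(sentences = s[keep_s, ], entities = e[keep_e, ]),
            class = "ann_corpus")
}

# Drop all entities (for handing a corpus to a tagger as plain text).
corpus_strip_entities <- function(corpus) {
  structure(list(sentences = corpus$sentences, entities = empty_entities()),
            class = "ann_corpus")
}
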