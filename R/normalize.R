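#' Normalize clinical text to full-width characters
#'
#' Prepares raw record text for annotation and tagging: the export artifact
#' `"_X000D_"` (a carriage-return marker left behind by spreadsheet exports of
#' electronic medical records) is removed, and all half-width ASCII
#' letters/digits/punctuation and half-width katakana are converted to their
#' full-width (2-byte) equivalents, including dakuten/handakuten composition
#' (so `"ｶﾞ"` becomes `"ガ"`).  The ASCII space becomes the ideographic space.
#'
#' The transform is idempotent: applying it twice gives the same result.
#'
#' @param raw Character vector of raw text.
#' @param x000d How to treat the literal `"_X000D_"` marker: `"delete"`
#'   (default) removes it outright; `"newline"` replaces it with a line break
#'   so that [split_sentences()] treats it as a sentence boundary.
#' @return Character vector of normalized full-width text.
#' @export
#' @examples
#' normalize_text("abc_X000D_def")
#' normalize_text("ﾒﾏｲ 3mg")
normalize_text <- function(raw, x000d = c("delete", "newline")) {
  x000d <- match.arg(x000d)
  stopifnot(is.character(raw))
  rep_with <- if (x000d == "delete") "" else "\n"
  # Remove the marker in both raw and already-widened form so the transform
  # stays idempotent.
  out <- stringr::str_replace_all(raw, stringr::fixed("_X000D_"), rep_with)
  out <- stringr::str_replace_all(out, stringr::fixed("＿Ｘ０００Ｄ＿"), rep_with)
  stringi::stri_trans_general(out, "Halfwidth-Fullwidth")
}

# Characters treated as blank when trimming sentence edges.
SPACE_CLASS <- "[\\s　]"

#' Split a record into normalized sentences
#'
#' Segments record text at line breaks and at full-width sentence periods
#' (the ideographic full stop \code{"。"} and the full-width period
#' \code{"．"}).  A full-width period flanked by full-width digits on both
#' sides is not treated as a boundary, so decimal laboratory values survive.
#' The terminal period stays attached to its sentence.  Leading and trailing
#' spaces (ASCII and ideographic) are stripped and blank segments are dropped.
#'
#' @param text Character scalar: the record text (normalized with
#'   [normalize_text()] first if `normalize = TRUE`, the default).
#' @param record_id Identifier copied onto each output row.
#' @param normalize Apply [normalize_text()] before splitting?
#' @param x000d Passed to [normalize_text()].
#' @return A tibble with columns `record_id`, `index` (0-based sentence
#'   position within the record) and `text`.
#' @export
#' @examples
#' split_sentences("頭痛。吐き気はない")
split_sentences <- function(text, record_id = "r1", normalize = TRUE,
                            x000d = c("delete", "newline")) {
  stopifnot(length(text) == 1L)
  if (normalize) text <- normalize_text(text, x000d = x000d)
  pieces <- stringr::str_split(text, "\\r\\n|\\r|\\n")[[1]]
  segs <- unlist(lapply(pieces, split_at_periods), use.names = FALSE)
  segs <- stringr::str_remove_all(segs, paste0("^", SPACE_CLASS, "+|", SPACE_CLASS, "+$"))
  segs <- segs[segs != ""]
  tibble::tibble(
    record_id = rep(as.character(record_id), length(segs)),
    index = seq_along(segs) - 1L,
    text = segs
  )
}

# Split one line after each sentence period, keeping the period, with a
# digit guard for decimal values written with the full-width period.
split_at_periods <- function(line) {
  if (is.na(line) || line == "") return(character())
  chars <- stringr::str_split(line, "")[[1]]
  n <- length(chars)
  is_digit <- chars >= "０" & chars <= "９"
  cut <- which(chars %in% c("。", "．"))
  if (length(cut)) {
    guarded <- chars[cut] == "．" &
      cut > 1L & cut < n &
      is_digit[pmax(cut - 1L, 1L)] & is_digit[pmin(cut + 1L, n)]
    cut <- cut[!guarded]
  }
  starts <- c(1L, cut + 1L)
  ends <- c(cut, n)
  keep <- starts <= ends
  mapply(function(s, e) paste(chars[s:e], collapse = ""),
         starts[keep], ends[keep], USE.NAMES = FALSE)
}

#' Read raw records from TSV
#'
#' Reads the raw-record interchange format: a UTF-8 TSV with columns
#' `record_id`, `source_field` and `text`, where line breaks inside `text`
#' are escaped as the two characters `"\\n"`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `record_id`, `source_field`, `text`.
#' @export
read_raw_records <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", fileEncoding = "UTF-8")
  need <- c("record_id", "source_field", "text")
  if (!all(need %in% names(df))) {
    abort_bad_arg("raw record TSV must have columns %s", paste(need, collapse = ", "))
  }
  df$text <- stringr::str_replace_all(df$text, stringr::fixed("\\n"), "\n")
  tibble::as_tibble(df[need])
}

#' Preprocess raw records into a corpus skeleton
#'
#' Applies [normalize_text()] and [split_sentences()] to every record and
#' returns an (entity-free) annotated corpus ready for annotation import or
#' tagging.
#'
#' @param records A data frame with columns `record_id` and `text` (e.g. from
#'   [read_raw_records()]).
#' @param x000d Passed to [normalize_text()].
#' @return An [ann_corpus] with no entities.
#' @export
preprocess_records <- function(records, x000d = c("delete", "newline")) {
  x000d <- match.arg(x000d)
  if (anyDuplicated(records$record_id)) {
    abort_bad_arg("duplicate record_id in raw records")
  }
  sent <- purrr::map2_dfr(records$text, records$record_id,
                          function(tx, id) split_sentences(tx, id, x000d = x000d))
  ann_corpus(sent, empty_entities())
}
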