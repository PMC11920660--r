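#' Inter-annotator agreement (Cohen's kappa) for span annotation
#'
#' Chance-corrected agreement between two annotations of the same sentences.
#' Because free-span annotation has no predefined unit, agreement is computed
#' per character, with each character labeled `O`, `positive` (inside an
#' affirmed entity) or `negative` (inside a denied entity).  This is the
#' standard reduction that makes kappa well defined for span annotation;
#' double annotation of clinical narratives typically reaches kappa above
#' 0.9 with mature guidelines.
#'
#' @param ann_a,ann_b Two [ann_corpus] objects over the identical sentence
#'   set (same keys and same text).
#' @return A one-row tibble with `kappa`, `observed_agreement`,
#'   `expected_agreement` and `unit` (always `"character"`).
#' @export
#' @examples
#' s <- tibble::tibble(record_id = "r", index = 0L, text = "頭痛なし")
#' e <- tibble::tibble(record_id = "r", index = 0L, start = 0L, end = 2L,
#'                     surface = "頭痛", polarity = "negative")
#' cohen_kappa(ann_corpus(s, e), ann_corpus(s, e))
cohen_kappa <- function(ann_a, ann_b) {
  stopifnot(inherits(ann_a, "ann_corpus"), inherits(ann_b, "ann_corpus"))
  ka <- sentence_key(ann_a$sentences$record_id, ann_a$sentences$index)
  kb <- sentence_key(ann_b$sentences$record_id, ann_b$sentences$index)
  if (!setequal(ka, kb) || length(ka) != length(kb)) {
    abort_bad_arg("the two annotations cover different sentence sets")
  }
  ord_b <- match(ka, kb)
  if (!all(ann_a$sentences$text == ann_b$sentences$text[ord_b])) {
    abort_bad_arg("sentence texts differ between the two annotations")
  }
  lab_a <- unlist(char_labels(ann_a))
  lab_b <- unlist(char_labels(ann_b)[ord_b])
  stopifnot(length(lab_a) == length(lab_b))
  n <- length(lab_a)
  if (n == 0) abort_bad_arg("empty corpus")
  classes <- c("O", "positive", "negative")
  fa <- factor(lab_a, levels = classes)
  fb <- factor(lab_b, levels = classes)
  po <- mean(fa == fb)
  pe <- sum(prop.table(table(fa)) * prop.table(table(fb)))
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  tibble::tibble(kappa = kappa, observed_agreement = po,
                 expected_agreement = pe, unit = "character")
}

# Per-sentence character labels in {O, positive, negative}.
char_labels <- function(corpus) {
  lapply(gold_tags(corpus), function(tags) {
    out <- polarity_of_tag(tags)
    out[is.na(out)] <- "O"
    out
  })
}
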