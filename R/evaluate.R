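#' Matching configuration
#'
#' Controls how predicted entities are aligned with gold entities and scored.
#' `partial_threshold` is the similarity at or above which a non-identical
#' overlapping pair still counts as a (partial) match; 0.66 is the default,
#' chosen where incomplete extractions that drop essential terms start to
#' dominate.  `vocab` optionally supplies a character vocabulary for
#' unknown-character masking: both gold and predicted surfaces are passed
#' through [mask_unknown()] before similarity is computed.
#'
#' @param partial_threshold Similarity threshold in (0, 1], default 0.66.
#' @param pairing Pairing algorithm; only `"overlap_greedy"` is implemented.
#' @param unk_masking Apply unknown-character masking? Requires `vocab`.
#' @param vocab Character vector of in-vocabulary characters (e.g.
#'   `crf_model$char_vocab`), or `NULL`.
#' @return A list of class `match_config`.
#' @export
match_config <- function(partial_threshold = 0.66,
                         pairing = "overlap_greedy",
                         unk_masking = !is.null(vocab),
                         vocab = NULL) {
  stopifnot(partial_threshold > 0, partial_threshold <= 1)
  pairing <- match.arg(pairing, "overlap_greedy")
  if (unk_masking && is.null(vocab)) {
    abort_bad_arg("unk_masking = TRUE requires a vocab")
  }
  structure(list(partial_threshold = partial_threshold, pairing = pairing,
                 unk_masking = unk_masking, vocab = vocab),
            class = "match_config")
}

#' Pair predicted with gold entities by overlap and similarity
#'
#' Candidate pairs are a gold and a predicted entity in the same sentence
#' whose character spans overlap.  Pairs are assigned one-to-one greedily in
#' descending surface similarity, with ties broken by smaller gold start
#' offset, then smaller predicted start offset, so the assignment is
#' deterministic.  Leftover entities (including overlapping ones that lost
#' the assignment) stay unmatched; this implements the rule that when one
#' side extracts two terms where the other extracts one, the mismatch counts
#' once per extraction on the larger side.
#'
#' @param gold,pred Entity tibbles (columns `record_id`, `index`, `start`,
#'   `end`, `surface`, `polarity`).
#' @param config A [match_config()].
#' @return A list with `pairs` (tibble: `gold_id`, `pred_id`, `similarity`),
#'   `unmatched_gold` and `unmatched_pred` (integer row indices into `gold`
#'   and `pred`).
#' @export
pair_entities <- function(gold, pred, config = match_config()) {
  gkey <- sentence_key(gold$record_id, gold$index)
  pkey <- sentence_key(pred$record_id, pred$index)
  gsurf <- if (config$unk_masking) mask_unknown(gold$surface, config$vocab) else gold$surface
  psurf <- if (config$unk_masking) mask_unknown(pred$surface, config$vocab) else pred$surface

  cand <- NULL
  if (nrow(gold) && nrow(pred)) {
    shared <- intersect(unique(gkey), unique(pkey))
    cand <- purrr::map_dfr(shared, function(k) {
      gi <- which(gkey == k); pi <- which(pkey == k)
      grid <- expand.grid(gold_id = gi, pred_id = pi)
      keep <- gold$start[grid$gold_id] < pred$end[grid$pred_id] &
        pred$start[grid$pred_id] < gold$end[grid$gold_id]
      grid[keep, , drop = FALSE]
    })
  }
  if (is.null(cand) || nrow(cand) == 0) {
    return(list(pairs = tibble::tibble(gold_id = integer(), pred_id = integer(),
                                       similarity = double()),
                unmatched_gold = seq_len(nrow(gold)),
                unmatched_pred = seq_len(nrow(pred))))
  }
  cand$similarity <- similarity_value(gsurf[cand$gold_id], psurf[cand$pred_id])
  ord <- order(-cand$similarity, gold$start[cand$gold_id], pred$start[cand$pred_id],
               cand$gold_id, cand$pred_id)
  cand <- cand[ord, ]
  used_g <- logical(nrow(gold)); used_p <- logical(nrow(pred))
  take <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    g <- cand$gold_id[i]; p <- cand$pred_id[i]
    if (!used_g[g] && !used_p[p]) {
      take[i] <- TRUE; used_g[g] <- TRUE; used_p[p] <- TRUE
    }
  }
  list(pairs = tibble::as_tibble(cand[take, c("gold_id", "pred_id", "similarity")]),
       unmatched_gold = which(!used_g),
       unmatched_pred = which(!used_p))
}

#' Classify paired and unmatched entities into the error taxonomy
#'
#' Applies the decision table that crosses named-entity match status with
#' polarity (positive-negative) match status:
#' \itemize{
#' \item identical masked surface and span, polarity agrees: `correct_exact`;
#' \item similarity at or above the threshold (but not exact), polarity
#'   agrees: `correct_partial`;
#' \item exact or high-similarity surface but polarity disagrees: `error3`;
#' \item overlapping pair below the threshold with polarity agreeing:
#'   `error4`;
#' \item overlapping pair below the threshold with polarity disagreeing:
#'   dissolved into one `error1` (the missed gold entity) plus one `error2`
#'   (the spurious prediction), recorded as outcome `"error1_error2"`;
#' \item unmatched gold entity: `error1`; unmatched prediction: `error2`.
#' }
#'
#' @param gold,pred Entity tibbles as in [pair_entities()].
#' @param pairing The result of [pair_entities()].
#' @param config A [match_config()].
#' @return A tibble with one row per pair or unmatched entity: sentence key
#'   columns, gold/pred offsets and surfaces, `similarity`, `ner_status`
#'   (`exact`, `partial_high`, `partial_low`, `unmatched`),
#'   `polarity_match`, and `outcome`.
#' @export
classify_matches <- function(gold, pred, pairing, config = match_config()) {
  thr <- config$partial_threshold
  gsurf <- if (config$unk_masking) mask_unknown(gold$surface, config$vocab) else gold$surface
  psurf <- if (config$unk_masking) mask_unknown(pred$surface, config$vocab) else pred$surface
  pr <- pairing$pairs
  rows <- list()
  if (nrow(pr)) {
    g <- pr$gold_id; p <- pr$pred_id
    exact <- gsurf[g] == psurf[p] & gold$start[g] == pred$start[p] &
      gold$end[g] == pred$end[p]
    ner_status <- ifelse(exact, "exact",
                         ifelse(pr$similarity >= thr, "partial_high", "partial_low"))
    pol_ok <- gold$polarity[g] == pred$polarity[p]
    outcome <- dplyr::case_when(
      ner_status == "exact" & pol_ok ~ "correct_exact",
      ner_status == "partial_high" & pol_ok ~ "correct_partial",
      ner_status %in% c("exact", "partial_high") & !pol_ok ~ "error3",
      ner_status == "partial_low" & pol_ok ~ "error4",
      TRUE ~ "error1_error2")
    rows$pairs <- tibble::tibble(
      record_id = gold$record_id[g], index = gold$index[g],
      gold_start = gold$start[g], gold_end = gold$end[g],
      gold_surface = gsurf[g], gold_polarity = gold$polarity[g],
      pred_start = pred$start[p], pred_end = pred$end[p],
      pred_surface = psurf[p], pred_polarity = pred$polarity[p],
      similarity = pr$similarity, ner_status = ner_status,
      polarity_match = pol_ok, outcome = outcome)
  }
  if (length(pairing$unmatched_gold)) {
    g <- pairing$unmatched_gold
    rows$gold <- tibble::tibble(
      record_id = gold$record_id[g], index = gold$index[g],
      gold_start = gold$start[g], gold_end = gold$end[g],
      gold_surface = gsurf[g], gold_polarity = gold$polarity[g],
      pred_start = NA_integer_, pred_end = NA_integer_,
      pred_surface = NA_character_, pred_polarity = NA_character_,
      similarity = NA_real_, ner_status = "unmatched",
      polarity_match = NA, outcome = "error1")
  }
  if (length(pairing$unmatched_pred)) {
    p <- pairing$unmatched_pred
    rows$pred <- tibble::tibble(
      record_id = pred$record_id[p], index = pred$index[p],
      gold_start = NA_integer_, gold_end = NA_integer_,
      gold_surface = NA_character_, gold_polarity = NA_character_,
      pred_start = pred$start[p], pred_end = pred$end[p],
      pred_surface = psurf[p], pred_polarity = pred$polarity[p],
      similarity = NA_real_, ner_status = "unmatched",
      polarity_match = NA, outcome = "error2")
  }
  dplyr::bind_rows(rows)
}

#' Precision, recall and F1 from counts
#'
#' `precision = TP / n_pred`, `recall = TP / n_gold`,
#' `f1 = 2 * precision * recall / (precision + recall)`; any 0/0 is defined
#' as 0.
#'
#' @param n_gold,n_pred,tp Non-negative counts with `tp <= min(n_gold, n_pred)`.
#' @return A one-row tibble with `precision`, `recall`, `f1`.
#' @export
#' @examples
#' prf(100, 90, 80)
prf <- function(n_gold, n_pred, tp) {
  stopifnot(tp >= 0, n_gold >= tp, n_pred >= tp)
  precision <- if (n_pred > 0) tp / n_pred else 0
  recall <- if (n_gold > 0) tp / n_gold else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(precision = precision, recall = recall, f1 = f1)
}

#' F1 from a precision/recall pair
#'
#' @param precision,recall Numeric vectors in \[0, 1\].
#' @return `2 * precision * recall / (precision + recall)`, with 0/0 = 0.
#' @export
#' @examples
#' f1_score(0.81, 0.83)
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
}

#' Total number of extractions
#'
#' The denominator of the error rates: every extraction made by either the
#' annotators or the system counts once, except that a gold-prediction pair
#' matching exactly or with similarity at or above the threshold counts as a
#' single extraction:
#' `n_gold + n_pred - (n_exact + n_partial_high)`.
#'
#' @param n_gold,n_pred Total gold and predicted entity counts.
#' @param n_exact Number of exact matches.
#' @param n_partial_high Number of partial matches at or above the threshold.
#' @return Integer total.
#' @export
#' @examples
#' total_extractions(10, 9, 7, 1)
total_extractions <- function(n_gold, n_pred, n_exact, n_partial_high) {
  if (n_exact + n_partial_high > min(n_gold, n_pred)) {
    abort_bad_arg("matched pairs exceed the smaller entity count")
  }
  as.integer(n_gold + n_pred - (n_exact + n_partial_high))
}

#' Error rates from category counts
#'
#' `rate = count * 100 / total_extractions`, in percent, per category and
#' overall.
#'
#' @param counts Named numeric vector or list with elements `error1` ..
#'   `error4`.
#' @param total Total number of extractions (must be positive).
#' @return A tibble with columns `category`, `count`, `rate` (percent); the
#'   final row is the overall error rate.
#' @export
#' @examples
#' error_rates(c(error1 = 178, error2 = 280, error3 = 209, error4 = 278), 2963)
error_rates <- function(counts, total) {
  if (total <= 0) abort_bad_arg("total_extractions must be positive")
  cats <- c("error1", "error2", "error3", "error4")
  counts <- unname(unlist(counts)[cats])
  stopifnot(!anyNA(counts))
  tibble::tibble(
    category = c(cats, "overall"),
    count = as.integer(c(counts, sum(counts))),
    rate = c(counts, sum(counts)) * 100 / total,
    total_extractions = as.integer(total))
}

#' Variation of an error rate across two training amounts
#'
#' `variation = rate_after / rate_before * 100` (percent).  When the rate
#' before increasing the training amount is 0\% the variation is defined as
#' 100\%, and a no-change pair (including 0 to 0) also yields 100\%.
#'
#' @param rate_before,rate_after Error rates in percent (non-negative).
#' @return A tibble with `rate_before`, `rate_after`, `variation`.
#' @export
#' @examples
#' variation(9.4, 3.7)
variation <- function(rate_before, rate_after) {
  stopifnot(all(rate_before >= 0), all(rate_after >= 0))
  v <- ifelse(rate_before > 0, rate_after / rate_before * 100, 100)
  tibble::tibble(rate_before = rate_before, rate_after = rate_after,
                 variation = v)
}

#' Evaluate predicted entities against gold annotations
#'
#' Full evaluation of a tagging run: entities are paired by overlap and
#' similarity ([pair_entities()]), classified under the four-category error
#' taxonomy ([classify_matches()]), and summarized as precision/recall/F1 in
#' two modes (exact matches only, and including partial matches at or above
#' the similarity threshold) together with per-category error rates.  A true
#' positive requires the correct affirmed/denied polarity in both modes.
#'
#' @param gold,pred [ann_corpus] objects over the same sentence set.
#' @param config A [match_config()].
#' @return An object of class `ner_eval`: a list with `metrics` (tibble, one
#'   row per mode), `errors` (tibble from [error_rates()]), `pairs` (the
#'   per-entity classification tibble) and `config`.
#' @export
#' @examples
#' s <- tibble::tibble(record_id = "r", index = 0L, text = "頭痛なし")
#' e <- tibble::tibble(record_id = "r", index = 0L, start = 0L, end = 2L,
#'                     surface = "頭痛", polarity = "negative")
#' g <- ann_corpus(s, e)
#' evaluate_ner(g, g)
evaluate_ner <- function(gold, pred, config = match_config()) {
  stopifnot(inherits(gold, "ann_corpus"), inherits(pred, "ann_corpus"))
  gk <- sentence_key(gold$sentences$record_id, gold$sentences$index)
  pk <- sentence_key(pred$sentences$record_id, pred$sentences$index)
  if (!setequal(gk, pk)) abort_bad_arg("gold and pred cover different sentence sets")
  pairing <- pair_entities(gold$entities, pred$entities, config)
  pairs <- classify_matches(gold$entities, pred$entities, pairing, config)
  n_gold <- nrow(gold$entities); n_pred <- nrow(pred$entities)
  if (nrow(pairs)) {
    n_exact <- sum(pairs$ner_status == "exact")
    n_high <- sum(pairs$ner_status == "partial_high")
    tp_exact <- sum(pairs$outcome == "correct_exact")
    tp_part <- tp_exact + sum(pairs$outcome == "correct_partial")
    counts <- c(
      error1 = sum(pairs$outcome %in% c("error1", "error1_error2")),
      error2 = sum(pairs$outcome %in% c("error2", "error1_error2")),
      error3 = sum(pairs$outcome == "error3"),
      error4 = sum(pairs$outcome == "error4"))
  } else {
    n_exact <- n_high <- tp_exact <- tp_part <- 0L
    counts <- c(error1 = 0L, error2 = 0L, error3 = 0L, error4 = 0L)
  }
  metrics <- dplyr::bind_rows(
    dplyr::mutate(prf(n_gold, n_pred, tp_exact), mode = "exact", tp = tp_exact),
    dplyr::mutate(prf(n_gold, n_pred, tp_part), mode = "with_partial", tp = tp_part))
  metrics <- dplyr::mutate(metrics, n_gold = n_gold, n_pred = n_pred,
                           .before = "precision")
  metrics <- dplyr::relocate(metrics, "mode")
  total <- total_extractions(n_gold, n_pred, n_exact, n_high)
  errors <- if (total > 0) error_rates(counts, total) else
    tibble::tibble(category = character(), count = integer(), rate = double(),
                   total_extractions = integer())
  structure(list(metrics = metrics, errors = errors, pairs = pairs,
                 config = config),
            class = "ner_eval")
}

#' @export
print.ner_eval <- function(x, ...) {
  cat("<ner_eval>\n")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s P = %.2f  R = %.2f  F1 = %.2f  (TP %d / gold %d / pred %d)\n",
                m$mode[i], m$precision[i], m$recall[i], m$f1[i],
                m$tp[i], m$n_gold[i], m$n_pred[i]))
  }
  if (nrow(x$errors)) {
    e <- x$errors
    cat(sprintf("  errors: %s (total extractions %d)\n",
                paste(sprintf("%s %.1f%%", e$category, round_half_up(e$rate, 1)),
                      collapse = ", "),
                e$total_extractions[1]))
  }
  invisible(x)
}
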