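ent <- function(record_id, index, start, end, surface, polarity) {
  tibble::tibble(record_id = record_id, index = as.integer(index),
                 start = as.integer(start), end = as.integer(end),
                 surface = surface, polarity = polarity)
}

test_that("pairing is one-to-one, overlap-constrained and deterministic", {
  g <- ent("r", 0, 0, 2, "頭痛", "positive")
  p <- g
  out <- pair_entities(g, p)
  expect_equal(nrow(out$pairs), 1L)
  expect_equal(out$pairs$similarity, 1)
  expect_length(out$unmatched_gold, 0)

  # disjoint spans never pair
  p2 <- ent("r", 0, 5, 7, "吐き", "positive")
  out2 <- pair_entities(g, p2)
  expect_equal(nrow(out2$pairs), 0L)
  expect_equal(out2$unmatched_gold, 1L)
  expect_equal(out2$unmatched_pred, 1L)

  # one gold overlapped by two predictions: one pair + one unmatched pred
  g3 <- ent("r", 0, 0, 4, "頭痛あり", "positive")
  p3 <- dplyr::bind_rows(ent("r", 0, 0, 2, "頭痛", "positive"),
                         ent("r", 0, 2, 4, "あり", "positive"))
  out3 <- pair_entities(g3, p3)
  expect_equal(nrow(out3$pairs), 1L)
  expect_length(out3$unmatched_pred, 1L)
  # higher-similarity candidate wins the assignment
  expect_equal(out3$pairs$pred_id, 1L)
})

test_that("the decision table maps match status and polarity to outcomes", {
  g <- ent("r", 0, 0, 2, "頭痛", "positive")
  cfg <- match_config()
  run <- function(pred) {
    classify_matches(g, pred, pair_entities(g, pred, cfg), cfg)
  }
  # exact surface, flipped polarity -> error3
  expect_equal(run(ent("r", 0, 0, 2, "頭痛", "negative"))$outcome, "error3")
  # high-similarity partial with matching polarity -> correct_partial
  g2 <- ent("r", 0, 0, 3, "冷や汗", "positive")
  p2 <- ent("r", 0, 0, 2, "冷や", "positive")
  out <- classify_matches(g2, p2, pair_entities(g2, p2, cfg), cfg)
  expect_equal(out$ner_status, "partial_high")
  expect_equal(out$outcome, "correct_partial")
  # similarity 0.5 with matching polarity -> error4
  g3 <- ent("r", 0, 0, 4, "立ちくら", "positive")
  p3 <- ent("r", 0, 0, 2, "立ち", "positive")
  out3 <- classify_matches(g3, p3, pair_entities(g3, p3, cfg), cfg)
  expect_equal(out3$outcome, "error4")
  # low-similarity pair with flipped polarity dissolves into error1 + error2
  p4 <- ent("r", 0, 0, 2, "立ち", "negative")
  out4 <- classify_matches(g3, p4, pair_entities(g3, p4, cfg), cfg)
  expect_equal(out4$outcome, "error1_error2")
  # unmatched entities
  out5 <- classify_matches(g, empty_entities(),
                           pair_entities(g, empty_entities(), cfg), cfg)
  expect_equal(out5$outcome, "error1")
  out6 <- classify_matches(empty_entities(), g,
                           pair_entities(empty_entities(), g, cfg), cfg)
  expect_equal(out6$outcome, "error2")
})

test_that("precision/recall/F1 follow the formulas with 0/0 = 0", {
  expect_equal(prf(10, 10, 10), tibble::tibble(precision = 1, recall = 1, f1 = 1))
  expect_equal(prf(5, 8, 0)$f1, 0)
  expect_equal(prf(0, 0, 0)$precision, 0)
  out <- prf(100, 80, 60)
  expect_equal(out$precision, 0.75)
  expect_equal(out$recall, 0.6)
  expect_equal(out$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(round_half_up(f1_score(0.81, 0.83), 2), 0.82)
})

test_that("total extractions and error rates follow the counting rules", {
  expect_equal(total_extractions(10, 9, 7, 1), 11L)
  expect_equal(total_extractions(5, 5, 5, 0), 5L)
  expect_error(total_extractions(3, 3, 4, 0), "exceed")
  er <- error_rates(c(error1 = 178, error2 = 280, error3 = 209, error4 = 278),
                    2963)
  expect_equal(round_half_up(er$rate[er$category == "overall"], 1), 31.9)
  expect_equal(round_half_up(er$rate[er$category == "error2"], 1), 9.4)
  expect_equal(error_rates(c(error1 = 0, error2 = 0, error3 = 0, error4 = 0),
                           10)$rate, rep(0, 5))
  expect_error(error_rates(c(error1 = 1, error2 = 0, error3 = 0, error4 = 0), 0),
               "positive")
})

test_that("variation of error rates handles the zero-before rule", {
  expect_equal(variation(0, 2.0)$variation, 100)
  expect_equal(variation(3.7, 3.7)$variation, 100)
  expect_equal(variation(0, 0)$variation, 100)
  expect_equal(round_half_up(variation(9.4, 3.7)$variation, 1), 39.4)
})

test_that("evaluate is exact on identity and forced on global polarity flips", {
  gen <- generate_corpus(default_lexicon(),
                         generator_config(n_records = 60, seed = 2))
  gold <- gen$corpus
  ev <- evaluate_ner(gold, gold)
  expect_equal(ev$metrics$f1, c(1, 1))
  expect_equal(sum(ev$errors$count), 0L)

  flipped <- gold
  flipped$entities$polarity <- ifelse(flipped$entities$polarity == "positive",
                                      "negative", "positive")
  ev2 <- evaluate_ner(gold, flipped)
  expect_equal(ev2$metrics$tp, c(0L, 0L))
  expect_equal(ev2$errors$count[ev2$errors$category == "error3"],
               nrow(gold$entities))
})

test_that("every entity lands in exactly one accounting bucket", {
  gen <- generate_corpus(default_lexicon(),
                         generator_config(n_records = 150, seed = 8))
  inj <- inject_errors(gen$corpus,
                       injection_config(p_delete = .08, p_spurious = .1,
                                        p_flip = .08, p_corrupt = .12,
                                        seed = 4))
  ev <- evaluate_ner(gen$corpus, inj$pred)
  pairs <- ev$pairs
  gold_buckets <- c("correct_exact", "correct_partial", "error1", "error3",
                    "error4", "error1_error2")
  pred_buckets <- c("correct_exact", "correct_partial", "error2", "error3",
                    "error4", "error1_error2")
  n_gold_rows <- sum(pairs$outcome %in% gold_buckets & !is.na(pairs$gold_start))
  n_pred_rows <- sum(pairs$outcome %in% pred_buckets & !is.na(pairs$pred_start))
  expect_equal(n_gold_rows, nrow(gen$corpus$entities))
  expect_equal(n_pred_rows, nrow(inj$pred$entities))
  # recount oracle: total extractions equals the direct count of countable items
  n_matched_high <- sum(pairs$ner_status %in% c("exact", "partial_high"))
  expect_equal(ev$errors$total_extractions[1],
               nrow(gen$corpus$entities) + nrow(inj$pred$entities) - n_matched_high)
})

test_that("evaluation is invariant under entity order permutation", {
  gen <- generate_corpus(default_lexicon(),
                         generator_config(n_records = 60, seed = 13))
  inj <- inject_errors(gen$corpus,
                       injection_config(p_delete = .1, p_spurious = .1,
                                        p_flip = .1, p_corrupt = .1, seed = 5))
  ev1 <- evaluate_ner(gen$corpus, inj$pred)
  perm_gold <- gen$corpus
  perm_pred <- inj$pred
  withr::with_seed(99, {
    perm_gold$entities <- perm_gold$entities[sample.int(nrow(perm_gold$entities)), ]
    perm_pred$entities <- perm_pred$entities[sample.int(nrow(perm_pred$entities)), ]
  })
  ev2 <- evaluate_ner(perm_gold, perm_pred)
  expect_equal(ev1$metrics, ev2$metrics)
  expect_equal(ev1$errors, ev2$errors)
})

test_that("threshold 1 collapses the partial mode onto exact matching", {
  gen <- generate_corpus(default_lexicon(),
                         generator_config(n_records = 80, seed = 21))
  inj <- inject_errors(gen$corpus,
                       injection_config(p_corrupt = .3, band = c(0.5, 1),
                                        seed = 6))
  strict <- evaluate_ner(gen$corpus, inj$pred,
                         match_config(partial_threshold = 1))
  expect_equal(strict$metrics$tp[1], strict$metrics$tp[2])
  loose <- evaluate_ner(gen$corpus, inj$pred)
  expect_gte(loose$metrics$tp[2], loose$metrics$tp[1])
})

test_that("tidy and glance summarize an evaluation", {
  corp <- tiny_corpus()
  ev <- evaluate_ner(corp, corp)
  expect_equal(nrow(tidy(ev)), 2L)
  g <- glance(ev)
  expect_equal(g$f1_exact, 1)
  expect_equal(g$overall_error_rate, 0)
})
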