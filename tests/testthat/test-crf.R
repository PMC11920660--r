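test_that("featurize emits the closed-form number of features per position", {
  cfgs <- list(feature_config(0, 1, use_char_class = FALSE),
               feature_config(2, c(1, 2)),
               feature_config(3, c(1, 3), use_char_class = TRUE))
  withr::with_seed(3, {
    for (cfg in cfgs) {
      for (i in 1:5) {
        txt <- paste(sample(c("頭", "痛", "な", "し", "あ"), sample(1:9, 1),
                            replace = TRUE), collapse = "")
        f <- featurize(txt, cfg)
        expect_equal(lengths(f), expected_feature_counts(nchar(txt), cfg))
        expect_identical(f, featurize(txt, cfg))  # determinism
      }
    }
  })
  f1 <- featurize("痛", feature_config(0, 1))
  expect_setequal(f1[[1]], c("0:1:痛", "c:0:kanji"))
})

test_that("sequence score matches hand arithmetic on a 3-character toy model", {
  W <- matrix(0, 3, 5, dimnames = list(NULL, bio_labels()))
  W[1, "B-POS"] <- 2; W[2, "I-POS"] <- 1.5; W[3, "O"] <- 0.5
  Tr <- matrix(0, 5, 5, dimnames = list(bio_labels(), bio_labels()))
  Tr["B-POS", "I-POS"] <- 0.7; Tr["I-POS", "O"] <- -0.2
  m <- toy_model(c("a", "b", "c"), W, Tr)
  expect_equal(sequence_log_score(m, "abc", c("B-POS", "I-POS", "O")),
               2 + 1.5 + 0.5 + 0.7 - 0.2)
  # zero weights score zero for any valid sequence
  m0 <- toy_model(c("a", "b", "c"), W * 0, Tr * 0)
  expect_equal(sequence_log_score(m0, "abc", c("O", "B-NEG", "I-NEG")), 0)
  # single character: emission only
  expect_equal(sequence_log_score(m, "a", "B-POS"), 2)
  expect_error(sequence_log_score(m, "abc", c("O", "I-POS", "O")), "follow")
})

test_that("log partition and viterbi agree with exhaustive enumeration", {
  alphabet <- letters[1:6]
  withr::with_seed(17, {
    for (i in 1:40) {
      T_ <- sample(1:5, 1)
      W <- matrix(rnorm(6 * 5), 6, 5)
      Tr <- matrix(rnorm(25), 5, 5)
      m <- toy_model(alphabet, W, Tr)
      txt <- paste(sample(alphabet, T_, replace = TRUE), collapse = "")
      E <- crf_emissions(m, txt)
      bf <- brute_force_chain(E, Tr)
      expect_equal(log_partition(m, txt), bf$log_z, tolerance = 1e-10)
      vit <- crf_viterbi(m, txt)
      expect_equal(match(vit, bio_labels()), unname(bf$best))
      # normalization: path probabilities sum to one
      expect_equal(sum(exp(bf$scores - bf$log_z)), 1, tolerance = 1e-10)
      # partition dominates every individual path score
      expect_gte(log_partition(m, txt), max(bf$scores) - 1e-12)
    }
  })
  m0 <- toy_model(letters[1:3], matrix(0, 3, 5), matrix(0, 5, 5))
  expect_equal(log_partition(m0, "abc"), 3 * log(5))
  expect_equal(crf_viterbi(m0, "abc"), rep("O", 3))  # tie-break to O
  expect_error(log_partition(m0, ""), "empty")
})

test_that("the analytic gradient matches central finite differences", {
  gen <- generate_corpus(separable_lexicon(),
                         generator_config(n_records = 6, mean_sentences = 1.5,
                                          entity_rate = 0.8,
                                          char_noise_rate = 0, seed = 30))
  model <- crf_fit(gen$corpus, feature_config(1, 1),
                   train_config(max_iter = 3))
  res <- nll_and_gradient(model, gen$corpus, l2_sigma = 0.7)
  h <- 1e-5
  nll_at <- function(m) nll_and_gradient(m, gen$corpus, l2_sigma = 0.7)$nll
  withr::with_seed(31, {
    coords <- cbind(sample(nrow(model$emission), 12, replace = TRUE),
                    sample(5, 12, replace = TRUE))
  })
  for (r in seq_len(nrow(coords))) {
    up <- model; up$emission[coords[r, 1], coords[r, 2]] <-
      up$emission[coords[r, 1], coords[r, 2]] + h
    dn <- model; dn$emission[coords[r, 1], coords[r, 2]] <-
      dn$emission[coords[r, 1], coords[r, 2]] - h
    fd <- (nll_at(up) - nll_at(dn)) / (2 * h)
    expect_equal(res$gradient$emission[coords[r, 1], coords[r, 2]], fd,
                 tolerance = 1e-4)
  }
  for (jk in list(c(1, 2), c(2, 3), c(5, 1))) {
    up <- model; up$transition[jk[1], jk[2]] <- up$transition[jk[1], jk[2]] + h
    dn <- model; dn$transition[jk[1], jk[2]] <- dn$transition[jk[1], jk[2]] - h
    fd <- (nll_at(up) - nll_at(dn)) / (2 * h)
    expect_equal(res$gradient$transition[jk[1], jk[2]], fd, tolerance = 1e-4)
  }
  # the L2 term adds w / sigma^2 to the gradient
  res_wide <- nll_and_gradient(model, gen$corpus, l2_sigma = 1e6)
  w <- model$emission[1, 2]
  expect_equal(res$gradient$emission[1, 2] - res_wide$gradient$emission[1, 2],
               w / 0.7^2 - w / 1e12, tolerance = 1e-6)
})

test_that("training is deterministic and solves a separable corpus", {
  gen <- generate_corpus(separable_lexicon(),
                         generator_config(n_records = 60, mean_sentences = 2,
                                          entity_rate = 0.6,
                                          char_noise_rate = 0, seed = 41))
  fc <- feature_config(2, 1)
  tc <- train_config(max_iter = 100)
  m1 <- crf_fit(gen$corpus, fc, tc)
  m2 <- crf_fit(gen$corpus, fc, tc)
  expect_identical(m1$emission, m2$emission)
  expect_identical(m1$transition, m2$transition)
  ev <- evaluate_ner(gen$corpus, crf_tag(m1, gen$corpus))
  expect_equal(ev$metrics$f1[ev$metrics$mode == "exact"], 1)
  expect_error(crf_fit(ann_corpus(gen$corpus$sentences)), "entities")
})

test_that("hard regularization shrinks weights toward the trivial tagger", {
  gen <- generate_corpus(separable_lexicon(),
                         generator_config(n_records = 30, mean_sentences = 2,
                                          entity_rate = 0.6,
                                          char_noise_rate = 0, seed = 43))
  fc <- feature_config(1, 1)
  loose <- crf_fit(gen$corpus, fc, train_config(l2_sigma = 1, max_iter = 80))
  tight <- crf_fit(gen$corpus, fc, train_config(l2_sigma = 1e-3, max_iter = 80))
  expect_lt(max(abs(tight$emission)), 1e-3)
  expect_lt(max(abs(tight$emission)), max(abs(loose$emission)))
  # near-zero weights decode to the majority class (all O -> no entities)
  pred <- crf_tag(tight, gen$corpus)
  expect_equal(nrow(pred$entities), 0L)
})

test_that("entity decoding handles orphans, masking and gold consistency", {
  expect_equal(decode_entities(c("B-POS", "I-POS", "O"), "頭痛だ")$surface, "頭痛")
  expect_equal(nrow(decode_entities(rep("O", 3), "頭痛だ")), 0L)
  # orphan I-x is promoted to B-x and counted
  out <- decode_entities(c("O", "I-NEG", "I-NEG"), "あ頭痛")
  expect_equal(out$start, 1L)
  expect_equal(out$polarity, "negative")
  expect_equal(attr(out, "n_orphans"), 1L)
  # OOV masking in the rendered surface; offsets still index the sentence
  out2 <- decode_entities(c("B-POS", "I-POS"), "頭x", vocab = c("頭"))
  expect_equal(out2$surface, "頭＊")
  expect_equal(out2$end, 2L)
  # decoding gold tags reproduces gold spans on any valid corpus
  gen <- generate_corpus(default_lexicon(),
                         generator_config(n_records = 40, seed = 44))
  back <- from_bio(to_bio(gen$corpus))
  expect_equal(dplyr::arrange(back$entities, record_id, index, start),
               dplyr::arrange(gen$corpus$entities, record_id, index, start))
})

test_that("model serialization round-trips through JSON", {
  gen <- generate_corpus(separable_lexicon(),
                         generator_config(n_records = 15, mean_sentences = 1.5,
                                          entity_rate = 0.7,
                                          char_noise_rate = 0, seed = 45))
  m <- crf_fit(gen$corpus, feature_config(1, 1), train_config(max_iter = 30))
  path <- file.path(withr::local_tempdir(), "model.json")
  write_crf(m, path)
  back <- read_crf(path)
  expect_equal(back$emission, m$emission)
  expect_equal(back$transition, m$transition)
  expect_equal(back$char_vocab, m$char_vocab)
  txt <- gen$corpus$sentences$text[1]
  expect_equal(crf_viterbi(back, txt), crf_viterbi(m, txt))
})
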