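# Shared fixtures and independent oracles used across the suite.

# A tiny hand-built corpus: two records, three sentences, three entities.
tiny_corpus <- function() {
  s <- tibble::tibble(
    record_id = c("r1", "r1", "r2"),
    index = c(0L, 1L, 0L),
    text = c("頭痛がある。", "吐き気はない。", "めまいと動悸あり。"))
  e <- tibble::tibble(
    record_id = c("r1", "r1", "r2", "r2"),
    index = c(0L, 1L, 0L, 0L),
    start = c(0L, 0L, 0L, 4L),
    end = c(2L, 3L, 3L, 6L),
    surface = c("頭痛", "吐き気", "めまい", "動悸"),
    polarity = c("positive", "negative", "positive", "positive"))
  ann_corpus(s, e)
}

# Naive exponential-recursion Levenshtein distance (independent oracle).
naive_lev <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    min(rec(i - 1, j) + 1,
        rec(i, j - 1) + 1,
        rec(i - 1, j - 1) + (ca[i] != cb[j]))
  }
  rec(length(ca), length(cb))
}

# Build a crf_model by hand with single-character features over `alphabet`,
# so emissions are fully controlled by the weight matrix.
toy_model <- function(alphabet, emission, transition) {
  structure(list(
    features = paste0("0:1:", alphabet),
    emission = emission,
    transition = transition,
    char_vocab = alphabet,
    unk_char = "＊",
    feature_config = feature_config(window_radius = 0, ngram_orders = 1,
                                    use_char_class = FALSE),
    train_config = train_config(),
    labels = bio_labels(),
    nll = NA_real_, convergence = 0L),
    class = "crf_model")
}

# Exhaustive enumeration over all K^T tag paths: log partition and the
# score-maximizing path (independent oracle for the dynamic programs).
brute_force_chain <- function(E, Tr) {
  T_ <- nrow(E); K <- ncol(E)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  scores <- rowSums(vapply(seq_len(T_), function(t) E[t, paths[, t]],
                           numeric(nrow(paths))))
  if (T_ > 1) {
    for (t in seq_len(T_ - 1)) {
      scores <- scores + Tr[cbind(paths[, t], paths[, t + 1])]
    }
  }
  m <- max(scores)
  list(log_z = m + log(sum(exp(scores - m))),
       best = paths[which.max(scores), ],
       scores = scores)
}

# Closed-form number of features emitted at every position of a sentence of
# length T under a feature_config (combinatorial oracle for featurize()).
expected_feature_counts <- function(T_, config) {
  vapply(seq_len(T_), function(t) {
    n <- 0L
    for (o in -config$window_radius:config$window_radius) {
      for (ord in config$ngram_orders) {
        if (t + o >= 1 && t + o + ord - 1 <= T_) n <- n + 1L
      }
      if (config$use_char_class && t + o >= 1 && t + o <= T_) n <- n + 1L
    }
    n
  }, integer(1))
}
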