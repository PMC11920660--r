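#' Lexicons for synthetic clinical narratives
#'
#' A lexicon bundles invented symptom-like terms, sentence templates with a
#' `{term}` slot (and an optional `{mod}` slot for time/site/severity
#' modifiers), and entity-free distractor sentences.  `default_lexicon()`
#' emulates the register of the subjective field of SOAP-format pharmaceutical
#' care records: short colloquial sentences, each affirming or denying a
#' symptom, mixed with administrative chatter.  No real patient vocabulary is
#' involved.
#'
#' `separable_lexicon()` is a deliberately easy variant for tagger smoke
#' tests: every affirmed term is flanked by one unique marker character and
#' every denied term by another, terms use a character set disjoint from the
#' filler text, and so a character-window tagger can reach F1 = 1.
#'
#' @return A list of class `sym_lexicon` with elements `symptom_terms`,
#'   `affirm_templates`, `negate_templates`, `modifiers`, `distractors`.
#' @export
default_lexicon <- function() {
  parts <- c("頭", "胸", "腹", "腰", "膝", "肩", "背中", "のど",
             "目", "耳", "歯", "手", "足", "首", "胃", "口")
  kinds <- c("の痛み", "のかゆみ", "のしびれ", "のむくみ", "の違和感")
  compound <- as.vector(outer(parts, kinds, paste0))
  standalone <- c(
    "頭痛", "腹痛", "吐き気", "めまい", "ふらつき", "だるさ", "発熱",
    "咳", "息切れ", "動悸", "下痢", "便秘", "食欲不振", "不眠", "悪寒",
    "発疹", "かゆみ", "むくみ", "しびれ", "耳鳴り", "眠気", "倦怠感",
    "口内炎", "胸やけ", "湿疹", "震え", "冷や汗", "立ちくらみ",
    "息苦しさ", "関節痛")
  onomatopoeia <- c("ズキズキ", "ムカムカ", "フラフラ", "ヒリヒリ",
                    "チクチク", "ゾクゾク", "イライラ", "ピリピリ",
                    "ガンガン", "クラクラ")
  new_lexicon(
    symptom_terms = unique(c(compound, standalone, onomatopoeia)),
    affirm_templates = c(
      "{mod}{term}がある。", "{term}がひどい。", "{term}が続いている。",
      "{mod}{term}がつらい。", "{term}あり。", "まだ{term}がある。",
      "少し{term}がする。", "{term}が気になる。", "{term}が出てきた。",
      "{term}で眠れない。", "{mod}{term}が出る。", "{term}は変わらずある。",
      "また{term}がした。", "{term}がずっとある。", "{mod}{term}もある。"),
    negate_templates = c(
      "{term}はない。", "{term}はありません。", "{term}なし。",
      "{mod}{term}はない。", "{term}は出ていない。", "{term}はもうない。",
      "{term}は特にない。", "{term}は感じない。", "{term}はなくなった。",
      "今のところ{term}はない。", "{mod}{term}はなかった。",
      "{term}はだいじょうぶ。", "{term}の心配はない。",
      "{term}はおさまった。", "{mod}{term}も出ていない。"),
    modifiers = c("昨日から", "朝に", "夜間の", "少しの", "強い", "軽い",
                  "食後に", "ときどき", "今朝の", "ずっと"),
    distractors = c(
      "薬はきちんと飲めています。", "特に変わりありません。",
      "昨日退院の説明を受けた。", "ごはんはおいしく食べられた。",
      "先生と相談します。", "散歩を再開した。", "次回は来週の予定です。",
      "家族が面会に来た。", "お薬の説明を受けた。", "手帳を忘れました。",
      "テレビを見て過ごした。", "よく休めています。",
      "退屈だが元気にしている。", "リハビリをがんばっている。",
      "新しい薬になった。", "飲み忘れが一回あった。",
      "仕事に復帰する予定です。", "天気がよくて気分がいい。",
      "detarame na hanashi。", "特記事項なし。"))
}

#' @rdname default_lexicon
#' @export
separable_lexicon <- function() {
  syll <- c("カ", "キ", "ク", "ケ", "コ", "サ", "シ", "ス", "セ", "ソ",
            "タ", "チ", "ツ", "テ", "ト", "ナ", "ニ", "ヌ", "ネ", "ノ")
  terms <- unique(c(
    as.vector(outer(syll[1:10], syll[11:20], paste0)),
    paste0(syll[1:10], rev(syll[1:10]))))
  fillers_a <- c("", "きょうは", "ゆうべは", "さっき", "ずっと")
  fillers_b <- c("", "です", "みたい", "とのこと")
  new_lexicon(
    symptom_terms = terms,
    affirm_templates = as.vector(outer(
      paste0(fillers_a, "有{term}在"), paste0(fillers_b, "。"), paste0)),
    negate_templates = as.vector(outer(
      paste0(fillers_a, "無{term}不"), paste0(fillers_b, "。"), paste0)),
    modifiers = character(),
    distractors = c("へやですごした。", "ほんをよんだ。", "よくねむれた。",
                    "たいくつだった。", "おちゃをのんだ。", "さんぽした。"))
}

new_lexicon <- function(symptom_terms, affirm_templates, negate_templates,
                        modifiers, distractors) {
  stopifnot(length(symptom_terms) > 0, !anyDuplicated(symptom_terms),
            length(affirm_templates) > 0, length(negate_templates) > 0,
            length(distractors) > 0)
  lens <- chr_len(symptom_terms)
  stopifnot(all(lens >= 1), all(lens <= 8))
  stopifnot(all(stringr::str_detect(c(affirm_templates, negate_templates),
                                    stringr::fixed("{term}"))))
  structure(list(symptom_terms = symptom_terms,
                 affirm_templates = affirm_templates,
                 negate_templates = negate_templates,
                 modifiers = modifiers,
                 distractors = distractors),
            class = "sym_lexicon")
}

#' Synthetic corpus configuration
#'
#' Defaults emulate the shape of a year of pharmaceutical care records:
#' about 3.63 sentences per record (43,553 sentences over 12,004 records,
#' geometric distribution), about 0.485 symptom mentions per sentence
#' (21,109 mentions over 43,553 sentences), and 58.2\% affirmed mentions
#' (12,287 affirmed vs 8,822 denied).
#'
#' @param n_records Number of records to generate.
#' @param mean_sentences Mean sentences per record (geometric, minimum 1).
#' @param entity_rate Probability that a sentence carries a symptom mention.
#' @param positive_fraction Probability that a mention is affirmed.
#' @param char_noise_rate Per-sentence probability of one random character
#'   substitution outside entity spans (surface-form noise).
#' @param seed Integer seed; every draw derives from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_records = 100L, mean_sentences = 3.63,
                             entity_rate = 0.485, positive_fraction = 0.582,
                             char_noise_rate = 0.02, seed = 1L) {
  stopifnot(n_records >= 1, mean_sentences >= 1,
            entity_rate >= 0, entity_rate <= 1,
            positive_fraction >= 0, positive_fraction <= 1,
            char_noise_rate >= 0, char_noise_rate <= 1)
  structure(list(n_records = as.integer(n_records),
                 mean_sentences = mean_sentences,
                 entity_rate = entity_rate,
                 positive_fraction = positive_fraction,
                 char_noise_rate = char_noise_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

NOISE_ALPHABET <- c("あ", "い", "う", "え", "お", "ん", "つ", "ら", "り", "る")

#' Generate a synthetic annotated corpus
#'
#' Builds records of short sentences from a lexicon: each sentence either
#' carries one symptom mention (rendered from an affirmation or negation
#' template, with recoverable character offsets) or is an entity-free
#' distractor.  Optional character noise substitutes one character outside
#' entity spans.  A generation ledger records every planted mention, so
#' downstream statistics can be checked against ground truth.  Fully
#' deterministic given `config$seed`.
#'
#' @param lexicon A lexicon from [default_lexicon()] or [separable_lexicon()].
#' @param config A [generator_config()].
#' @return A list with `corpus` (an [ann_corpus]) and `ledger` (tibble of
#'   planted mentions: sentence key, offsets, surface, polarity, term).
#' @export
generate_corpus <- function(lexicon, config = generator_config()) {
  stopifnot(inherits(lexicon, "sym_lexicon"), inherits(config, "generator_config"))
  with_seed(derive_seed(config$seed, "generate"), {
    n_s <- 1L + stats::rgeom(config$n_records,
                             prob = min(1, 1 / config$mean_sentences))
    N <- sum(n_s)
    rid <- rep(sprintf("r%05d", seq_len(config$n_records)), n_s)
    idx <- sequence(n_s) - 1L
    is_ent <- stats::runif(N) < config$entity_rate
    text <- character(N)
    start <- end <- rep(NA_integer_, N)
    pol <- term <- rep(NA_character_, N)
    n_e <- sum(is_ent)
    if (n_e > 0) {
      pol[is_ent] <- ifelse(stats::runif(n_e) < config$positive_fraction,
                            "positive", "negative")
      term[is_ent] <- sample(lexicon$symptom_terms, n_e, replace = TRUE)
      tmpl <- character(n_e)
      pos_e <- pol[is_ent] == "positive"
      tmpl[pos_e] <- sample(lexicon$affirm_templates, sum(pos_e), replace = TRUE)
      tmpl[!pos_e] <- sample(lexicon$negate_templates, sum(!pos_e), replace = TRUE)
      mod <- if (length(lexicon$modifiers)) {
        ifelse(stats::runif(n_e) < 0.5,
               sample(lexicon$modifiers, n_e, replace = TRUE), "")
      } else rep("", n_e)
      with_mod <- stringr::str_replace_all(tmpl, stringr::fixed("{mod}"), mod)
      at <- stringr::str_locate(with_mod, stringr::fixed("{term}"))[, 1]
      start[is_ent] <- unname(at) - 1L
      text[is_ent] <- stringr::str_replace(with_mod, stringr::fixed("{term}"),
                                           term[is_ent])
      end[is_ent] <- start[is_ent] + chr_len(term[is_ent])
    }
    if (any(!is_ent)) {
      text[!is_ent] <- sample(lexicon$distractors, sum(!is_ent), replace = TRUE)
    }
    if (config$char_noise_rate > 0) {
      for (i in which(stats::runif(N) < config$char_noise_rate)) {
        free <- seq_len(chr_len(text[i]))
        if (is_ent[i]) free <- setdiff(free, (start[i] + 1L):end[i])
        if (!length(free)) next
        p <- free[sample.int(length(free), 1)]
        stringr::str_sub(text[i], p, p) <- sample(NOISE_ALPHABET, 1)
      }
    }
    sentences <- tibble::tibble(record_id = rid, index = idx, text = text)
    surf <- substr0(text[is_ent], start[is_ent], end[is_ent])
    ledger <- tibble::tibble(
      record_id = rid[is_ent], index = idx[is_ent],
      start = start[is_ent], end = end[is_ent],
      surface = surf,
      polarity = pol[is_ent], term = term[is_ent])
    corpus <- ann_corpus(sentences, dplyr::select(ledger, -"term"))
    list(corpus = corpus, ledger = ledger)
  })
}

# Substitute {mod} then {term} into a template, tracking the term offsets.
render_template <- function(template, term, mod = "") {
  text <- stringr::str_replace_all(template, stringr::fixed("{mod}"), mod)
  at <- stringr::str_locate(text, stringr::fixed("{term}"))
  start <- unname(at[1, 1]) - 1L
  text <- stringr::str_replace(text, stringr::fixed("{term}"), term)
  list(text = text, start = start, end = start + chr_len(term))
}

#' Controlled tagger-error injection configuration
#'
#' The injector is the constructive inverse of the error taxonomy: each gold
#' mention is independently deleted (a system extraction failure, error 1),
#' polarity-flipped (error 3), boundary-corrupted into a target similarity
#' band (error 4 below the partial threshold, a partial match above it), or
#' kept exact; spurious mentions (incorrect extractions, error 2) are added
#' in entity-free sentences.
#'
#' @param p_delete,p_flip,p_corrupt,p_spurious Per-mention probabilities (the
#'   spurious count is drawn as `Binomial(n_gold, p_spurious)`).
#' @param band Target similarity band `[lo, hi)` for corruption; the default
#'   `c(0, 0.66)` lands below the standard partial threshold.
#' @param method `"bernoulli"` draws each mention's fate independently;
#'   `"exact"` applies `round(p * n)` manipulations of each kind to a random
#'   subset, which removes binomial noise from recovered rates.
#' @param seed Integer seed.
#' @return A list of class `injection_config`.
#' @export
injection_config <- function(p_delete = 0, p_spurious = 0, p_flip = 0,
                             p_corrupt = 0, band = c(0, 0.66),
                             method = c("bernoulli", "exact"), seed = 1L) {
  method <- match.arg(method)
  p <- c(p_delete, p_spurious, p_flip, p_corrupt)
  stopifnot(all(p >= 0), all(p <= 1), p_delete + p_flip + p_corrupt <= 1,
            length(band) == 2, band[1] >= 0, band[2] <= 1, band[1] < band[2])
  structure(list(p_delete = p_delete, p_spurious = p_spurious,
                 p_flip = p_flip, p_corrupt = p_corrupt, band = band,
                 method = method, seed = as.integer(seed)),
            class = "injection_config")
}

#' Inject controlled tagger errors into a gold corpus
#'
#' Produces a predicted corpus whose disagreements with `gold` have known
#' intended categories, so the evaluator's taxonomy can be validated end to
#' end.  Boundary corruption is constructive: shrink or extend amounts are
#' enumerated and one whose similarity `(L - d) / L` or `L / (L + d)` lands
#' in the requested band is chosen; a mention too short to reach the band is
#' kept exact and logged as `corrupt_skipped`.
#'
#' @param gold An [ann_corpus].
#' @param config An [injection_config()].
#' @return A list with `pred` (an [ann_corpus] over the same sentences) and
#'   `ledger` (tibble: one row per gold mention plus one per spurious
#'   mention, with `kind` and the `intended` evaluation outcome).
#' @export
inject_errors <- function(gold, config) {
  stopifnot(inherits(gold, "ann_corpus"), inherits(config, "injection_config"))
  e <- gold$entities
  s <- gold$sentences
  n <- nrow(e)
  skey <- sentence_key(s$record_id, s$index)
  ekey <- sentence_key(e$record_id, e$index)
  with_seed(derive_seed(config$seed, "inject"), {
    kind <- rep("keep", n)
    if (n > 0) {
      if (config$method == "bernoulli") {
        u <- stats::runif(n)
        kind[u < config$p_delete] <- "delete"
        kind[u >= config$p_delete &
               u < config$p_delete + config$p_flip] <- "flip"
        kind[u >= config$p_delete + config$p_flip &
               u < config$p_delete + config$p_flip + config$p_corrupt] <- "corrupt"
        n_spur <- stats::rbinom(1, n, config$p_spurious)
      } else {
        n_del <- round(config$p_delete * n)
        n_flip <- round(config$p_flip * n)
        n_corr <- round(config$p_corrupt * n)
        perm <- sample.int(n)
        kind[perm[seq_len(n_del)]] <- "delete"
        kind[perm[n_del + seq_len(n_flip)]] <- "flip"
        kind[perm[n_del + n_flip + seq_len(n_corr)]] <- "corrupt"
        n_spur <- round(config$p_spurious * n)
      }
    } else {
      n_spur <- 0L
    }

    pred_start <- e$start; pred_end <- e$end
    pred_pol <- e$polarity
    intended <- rep("correct_exact", n)
    keep_in_pred <- kind != "delete"
    intended[kind == "delete"] <- "error1"
    flip <- kind == "flip"
    pred_pol[flip] <- ifelse(e$polarity[flip] == "positive",
                             "negative", "positive")
    intended[flip] <- "error3"
    sent_len <- chr_len(s$text)[match(ekey, skey)]
    for (i in which(kind == "corrupt")) {
      others <- e[ekey == ekey[i] & seq_len(n) != i, ]
      cand <- corruption_candidates(e$start[i], e$end[i], sent_len[i], others)
      ok <- cand$sim >= config$band[1] & cand$sim < config$band[2] & cand$sim > 0
      if (any(ok)) {
        pick <- which(ok)[sample.int(sum(ok), 1)]
        pred_start[i] <- cand$start[pick]
        pred_end[i] <- cand$end[pick]
        intended[i] <- if (cand$sim[pick] >= 0.66) "correct_partial" else "error4"
      } else {
        kind[i] <- "corrupt_skipped"
      }
    }
    ledger <- tibble::tibble(
      kind = kind, record_id = e$record_id, index = e$index,
      gold_start = e$start, gold_end = e$end,
      gold_surface = e$surface, gold_polarity = e$polarity,
      pred_start = ifelse(keep_in_pred, pred_start, NA_integer_),
      pred_end = ifelse(keep_in_pred, pred_end, NA_integer_),
      intended = intended)

    # spurious mentions in entity-free sentences
    sp_rid <- sp_idx <- character(); sp_start <- sp_end <- integer()
    sp_pol <- character()
    free_keys <- setdiff(skey, ekey)
    taken_start <- split(integer(), character())
    taken_end <- split(integer(), character())
    placed <- 0L
    guard <- 0L
    while (placed < n_spur && length(free_keys) > 0 && guard < 50L * n_spur) {
      guard <- guard + 1L
      k <- free_keys[sample.int(length(free_keys), 1)]
      si <- match(k, skey)
      len <- chr_len(s$text[si])
      w <- sample(2:4, 1)
      if (len < w) next
      st <- sample.int(len - w + 1L, 1) - 1L
      en <- st + w
      if (!is.null(taken_start[[k]]) &&
          any(st < taken_end[[k]] & taken_start[[k]] < en)) next
      taken_start[[k]] <- c(taken_start[[k]], st)
      taken_end[[k]] <- c(taken_end[[k]], en)
      sp_rid <- c(sp_rid, s$record_id[si]); sp_idx <- c(sp_idx, s$index[si])
      sp_start <- c(sp_start, st); sp_end <- c(sp_end, en)
      sp_pol <- c(sp_pol, sample(c("positive", "negative"), 1))
      placed <- placed + 1L
    }
    if (placed > 0) {
      sp_text <- s$text[match(sentence_key(sp_rid, sp_idx), skey)]
      spurious <- tibble::tibble(
        record_id = sp_rid, index = as.integer(sp_idx),
        start = sp_start, end = sp_end,
        surface = substr0(sp_text, sp_start, sp_end), polarity = sp_pol)
      ledger <- dplyr::bind_rows(ledger, tibble::tibble(
        kind = "spurious", record_id = spurious$record_id,
        index = spurious$index,
        gold_start = NA_integer_, gold_end = NA_integer_,
        gold_surface = NA_character_, gold_polarity = NA_character_,
        pred_start = spurious$start, pred_end = spurious$end,
        intended = "error2"))
    } else {
      spurious <- empty_entities()
    }

    kept <- e[keep_in_pred, ]
    kept$polarity <- pred_pol[keep_in_pred]
    kept$start <- pred_start[keep_in_pred]
    kept$end <- pred_end[keep_in_pred]
    kept_text <- s$text[match(ekey[keep_in_pred], skey)]
    kept$surface <- substr0(kept_text, kept$start, kept$end)
    pred_ents <- dplyr::bind_rows(kept, spurious)
    if (nrow(pred_ents) == 0) pred_ents <- empty_entities()
    list(pred = ann_corpus(s, pred_ents), ledger = ledger)
  })
}

# Enumerate boundary corruptions of span [start, end) in a sentence of
# length len, avoiding overlap with other gold spans, with the similarity
# each would score against the original surface.
corruption_candidates <- function(start, end, len, others) {
  L <- end - start
  cs <- ce <- integer(); sim <- double()
  if (L >= 2) {
    d <- seq_len(L - 1)
    cs <- c(cs, start + d, rep(start, L - 1))      # shrink left / right
    ce <- c(ce, rep(end, L - 1), end - d)
    sim <- c(sim, (L - d) / L, (L - d) / L)
  }
  d <- seq_len(6L)
  right <- d[end + d <= len]
  cs <- c(cs, rep(start, length(right)))           # extend right
  ce <- c(ce, end + right)
  sim <- c(sim, L / (L + right))
  left <- d[start - d >= 0]
  cs <- c(cs, start - left)                        # extend left
  ce <- c(ce, rep(end, length(left)))
  sim <- c(sim, L / (L + left))
  keep <- rep(TRUE, length(cs))
  if (nrow(others) && length(cs)) {
    for (j in seq_len(nrow(others))) {
      keep <- keep & !(cs < others$end[j] & others$start[j] < ce)
    }
  }
  tibble::tibble(start = cs[keep], end = ce[keep], sim = sim[keep])
}
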