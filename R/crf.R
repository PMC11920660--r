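#' Training configuration for the CRF tagger
#'
#' Full-batch maximum-likelihood training with an L2 (Gaussian) penalty,
#' optimized by L-BFGS from a zero start.  Training is deterministic: the
#' same corpus and configuration always give the same weights; `seed` is
#' recorded for provenance and used only by stochastic emission providers
#' plugged in behind the emission contract.
#'
#' @param l2_sigma Standard deviation of the Gaussian prior on weights
#'   (penalty `sum(w^2) / (2 * l2_sigma^2)`); smaller values shrink weights
#'   harder.  Default 1.
#' @param max_iter Maximum L-BFGS iterations (default 200).
#' @param tol Projected-gradient convergence tolerance (default 1e-6).
#' @param seed Integer seed recorded on the model.
#' @return A list of class `train_config`.
#' @export
train_config <- function(l2_sigma = 1, max_iter = 200L, tol = 1e-6, seed = 1L) {
  stopifnot(l2_sigma > 0, max_iter >= 1, tol > 0)
  structure(list(l2_sigma = l2_sigma, max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed)),
            class = "train_config")
}

#' Emission scores for a sentence
#'
#' The pluggable emission contract: given a model and a normalized sentence,
#' return a `nchar(text) x 5` matrix of per-position, per-tag log potentials
#' (columns in [bio_labels()] order).  The bundled `crf_model` method sums
#' sparse character-window feature weights; an alternative encoder can
#' provide its own method and reuse training-free decoding and evaluation.
#'
#' @param model A fitted model object.
#' @param text Character scalar.
#' @return Numeric matrix, `nchar(text)` rows and 5 columns.
#' @export
crf_emissions <- function(model, text) UseMethod("crf_emissions")

#' @export
crf_emissions.crf_model <- function(model, text) {
  feats <- featurize(text, model$feature_config)
  emission_from_features(feats, model$features, model$emission)
}

emission_from_features <- function(feats, feat_names, weights) {
  T_ <- length(feats)
  K <- ncol(weights)
  E <- matrix(0, T_, K)
  if (T_ == 0) return(E)
  fid <- match(unlist(feats, use.names = FALSE), feat_names)
  pos <- rep.int(seq_len(T_), lengths(feats))
  keep <- !is.na(fid)
  if (any(keep)) {
    agg <- rowsum(weights[fid[keep], , drop = FALSE], group = pos[keep])
    E[as.integer(rownames(agg)), ] <- agg
  }
  E
}

tags_to_int <- function(tags) {
  out <- match(tags, bio_labels())
  if (anyNA(out)) abort_bad_arg("unknown tag %s", tags[is.na(out)][1])
  out
}

check_tag_validity <- function(tags_int) {
  labs <- bio_labels()
  tags <- labs[tags_int]
  prev <- c("O", tags[-length(tags)])
  is_i <- grepl("^I-", tags)
  stem <- sub("^I", "", tags)
  ok <- !is_i | prev == paste0("B", stem) | prev == paste0("I", stem)
  if (!all(ok)) {
    abort_bad_arg("invalid tag sequence: %s cannot follow %s at position %d",
                  tags[!ok][1], prev[!ok][1], which(!ok)[1])
  }
  invisible(TRUE)
}

#' Log potential of one tag sequence
#'
#' The unnormalized linear-chain score: the sum of emission weights for each
#' (position, tag) plus transition weights for each adjacent tag pair.
#'
#' @param model A fitted `crf_model` (or any object with a [crf_emissions()]
#'   method and a `transition` matrix).
#' @param text Character scalar, the sentence.
#' @param tags Character vector of tags from [bio_labels()], one per
#'   character; must satisfy the BIO validity constraint.
#' @return Numeric scalar.
#' @export
sequence_log_score <- function(model, text, tags) {
  T_ <- chr_len(text)
  if (length(tags) != T_) abort_bad_arg("need %d tags, got %d", T_, length(tags))
  ti <- tags_to_int(tags)
  check_tag_validity(ti)
  E <- crf_emissions(model, text)
  sc <- sum(E[cbind(seq_len(T_), ti)])
  if (T_ > 1) sc <- sc + sum(model$transition[cbind(ti[-T_], ti[-1])])
  sc
}

#' Log partition function of a sentence
#'
#' Log of the sum over all `5^T` tag sequences of the exponentiated sequence
#' score, computed by the scaled forward recursion (overflow-safe).
#'
#' @inheritParams sequence_log_score
#' @return Numeric scalar; always at least the score of any single sequence.
#' @export
log_partition <- function(model, text) {
  if (chr_len(text) == 0) abort_bad_arg("empty sentence")
  fb <- crf_forward_backward(crf_emissions(model, text), model$transition)
  fb$log_z
}

#' Most probable tag sequence (Viterbi decoding)
#'
#' The argmax over tag sequences of [sequence_log_score()].  Ties are broken
#' toward the tag earliest in [bio_labels()] order at the latest position
#' where candidate sequences differ, so an all-zero model decodes to all-`O`.
#'
#' @inheritParams sequence_log_score
#' @return Character vector of tags, one per character.
#' @export
crf_viterbi <- function(model, text) {
  if (chr_len(text) == 0) abort_bad_arg("empty sentence")
  path <- crf_viterbi_path(crf_emissions(model, text), model$transition)
  bio_labels()[path]
}

#' Decode BIO tags into entity spans
#'
#' Maximal `B-x (I-x)*` runs become entity spans with polarity `x`.  An
#' orphan `I-x` (not preceded by `B-x`/`I-x`) is promoted to `B-x` rather
#' than discarded; the number of promotions is attached as attribute
#' `"n_orphans"`.  When a vocabulary is supplied, out-of-vocabulary
#' characters in the returned surfaces are masked with `"＊"` while offsets
#' keep indexing the original sentence.
#'
#' @param tags Character tag vector, one per character of `text`.
#' @param text The sentence.
#' @param record_id,index Sentence identity for the output rows.
#' @param vocab Optional character vocabulary for surface masking (e.g.
#'   `model$char_vocab`).
#' @return Entity tibble (see [ann_corpus()]).
#' @export
decode_entities <- function(tags, text, record_id = "r1", index = 0L,
                            vocab = NULL) {
  T_ <- chr_len(text)
  if (length(tags) != T_) abort_bad_arg("need %d tags, got %d", T_, length(tags))
  prev <- c("O", tags[-length(tags)])
  stem <- sub("^I", "", tags)
  orphans <- sum(grepl("^I-", tags) &
                   prev != paste0("B", stem) & prev != paste0("I", stem))
  out <- spans_from_tags(tags, text, as.character(record_id), as.integer(index))
  if (!is.null(vocab)) out$surface <- mask_unknown(out$surface, vocab)
  attr(out, "n_orphans") <- orphans
  out
}

# ---- training -------------------------------------------------------------

# Precompute per-sentence feature indices and gold tags.
build_sentence_data <- function(texts, tag_list, fconfig, feat_names = NULL) {
  feats <- lapply(texts, featurize, config = fconfig)
  if (is.null(feat_names)) {
    feat_names <- unique(unlist(feats, use.names = FALSE))
  }
  dat <- vector("list", length(texts))
  for (i in seq_along(texts)) {
    f <- feats[[i]]
    fid <- match(unlist(f, use.names = FALSE), feat_names)
    pos <- rep.int(seq_along(f), lengths(f))
    keep <- !is.na(fid)
    dat[[i]] <- list(T = length(f), pos = pos[keep], fid = fid[keep],
                     gold = if (is.null(tag_list)) NULL else tags_to_int(tag_list[[i]]))
  }
  list(data = dat, feat_names = feat_names)
}

# Negative log-likelihood and gradient over prepared sentence data.
crf_objective <- function(par, dat, nf, K, l2_sigma) {
  W <- matrix(par[seq_len(nf * K)], nf, K)
  Tr <- matrix(par[nf * K + seq_len(K * K)], K, K)
  nll <- 0
  gradW <- matrix(0, nf, K)
  gradT <- matrix(0, K, K)
  for (sd_ in dat) {
    T_ <- sd_$T
    if (T_ == 0) next
    E <- matrix(0, T_, K)
    if (length(sd_$fid)) {
      agg <- rowsum(W[sd_$fid, , drop = FALSE], group = sd_$pos)
      E[as.integer(rownames(agg)), ] <- agg
    }
    fb <- crf_forward_backward(E, Tr)
    g <- sd_$gold
    gold_score <- sum(E[cbind(seq_len(T_), g)])
    if (T_ > 1) gold_score <- gold_score + sum(Tr[cbind(g[-T_], g[-1])])
    nll <- nll + fb$log_z - gold_score
    if (length(sd_$fid)) {
      D <- fb$node_marginals[sd_$pos, , drop = FALSE]
      idx <- cbind(seq_along(sd_$pos), g[sd_$pos])
      D[idx] <- D[idx] - 1
      contrib <- rowsum(D, group = sd_$fid)
      uf <- as.integer(rownames(contrib))
      gradW[uf, ] <- gradW[uf, ] + contrib
    }
    gradT <- gradT + fb$expected_transitions
    if (T_ > 1) {
      obs <- table(factor(g[-T_], levels = 1:K), factor(g[-1], levels = 1:K))
      gradT <- gradT - unclass(obs)
    }
  }
  nll <- nll + sum(par^2) / (2 * l2_sigma^2)
  grad <- c(as.vector(gradW), as.vector(gradT)) + par / l2_sigma^2
  list(value = nll, gradient = grad)
}

#' Negative log-likelihood and gradient of a model on a corpus
#'
#' The full-batch training objective evaluated at the model's current
#' weights: `sum over sentences of (log Z - gold score)` plus the L2 penalty
#' `sum(w^2) / (2 * l2_sigma^2)`.  The gradient (expected minus observed
#' feature counts, plus `w / l2_sigma^2`) matches central finite differences.
#'
#' @param model A `crf_model`.
#' @param corpus An [ann_corpus] providing the gold tags.
#' @param l2_sigma L2 prior width; defaults to the model's training value.
#' @return A list with `nll` (scalar) and `gradient` (list with `emission`
#'   and `transition` matrices).
#' @export
nll_and_gradient <- function(model, corpus, l2_sigma = model$train_config$l2_sigma) {
  stopifnot(inherits(model, "crf_model"), inherits(corpus, "ann_corpus"))
  prep <- build_sentence_data(corpus$sentences$text, gold_tags(corpus),
                              model$feature_config, model$features)
  nf <- length(model$features); K <- length(bio_labels())
  par <- c(as.vector(model$emission), as.vector(model$transition))
  obj <- crf_objective(par, prep$data, nf, K, l2_sigma)
  list(nll = obj$value,
       gradient = list(
         emission = matrix(obj$gradient[seq_len(nf * K)], nf, K,
                           dimnames = list(model$features, bio_labels())),
         transition = matrix(obj$gradient[nf * K + seq_len(K * K)], K, K,
                             dimnames = list(bio_labels(), bio_labels()))))
}

#' Fit the character-level CRF tagger
#'
#' Trains a linear-chain CRF over the joint span-polarity label set on the
#' gold annotations of a corpus by penalized maximum likelihood (L-BFGS,
#' zero start, full batch).  Deterministic: the same corpus and
#' configurations reproduce the weights bit for bit.
#'
#' @param corpus An [ann_corpus]; must be non-empty and contain at least one
#'   entity.
#' @param fconfig A [feature_config()].
#' @param tconfig A [train_config()].
#' @return An object of class `crf_model`: feature names, emission weight
#'   matrix (features x tags), transition matrix (5 x 5), `char_vocab` (the
#'   characters seen in training), the configurations, and the final
#'   penalized negative log-likelihood `nll`.
#' @export
crf_fit <- function(corpus, fconfig = feature_config(),
                    tconfig = train_config()) {
  stopifnot(inherits(corpus, "ann_corpus"))
  if (nrow(corpus$sentences) == 0) abort_bad_arg("empty corpus")
  if (nrow(corpus$entities) == 0) abort_bad_arg("corpus has no entities to learn from")
  texts <- corpus$sentences$text
  prep <- build_sentence_data(texts, gold_tags(corpus), fconfig)
  nf <- length(prep$feat_names)
  K <- length(bio_labels())
  cache <- new.env(parent = emptyenv())
  eval_at <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$obj)
    obj <- crf_objective(par, prep$data, nf, K, tconfig$l2_sigma)
    cache$par <- par; cache$obj <- obj
    obj
  }
  fit <- stats::optim(
    par = numeric(nf * K + K * K),
    fn = function(p) eval_at(p)$value,
    gr = function(p) eval_at(p)$gradient,
    method = "L-BFGS-B",
    control = list(maxit = tconfig$max_iter, pgtol = tconfig$tol, factr = 1e7))
  W <- matrix(fit$par[seq_len(nf * K)], nf, K,
              dimnames = list(prep$feat_names, bio_labels()))
  Tr <- matrix(fit$par[nf * K + seq_len(K * K)], K, K,
               dimnames = list(bio_labels(), bio_labels()))
  structure(list(
    features = prep$feat_names,
    emission = W,
    transition = Tr,
    char_vocab = sort(unique(unlist(stringr::str_split(texts, ""), use.names = FALSE))),
    unk_char = "＊",
    feature_config = fconfig,
    train_config = tconfig,
    labels = bio_labels(),
    nll = fit$value,
    convergence = fit$convergence),
    class = "crf_model")
}

#' @export
print.crf_model <- function(x, ...) {
  cat(sprintf("<crf_model> %d features, %d-character vocab, penalized NLL %.3f\n",
              length(x$features), length(x$char_vocab), x$nll))
  invisible(x)
}

#' Tag a corpus with a fitted model
#'
#' Runs Viterbi decoding on every sentence and decodes the tag sequences into
#' predicted entities.  Surfaces in the returned corpus are the literal
#' sentence substrings (so the corpus is valid for I/O); apply
#' unknown-character masking at evaluation time via
#' `match_config(vocab = model$char_vocab)`.
#'
#' @param model A `crf_model`.
#' @param corpus An [ann_corpus]; its entities, if any, are ignored.
#' @return An [ann_corpus] with predicted entities.
#' @export
crf_tag <- function(model, corpus) {
  stopifnot(inherits(corpus, "ann_corpus"))
  s <- corpus$sentences
  ents <- purrr::map_dfr(seq_len(nrow(s)), function(i) {
    tags <- crf_viterbi(model, s$text[i])
    decode_entities(tags, s$text[i], s$record_id[i], s$index[i])
  })
  if (nrow(ents) == 0) ents <- empty_entities()
  ann_corpus(s, ents)
}

# ---- serialization --------------------------------------------------------

CRF_FORMAT_VERSION <- "sympner-crf-1"

#' Save and load a fitted CRF model as JSON
#'
#' A single UTF-8 JSON file holding the sparse emission weights, the
#' transition matrix, the character vocabulary, both configurations and a
#' format-version field.  `read_crf(write_crf(m, path))` reproduces the
#' model.
#'
#' @param model A `crf_model`.
#' @param path File path.
#' @return `read_crf()` returns the `crf_model`; `write_crf()` returns
#'   `model` invisibly.
#' @export
write_crf <- function(model, path) {
  stopifnot(inherits(model, "crf_model"))
  nz <- which(model$emission != 0, arr.ind = TRUE)
  obj <- list(
    format_version = CRF_FORMAT_VERSION,
    labels = model$labels,
    features = model$features,
    emission = list(i = as.integer(nz[, 1]), j = as.integer(nz[, 2]),
                    x = as.numeric(model$emission[nz])),
    transition = as.numeric(model$transition),
    char_vocab = model$char_vocab,
    unk_char = model$unk_char,
    feature_config = unclass(model$feature_config),
    train_config = unclass(model$train_config),
    nll = model$nll,
    convergence = model$convergence)
  writeLines(enc2utf8(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))),
             path, useBytes = TRUE)
  invisible(model)
}

#' @rdname write_crf
#' @export
read_crf <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path, encoding = "UTF-8", warn = FALSE))
  if (!identical(obj$format_version, CRF_FORMAT_VERSION)) {
    abort_bad_arg("unsupported model format: %s", obj$format_version)
  }
  K <- length(obj$labels)
  nf <- length(obj$features)
  W <- matrix(0, nf, K, dimnames = list(obj$features, obj$labels))
  if (length(obj$emission$i)) {
    W[cbind(obj$emission$i, obj$emission$j)] <- obj$emission$x
  }
  fc <- obj$feature_config
  tc <- obj$train_config
  structure(list(
    features = obj$features,
    emission = W,
    transition = matrix(obj$transition, K, K,
                        dimnames = list(obj$labels, obj$labels)),
    char_vocab = obj$char_vocab,
    unk_char = obj$unk_char,
    feature_config = feature_config(fc$window_radius, fc$ngram_orders,
                                    fc$use_char_class),
    train_config = train_config(tc$l2_sigma, tc$max_iter, tc$tol, tc$seed),
    labels = obj$labels,
    nll = obj$nll,
    convergence = obj$convergence),
    class = "crf_model")
}
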