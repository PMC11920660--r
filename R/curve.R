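#' Cross-validation fold plan
#'
#' Shuffles the corpus units (sentences, or whole records) with a fixed seed
#' and deals them into `k` folds whose sizes differ by at most one unit.
#' The shuffled order is retained: when the training amount is increased
#' stepwise, "the first s units" always means the same deterministic prefix.
#'
#' @param corpus An [ann_corpus].
#' @param k Number of folds (default 10).
#' @param unit `"sentence"` (default) or `"record"`.
#' @param seed Integer seed.
#' @return A list of class `fold_plan`: `k`, `unit`, `seed`, `assignment`
#'   (tibble `unit_id`, `fold`) and `order` (unit ids in shuffled order).
#' @export
make_folds <- function(corpus, k = 10L, unit = c("sentence", "record"),
                       seed = 1L) {
  stopifnot(inherits(corpus, "ann_corpus"), k >= 2)
  unit <- match.arg(unit)
  ids <- if (unit == "sentence") {
    sentence_key(corpus$sentences$record_id, corpus$sentences$index)
  } else {
    unique(corpus$sentences$record_id)
  }
  if (length(ids) < k) {
    abort_bad_arg("corpus has %d %ss but k = %d", length(ids), unit, k)
  }
  ord <- with_seed(derive_seed(seed, "folds", unit, k),
                   ids[sample.int(length(ids))])
  structure(list(
    k = as.integer(k), unit = unit, seed = as.integer(seed),
    assignment = tibble::tibble(unit_id = ord,
                                fold = rep_len(seq_len(k), length(ord))),
    order = ord),
    class = "fold_plan")
}

# Sentence keys belonging to a set of units.
unit_keys <- function(corpus, plan, unit_ids) {
  if (plan$unit == "sentence") return(unit_ids)
  sk <- corpus$sentences
  sentence_key(sk$record_id, sk$index)[sk$record_id %in% unit_ids]
}

#' Stepwise training sizes
#'
#' `n_steps` approximately evenly spaced training amounts, the first about
#' `n_total / n_steps` and the last exactly `n_total` (e.g. 10 steps over
#' 12,004 records run 1200, 2401, ... 12,004).
#'
#' @param n_total Total available units.
#' @param n_steps Number of steps (at least 2).
#' @return Strictly increasing integer vector of length `n_steps`.
#' @export
#' @examples
#' step_sizes(12004, 10)
step_sizes <- function(n_total, n_steps) {
  stopifnot(n_steps >= 2, n_total >= n_steps)
  sizes <- round(n_total * seq_len(n_steps) / n_steps)
  sizes[n_steps] <- n_total
  for (i in seq_len(n_steps - 1)[-1]) {
    if (sizes[i] <= sizes[i - 1]) sizes[i] <- sizes[i - 1] + 1L
  }
  stopifnot(all(diff(sizes) > 0))
  as.integer(sizes)
}

#' Trainer factories for learning-curve runs
#'
#' A trainer is `function(train_corpus, seed)` returning a tagging function
#' `function(corpus) -> ann_corpus` (the tagger may inspect the gold
#' entities of its input only if it is a simulator).
#'
#' * `crf_trainer()` fits the bundled CRF ([crf_fit()]) and tags with
#'   [crf_tag()].
#' * `memorizing_trainer()` returns the gold annotations unchanged — the
#'   oracle upper bound (F1 = 1 everywhere on noise-free data).
#' * `degraded_trainer(a, b)` simulates a tagger whose exact-match F1
#'   follows the power law `min(a * s^b, cap)` in the training size `s`:
#'   it deletes a matching fraction of gold mentions and adds the same
#'   number of spurious ones via [inject_errors()], so precision and recall
#'   both sit at the target.  With `method = "exact"` the realized F1 is
#'   deterministic up to count rounding.
#'
#' @param fconfig,tconfig CRF configurations.
#' @param a,b Power-law parameters of the simulated learning curve.
#' @param cap Ceiling applied to the simulated F1 (default 0.99).
#' @param method Passed to [injection_config()].
#' @return A trainer function.
#' @export
crf_trainer <- function(fconfig = feature_config(), tconfig = train_config()) {
  function(train_corpus, seed = 1L) {
    model <- crf_fit(train_corpus, fconfig, tconfig)
    function(corpus) crf_tag(model, corpus)
  }
}

#' @rdname crf_trainer
#' @export
memorizing_trainer <- function() {
  function(train_corpus, seed = 1L) function(corpus) corpus
}

#' @rdname crf_trainer
#' @export
degraded_trainer <- function(a = 0.40, b = 0.08, cap = 0.99,
                             method = "exact") {
  force(a); force(b); force(cap); force(method)
  function(train_corpus, seed = 1L) {
    size <- nrow(train_corpus$sentences)
    q <- min(a * size^b, cap)
    function(corpus) {
      cfg <- injection_config(p_delete = 1 - q, p_spurious = 1 - q,
                              method = method, seed = seed)
      inject_errors(corpus, cfg)$pred
    }
  }
}

#' Run a learning curve by cross-validation
#'
#' For every training size `s` and every fold `f`: train on the first `s`
#' units of the shuffled non-`f` folds, tag fold `f`, and evaluate against
#' its gold annotations.  Per-fold precision/recall/F1 (exact and including
#' partial matches) are aggregated into arithmetic means per size.  Fully
#' seeded and reproducible.
#'
#' @param corpus A gold [ann_corpus].
#' @param trainer A trainer factory (see [crf_trainer()]).
#' @param plan A [make_folds()] plan.
#' @param sizes Integer vector of training sizes in plan units; each must
#'   fit within the available training units of every fold.
#' @param config A [match_config()] for evaluation.
#' @param folds Which folds to evaluate (default all `1:k`).
#' @return An object of class `learning_curve`: a list with `points` (one
#'   row per size: mean metrics) and `folds` (one row per size x fold x
#'   mode).
#' @export
run_curve <- function(corpus, trainer, plan, sizes,
                      config = match_config(), folds = seq_len(plan$k)) {
  stopifnot(inherits(corpus, "ann_corpus"), inherits(plan, "fold_plan"))
  sizes <- as.integer(sizes)
  fold_of <- plan$assignment$fold[match(plan$order, plan$assignment$unit_id)]
  res <- list()
  for (f in folds) {
    train_units <- plan$order[fold_of != f]
    test_keys <- unit_keys(corpus, plan, plan$order[fold_of == f])
    test_gold <- corpus_subset(corpus, test_keys)
    for (s in sizes) {
      if (s > length(train_units)) {
        abort_bad_arg("size %d exceeds the %d units available outside fold %d",
                      s, length(train_units), f)
      }
      train_keys <- unit_keys(corpus, plan, train_units[seq_len(s)])
      train_corpus <- corpus_subset(corpus, train_keys)
      seed_sf <- derive_seed(plan$seed, "curve", s, f)
      tagger <- trainer(train_corpus, seed = seed_sf)
      pred <- tagger(test_gold)
      ev <- evaluate_ner(test_gold, pred, config)
      res[[length(res) + 1L]] <- dplyr::mutate(
        ev$metrics, train_size = s, fold = f, .before = 1)
    }
  }
  folds_tbl <- dplyr::bind_rows(res)
  points <- dplyr::summarise(
    dplyr::group_by(folds_tbl, .data$train_size, .data$mode),
    precision = mean(.data$precision), recall = mean(.data$recall),
    f1 = mean(.data$f1), n_folds = dplyr::n(), .groups = "drop")
  structure(list(points = points, folds = folds_tbl,
                 plan = list(k = plan$k, unit = plan$unit, seed = plan$seed),
                 sizes = sizes),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("<learning_curve> %d sizes x %d folds (unit: %s)\n",
              length(x$sizes), length(unique(x$folds$fold)), x$plan$unit))
  print(x$points)
  invisible(x)
}

#' Fit a power law to learning-curve points
#'
#' Least squares on the log-transformed pairs: `lm(log(y) ~ log(x))`, with
#' `a = exp(intercept)` and `b = slope`, modeling performance as
#' `y = a * x^b`.
#'
#' @param x Training sizes (positive), or a `learning_curve` object.
#' @param y Metric values (positive); ignored when `x` is a curve.
#' @param mode,metric When `x` is a `learning_curve`: which evaluation mode
#'   and metric column to fit (defaults `"exact"` F1).
#' @return An object of class `power_law_fit` with `a`, `b`, `r_squared` and
#'   the underlying `lm` fit.
#' @export
#' @examples
#' fit_power(c(1200, 3600, 12004), 0.4 * c(1200, 3600, 12004)^0.08)
fit_power <- function(x, y = NULL, mode = "exact", metric = "f1") {
  if (inherits(x, "learning_curve")) {
    pts <- x$points[x$points$mode == mode, ]
    y <- pts[[metric]]
    x <- pts$train_size
  }
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (any(x <= 0) || any(y <= 0)) {
    abort_bad_arg("power-law fitting needs strictly positive x and y")
  }
  fit <- stats::lm(ly ~ lx, data = data.frame(lx = log(x), ly = log(y)))
  # summary.lm warns on numerically perfect fits (e.g. noise-free curves)
  r2 <- if (length(x) == 2) 1 else suppressWarnings(summary(fit)$r.squared)
  structure(list(a = exp(unname(stats::coef(fit)[1])),
                 b = unname(stats::coef(fit)[2]),
                 r_squared = r2, fit = fit, n = length(x)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> y = %.4f * x^%.4f (R^2 = %.4f, n = %d)\n",
              x$a, x$b, x$r_squared, x$n))
  invisible(x)
}

#' Evaluate and invert a fitted power law
#'
#' `predict_f1()` evaluates `y = a * x^b`; `required_size()` inverts it,
#' `x = (y / a)^(1/b)`, answering "how much training data for a target
#' F1" (e.g. a = 0.40, b = 0.08 predicts F1 = 0.90 at about 25,251 training
#' records).
#'
#' @param fit A `power_law_fit` (or any list with `a` and `b`).
#' @param x Training sizes (positive).
#' @param y_target Target metric value (positive).
#' @return Numeric vector.
#' @export
#' @examples
#' predict_f1(list(a = 0.40, b = 0.08), 25251)
predict_f1 <- function(fit, x) {
  stopifnot(all(x > 0))
  fit$a * x^fit$b
}

#' @rdname predict_f1
#' @export
required_size <- function(fit, y_target) {
  stopifnot(all(y_target > 0))
  if (fit$b == 0) {
    abort_bad_arg("flat power law (b = 0) cannot be inverted")
  }
  (y_target / fit$a)^(1 / fit$b)
}
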