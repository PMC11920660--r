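#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidiers for fitted objects and evaluation results
#'
#' Broom-style summaries: `tidy()` returns one row per component (power-law
#' coefficients, evaluation metric rows, learning-curve points, CRF
#' weights), `glance()` a one-row model summary.
#'
#' @param x A `power_law_fit`, `ner_eval`, `learning_curve` or `crf_model`.
#' @param ... Unused.
#' @return A tibble.
#' @name sympner-tidiers
NULL

#' @rdname sympner-tidiers
#' @export
tidy.power_law_fit <- function(x, ...) {
  co <- suppressWarnings(summary(x$fit)$coefficients)
  tibble::tibble(
    term = c("a", "b"),
    estimate = c(x$a, x$b),
    std.error = c(x$a * co[1, 2], co[2, 2]))
}

#' @rdname sympner-tidiers
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, r_squared = x$r_squared, n = x$n)
}

#' @rdname sympner-tidiers
#' @export
tidy.ner_eval <- function(x, ...) x$metrics

#' @rdname sympner-tidiers
#' @export
glance.ner_eval <- function(x, ...) {
  m <- x$metrics
  ex <- m[m$mode == "exact", ]
  wp <- m[m$mode == "with_partial", ]
  ov <- x$errors[x$errors$category == "overall", ]
  tibble::tibble(
    n_gold = ex$n_gold, n_pred = ex$n_pred,
    precision_exact = ex$precision, recall_exact = ex$recall, f1_exact = ex$f1,
    f1_with_partial = wp$f1,
    total_extractions = if (nrow(ov)) ov$total_extractions else NA_integer_,
    overall_error_rate = if (nrow(ov)) ov$rate else NA_real_)
}

#' @rdname sympner-tidiers
#' @export
tidy.learning_curve <- function(x, ...) x$points

#' @rdname sympner-tidiers
#' @export
glance.learning_curve <- function(x, ...) {
  pts <- x$points[x$points$mode == "exact", ]
  tibble::tibble(n_sizes = length(x$sizes), k = x$plan$k, unit = x$plan$unit,
                 f1_first = pts$f1[which.min(pts$train_size)],
                 f1_last = pts$f1[which.max(pts$train_size)])
}

#' @rdname sympner-tidiers
#' @export
tidy.crf_model <- function(x, ...) {
  nz <- which(x$emission != 0, arr.ind = TRUE)
  dplyr::arrange(
    tibble::tibble(feature = x$features[nz[, 1]],
                   tag = x$labels[nz[, 2]],
                   weight = x$emission[nz]),
    dplyr::desc(abs(.data$weight)))
}

#' @rdname sympner-tidiers
#' @export
glance.crf_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$features),
                 n_vocab = length(x$char_vocab),
                 nll = x$nll, converged = x$convergence == 0)
}

#' Plot methods
#'
#' `autoplot.learning_curve()` draws mean F1 against training size (log-x)
#' for both evaluation modes, optionally overlaying a fitted power law;
#' `autoplot.ner_eval()` draws the error-category rates.
#'
#' @param object A `learning_curve` or `ner_eval`.
#' @param fit Optional `power_law_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @name sympner-autoplot
NULL

#' @rdname sympner-autoplot
#' @export
autoplot.learning_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object$points,
                       ggplot2::aes(x = .data$train_size, y = .data$f1,
                                    colour = .data$mode)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "training size (units)", y = "mean F1",
                  colour = "match mode")
  if (!is.null(fit)) {
    xs <- exp(seq(log(min(object$sizes)), log(max(object$sizes)),
                  length.out = 50))
    p <- p + ggplot2::geom_line(
      data = data.frame(train_size = xs, f1 = predict_f1(fit, xs),
                        mode = "power-law fit"),
      linetype = "dashed")
  }
  p
}

#' @rdname sympner-autoplot
#' @export
autoplot.ner_eval <- function(object, ...) {
  e <- object$errors[object$errors$category != "overall", ]
  ggplot2::ggplot(e, ggplot2::aes(x = .data$category, y = .data$rate)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "error rate (% of total extractions)")
}
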