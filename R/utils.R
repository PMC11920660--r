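#' Round half up
#'
#' Decimal rounding where ties go away from zero, the convention used when
#' printing clinical percentages (e.g. 6.05 -> 6.1 at one decimal), unlike
#' [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(0.665, 6.05, 2.5), 1)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Derive a reproducible child seed (< 2^31) from a base seed and a stream tag.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  raw <- utf8ToInt(key)
  h <- 0
  for (v in raw) h <- (h * 31 + v) %% 2147483587
  as.integer(h + 1L)
}

# Run code with a local RNG state seeded deterministically.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

chr_len <- function(x) stringr::str_length(x)

# Substring by 0-based half-open [start, end) character offsets.
substr0 <- function(x, start, end) stringr::str_sub(x, start + 1L, end)

abort_bad_arg <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = "sympner_error")
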