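#' Numerically stable softmax
#'
#' @param x numeric vector of logits.
#' @return probability vector summing to 1.
#' @keywords internal
softmax <- function(x) {
  if (!all(is.finite(x))) stop("softmax: non-finite logits")
  z <- exp(x - max(x))
  z / sum(z)
}

#' Row-wise softmax of a matrix
#' @keywords internal
softmax_rows <- function(m) {
  z <- exp(m - apply(m, 1L, max))
  z / rowSums(z)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Deterministic 31-bit string hash
#'
#' Polynomial rolling hash over the UTF-8 code points, seeded. Stable across
#' sessions and platforms (pure integer arithmetic in double precision,
#' always below 2^53).
#' @keywords internal
hash_string <- function(x, seed = 0L) {
  vapply(x, function(s) {
    h <- (as.numeric(seed) %% 2147483647) + 1
    for (cp in utf8ToInt(s)) h <- (h * 31 + cp) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Whitespace tokenization after light normalization
#'
#' Lowercases and collapses whitespace; punctuation is preserved inside
#' tokens. This is the tokenizer behind the post length filter and the mock
#' embedder.
#' @param x character vector.
#' @return list of character vectors (one per input text).
#' @export
tokenize <- function(x) {
  x <- tolower(trimws(x))
  strsplit(x, "\\s+")
}

#' Count whitespace tokens per text
#' @keywords internal
n_tokens <- function(x) {
  lengths(tokenize(x)) - (trimws(x) == "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample standard deviation that tolerates length-1 input
#' @keywords internal
sd_or_zero <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
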