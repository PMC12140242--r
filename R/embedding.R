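#' Construct an embedding backend
#'
#' A backend is the contract between the pipeline and whatever produces
#' sentence vectors: an id, a fixed output dimension, and a function mapping
#' a character vector to a `length(texts) x dim` numeric matrix. Backends
#' are frozen by assumption: the same text must always map to the same row,
#' and the head never backpropagates into the encoder. Real pretrained
#' sentence encoders (native dims such as 384 or 768) plug in by wrapping
#' their inference call in `embed_fn`; the deterministic
#' [mock_backend()] requires no external model and is the default in tests
#' and simulations.
#'
#' @param id short identifier string.
#' @param dim embedding dimension (>= 2).
#' @param embed_fn function(character) -> numeric matrix with `dim` columns.
#' @param deterministic logical flag, informational.
#' @return an `embedding_backend` object.
#' @export
embedding_backend <- function(id, dim, embed_fn, deterministic = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, dim >= 2L, is.function(embed_fn))
  structure(
    list(id = id, dim = as.integer(dim), fn = embed_fn,
         deterministic = isTRUE(deterministic)),
    class = "embedding_backend"
  )
}

#' @export
print.embedding_backend <- function(x, ...) {
  cat("<embedding_backend> ", x$id, " (dim ", x$dim,
      if (x$deterministic) ", deterministic" else "", ")\n", sep = "")
  invisible(x)
}

#' Embed a batch of texts
#'
#' @param backend an [embedding_backend()].
#' @param texts non-empty character vector; every text must contain at least
#'   one token.
#' @return numeric matrix, one row per text, `backend$dim` columns, with
#'   attributes `backend_id` and `dim`.
#' @export
embed_texts <- function(backend, texts) {
  stopifnot(inherits(backend, "embedding_backend"))
  if (!length(texts)) stop("no texts to embed")
  if (any(!nzchar(trimws(texts)))) stop("empty text cannot be embedded")
  m <- backend$fn(as.character(texts))
  if (!is.matrix(m) || nrow(m) != length(texts) || ncol(m) != backend$dim) {
    stop("backend '", backend$id, "' returned a malformed matrix")
  }
  if (!all(is.finite(m))) stop("backend '", backend$id, "' returned non-finite values")
  attr(m, "backend_id") <- backend$id
  attr(m, "dim_d") <- backend$dim
  m
}

# Deterministic +-1/sqrt(dim) vector per token: the rolling hash of the
# token seeds a small LCG whose high bit supplies one sign per dimension.
# Distinct tokens get near-orthogonal vectors (expected dot 0, sd
# 1/sqrt(dim)); identical tokens get identical vectors. Pure integer
# arithmetic kept below 2^53, so stable across sessions and platforms.
token_vectors <- function(tokens, dim, seed) {
  h <- hash_string(tokens, seed)
  V <- matrix(0, length(tokens), dim)
  for (j in seq_len(dim)) {
    h <- (h * 69069 + 1) %% 2147483648
    V[, j] <- ifelse(h >= 1073741824, 1, -1)
  }
  V / sqrt(dim)
}

#' Deterministic bag-of-tokens mock text embedding
#'
#' Every token maps to a fixed pseudo-random unit vector (signed
#' random-projection, derived from a seeded hash of the token); a text's
#' embedding is the sum of its token vectors, L2-normalized. Texts sharing
#' tokens therefore get systematically higher dot products than
#' token-disjoint texts (whose expected similarity is 0 with sd
#' `1/sqrt(dim)`), which is the geometric property the retrieval and head
#' algorithms rely on. Deterministic across sessions and platforms; no
#' external model needed.
#'
#' @param text a single text (>= 1 token).
#' @param dim embedding dimension (>= 2).
#' @param seed integer hash seed (default 0).
#' @return unit-norm numeric vector of length `dim`.
#' @export
mock_embed <- function(text, dim = 128L, seed = 0L) {
  drop(mock_embed_matrix(text, dim, seed))
}

# Vectorized mock embedding for many texts: sparse token-count matrix times
# the dense vocabulary projection.
mock_embed_matrix <- function(texts, dim, seed) {
  stopifnot(dim >= 2L)
  toks <- tokenize(texts)
  if (any(lengths(toks) == 0L)) stop("empty text cannot be embedded")
  vocab <- unique(unlist(toks, use.names = FALSE))
  V <- token_vectors(vocab, dim, seed)
  flat <- match(unlist(toks, use.names = FALSE), vocab)
  row <- rep.int(seq_along(texts), lengths(toks))
  counts <- Matrix::sparseMatrix(i = row, j = flat, x = 1,
                                 dims = c(length(texts), length(vocab)))
  m <- as.matrix(counts %*% V)
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1  # token vectors can cancel exactly; keep the zero row
  m / nrm
}

#' Deterministic mock sentence-embedding backend
#'
#' Wraps [mock_embed()] as an [embedding_backend()]. Intended as the default
#' encoder for tests and synthetic cohorts; see `mock_embed` for the
#' construction.
#'
#' @param dim embedding dimension.
#' @param seed integer hash seed.
#' @return an `embedding_backend`.
#' @export
mock_backend <- function(dim = 128L, seed = 0L) {
  embedding_backend(
    id = sprintf("mock-hash-d%d-s%d", as.integer(dim), as.integer(seed)),
    dim = dim,
    embed_fn = function(texts) mock_embed_matrix(texts, dim, seed)
  )
}

#' Word-vector backend with mean pooling
#'
#' For word-embedding models (as opposed to sentence encoders), a sentence
#' representation is the mean of its per-token vectors. The backend holds a
#' token -> vector table; out-of-vocabulary tokens are skipped, and a text
#' whose tokens are all out-of-vocabulary maps to the zero vector with a
#' warning.
#'
#' @param vectors numeric matrix with rownames = vocabulary tokens.
#' @param id identifier string.
#' @return an `embedding_backend`.
#' @export
word_vector_backend <- function(vectors, id = "word-mean") {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  embedding_backend(id, ncol(vectors), function(texts) {
    t(vapply(texts, function(tx) embed_word_mean_impl(vectors, tx),
             numeric(ncol(vectors)), USE.NAMES = FALSE))
  })
}

embed_word_mean_impl <- function(vectors, text) {
  toks <- tokenize(text)[[1]]
  if (!length(toks)) stop("text has no tokens")
  known <- toks[toks %in% rownames(vectors)]
  if (!length(known)) {
    warning("all tokens out of vocabulary; returning zero vector")
    return(numeric(ncol(vectors)))
  }
  colMeans(vectors[known, , drop = FALSE])
}

#' Mean-of-word-vectors sentence embedding
#'
#' @param backend a backend created by [word_vector_backend()] (or any
#'   backend; the text is embedded through it).
#' @param text a single text.
#' @return numeric vector of length `backend$dim`.
#' @export
embed_word_mean <- function(backend, text) {
  stopifnot(inherits(backend, "embedding_backend"))
  drop(backend$fn(text))
}
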