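#' Dot-product relevance of posts against an item description
#'
#' Zero-shot dense retrieval scores each post embedding against the item
#' description embedding by a raw dot product (no normalization), i.e.
#' `similarity(E_p, E_item) = E_p . E_item`.
#'
#' @param post_embeddings n x d numeric matrix.
#' @param item_embedding length-d numeric vector.
#' @return numeric vector of n similarities.
#' @export
score_posts <- function(post_embeddings, item_embedding) {
  if (!is.matrix(post_embeddings)) post_embeddings <- rbind(post_embeddings)
  if (ncol(post_embeddings) != length(item_embedding)) {
    stop("dimension mismatch: posts are d=", ncol(post_embeddings),
         ", item is d=", length(item_embedding))
  }
  drop(post_embeddings %*% item_embedding)
}

#' Top-k most relevant posts for one (user, item) pair
#'
#' Selects the `k` posts with the largest dot-product similarity to the
#' item description embedding. Ties are broken by ascending post index, so
#' retrieval is fully deterministic. When fewer than `k` posts exist, all
#' posts are returned.
#'
#' @param post_embeddings n x d matrix of the user's (filtered) post
#'   embeddings, rows aligned with `post_ids`.
#' @param item_embedding length-d description embedding.
#' @param k number of posts to retrieve (default 20).
#' @param post_ids optional ids aligned with rows (default row sequence).
#' @return a `retrieved_set`: list with `post_indices` (row indices into
#'   `post_embeddings`), `post_ids`, `similarities` (non-increasing),
#'   `embeddings` (the retrieved rows) and `k_requested`.
#' @export
retrieve_top_k <- function(post_embeddings, item_embedding, k = 20L,
                           post_ids = NULL) {
  if (!is.matrix(post_embeddings)) post_embeddings <- rbind(post_embeddings)
  n <- nrow(post_embeddings)
  if (n == 0L) stop("no posts to retrieve from")
  stopifnot(k >= 1L)
  sims <- score_posts(post_embeddings, item_embedding)
  # order by similarity desc, index asc on ties
  ord <- order(-sims, seq_len(n))
  take <- ord[seq_len(min(k, n))]
  structure(
    list(
      post_indices = take,
      post_ids = if (is.null(post_ids)) take else post_ids[take],
      similarities = sims[take],
      embeddings = post_embeddings[take, , drop = FALSE],
      k_requested = as.integer(k)
    ),
    class = "retrieved_set"
  )
}

#' @export
print.retrieved_set <- function(x, ...) {
  cat("<retrieved_set> ", length(x$post_indices), "/", x$k_requested,
      " posts; similarity range [", round(min(x$similarities), 4), ", ",
      round(max(x$similarities), 4), "]\n", sep = "")
  invisible(x)
}

#' Retrieval results for every (user, item) pair as a table
#'
#' @param sets named list (by user) of lists (by item) of `retrieved_set`.
#' @return data frame with user_id, item_id, rank, post_id, similarity.
#' @export
retrieval_table <- function(sets) {
  rows <- list()
  for (uid in names(sets)) {
    for (item in seq_along(sets[[uid]])) {
      rs <- sets[[uid]][[item]]
      if (is.null(rs)) next
      rows[[length(rows) + 1L]] <- data.frame(
        user_id = uid, item_id = item,
        rank = seq_along(rs$post_indices),
        post_id = rs$post_ids,
        similarity = rs$similarities,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
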