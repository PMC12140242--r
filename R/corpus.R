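#' Construct a user corpus
#'
#' A `user_corpus` holds one user's posts (a data frame with `post_id`,
#' `timestamp`, `text`) plus optional gold item scores (length-21 integer
#' vector, each entry in 0-3).
#'
#' @param user_id identifier (coerced to character).
#' @param posts data frame with at least a `text` column; `post_id` defaults
#'   to the row sequence and `timestamp` to `NA`.
#' @param gold_scores optional integer vector of 21 item scores.
#' @return a `user_corpus` object.
#' @export
user_corpus <- function(user_id, posts, gold_scores = NULL) {
  stopifnot(is.data.frame(posts), "text" %in% names(posts))
  text <- as.character(posts$text)
  if (anyNA(text)) stop("user ", user_id, ": missing post text")
  posts <- data.frame(
    post_id = if ("post_id" %in% names(posts)) as.integer(posts$post_id) else seq_along(text),
    timestamp = if ("timestamp" %in% names(posts)) as.character(posts$timestamp) else NA_character_,
    text = text,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(posts$post_id)) stop("user ", user_id, ": duplicate post_id")
  if (!is.null(gold_scores)) {
    if (length(gold_scores) != 21L || anyNA(gold_scores) || !all(gold_scores %in% 0:3)) {
      stop("user ", user_id, ": gold_scores must be 21 integers in {0,1,2,3}")
    }
    gold_scores <- as.integer(gold_scores)
  }
  structure(
    list(user_id = as.character(user_id), posts = posts, gold_scores = gold_scores),
    class = "user_corpus"
  )
}

#' @export
print.user_corpus <- function(x, ...) {
  cat("<user_corpus> ", x$user_id, ": ", nrow(x$posts), " posts",
      if (!is.null(x$gold_scores)) paste0(", overall gold ", sum(x$gold_scores)),
      "\n", sep = "")
  invisible(x)
}

#' Read per-user post collections from a line-delimited JSON file
#'
#' Each line is one JSON record with fields `user_id`, `text` and optional
#' `timestamp`. Posts are grouped by user in original line order; the line
#' order defines the post order and (absent an explicit `post_id`) the
#' post ids.
#'
#' @param path file path.
#' @return named list of `user_corpus` objects, keyed by user id, in order
#'   of first appearance.
#' @export
read_posts <- function(path) {
  if (!file.exists(path)) stop("post file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  idx <- which(nzchar(trimws(lines)))
  if (!length(idx)) return(list())
  recs <- lapply(idx, function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("line ", i, ": malformed record"))
    if (is.null(rec$user_id)) stop("line ", i, ": missing field 'user_id'")
    if (is.null(rec$text)) stop("line ", i, ": missing field 'text'")
    rec
  })
  uid <- vapply(recs, function(r) as.character(r$user_id), character(1))
  tab <- data.frame(
    user_id = uid,
    timestamp = vapply(recs, function(r) as.character(r$timestamp %||% NA_character_),
                       character(1)),
    text = vapply(recs, function(r) as.character(r$text), character(1)),
    stringsAsFactors = FALSE
  )
  users <- unique(uid)
  out <- lapply(users, function(u) {
    user_corpus(u, tab[tab$user_id == u, c("timestamp", "text"), drop = FALSE])
  })
  stats::setNames(out, users)
}

#' Attach gold item scores from a tabular file
#'
#' The score file is CSV with a `user_id` column followed by 21 integer
#' columns (one per item, in item order).
#'
#' @param corpora named list of `user_corpus`.
#' @param path CSV path.
#' @return the corpora with `gold_scores` filled in where available.
#' @export
read_gold_scores <- function(corpora, path) {
  if (!file.exists(path)) stop("score file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"user_id" %in% names(tab)) stop("score file must have a user_id column")
  score_cols <- setdiff(names(tab), "user_id")
  if (length(score_cols) != 21L) {
    stop("score file must have 21 item columns, got ", length(score_cols))
  }
  for (r in seq_len(nrow(tab))) {
    uid <- as.character(tab$user_id[r])
    if (uid %in% names(corpora)) {
      corpora[[uid]]$gold_scores <- as.integer(unlist(tab[r, score_cols]))
      if (length(corpora[[uid]]$gold_scores) != 21L ||
          !all(corpora[[uid]]$gold_scores %in% 0:3)) {
        stop("user ", uid, ": scores must be 21 integers in {0,1,2,3}")
      }
    }
  }
  corpora
}

#' Drop posts shorter than a token threshold
#'
#' Retains posts with at least `min_words` whitespace tokens; the default
#' of 3 implements the "more than two words" rule used when assembling the
#' retrieval pool. Post ids are preserved. A user whose posts are all too
#' short is retained with zero posts (and a message).
#'
#' @param corpus a `user_corpus`.
#' @param min_words minimum token count (>= 1).
#' @return the filtered `user_corpus`.
#' @export
filter_short_posts <- function(corpus, min_words = 3L) {
  stopifnot(inherits(corpus, "user_corpus"), min_words >= 1L)
  keep <- n_tokens(corpus$posts$text) >= min_words
  corpus$posts <- corpus$posts[keep, , drop = FALSE]
  rownames(corpus$posts) <- NULL
  if (nrow(corpus$posts) == 0L) {
    message("user ", corpus$user_id, ": no posts survive the length filter")
  }
  corpus
}

#' Split users into train and test sets
#'
#' User-level holdout: the test set has `round(n * test_fraction)` users,
#' drawn without replacement; deterministic given `seed`. Users are never
#' split across sets, so no post of a test user is seen in training.
#'
#' @param corpora named list of `user_corpus`.
#' @param test_fraction in (0, 1); default 0.2 (an 80/20 holdout).
#' @param seed integer RNG seed.
#' @return list with elements `train` and `test` (named lists of corpora).
#' @export
split_users <- function(corpora, test_fraction = 0.2, seed = 1L) {
  n <- length(corpora)
  if (n < 2L) stop("need at least 2 users to split")
  if (!(test_fraction > 0 && test_fraction < 1)) stop("test_fraction must be in (0, 1)")
  n_test <- max(1L, round(n * test_fraction))
  test_idx <- sort(with_seed(seed, sample.int(n, n_test)))
  list(train = corpora[-test_idx], test = corpora[test_idx])
}

#' Summary statistics of a corpus collection
#'
#' Posts-per-user mean/median/sd (sample sd by default), the coefficient of
#' variation in percent, score marginals over all (user, item) gold scores,
#' and severity category counts from the gold overall scores.
#'
#' @param corpora named list of `user_corpus`.
#' @param sd_denominator `"sample"` (n-1, default) or `"population"` (n).
#' @return a `corpus_stats` list.
#' @export
summarize_corpus <- function(corpora, sd_denominator = c("sample", "population")) {
  sd_denominator <- match.arg(sd_denominator)
  counts <- vapply(corpora, function(u) nrow(u$posts), numeric(1))
  n <- length(counts)
  m <- mean(counts)
  s <- sd_or_zero(counts)
  if (sd_denominator == "population" && n > 1L) s <- s * sqrt((n - 1) / n)
  cv <- if (m > 0) 100 * s / m else NA_real_

  gold <- lapply(corpora, function(u) u$gold_scores)
  gold <- gold[!vapply(gold, is.null, logical(1))]
  marginals <- category_counts <- NULL
  if (length(gold)) {
    all_scores <- unlist(gold)
    marginals <- as.numeric(table(factor(all_scores, levels = 0:3))) / length(all_scores)
    names(marginals) <- 0:3
    overall <- vapply(gold, sum, numeric(1))
    cats <- categorize_overall(overall)
    category_counts <- as.integer(table(factor(cats, levels = 0:3)))
    names(category_counts) <- severity_labels()
  }
  structure(
    list(
      n_users = n,
      posts_per_user_mean = m,
      posts_per_user_median = stats::median(counts),
      posts_per_user_sd = s,
      cv_percent = cv,
      score_marginals = marginals,
      category_counts = category_counts
    ),
    class = "corpus_stats"
  )
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat("<corpus_stats> ", x$n_users, " users; posts/user mean ",
      round(x$posts_per_user_mean, 1), ", median ", x$posts_per_user_median,
      ", sd ", round(x$posts_per_user_sd, 1), " (CV ",
      round(x$cv_percent, 2), "%)\n", sep = "")
  if (!is.null(x$score_marginals)) {
    cat("  score marginals:", paste(sprintf("%d: %.1f%%", 0:3, 100 * x$score_marginals),
                                    collapse = ", "), "\n")
    cat("  categories:", paste(names(x$category_counts), x$category_counts,
                               collapse = ", "), "\n")
  }
  invisible(x)
}
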