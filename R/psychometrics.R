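#' Users x items score matrix from corpora
#'
#' @param corpora named list of `user_corpus`, all with gold scores.
#' @param item_names optional column names (e.g. from a questionnaire).
#' @return integer matrix, one row per user, 21 columns.
#' @export
score_matrix <- function(corpora, item_names = NULL) {
  gold <- lapply(corpora, function(u) {
    if (is.null(u$gold_scores)) stop("user ", u$user_id, " has no gold scores")
    u$gold_scores
  })
  m <- do.call(rbind, gold)
  rownames(m) <- names(corpora)
  if (!is.null(item_names)) colnames(m) <- item_names
  m
}

check_score_matrix <- function(m, min_users = 2L) {
  if (!is.matrix(m)) stop("expected a users x items matrix")
  if (anyNA(m)) stop("score matrix has missing entries")
  if (nrow(m) < min_users) stop("need at least ", min_users, " users")
  if (ncol(m) < 2L) stop("need at least 2 items")
  invisible(TRUE)
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = K/(K-1) * (1 - sum_i var(item_i) / var(total))` over a
#' users x items score matrix, with sample (n-1) variances.
#'
#' @param m users x items numeric matrix.
#' @return alpha (scalar).
#' @export
cronbach_alpha <- function(m) {
  check_score_matrix(m)
  K <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) stop("total-score variance is zero; alpha undefined")
  item_vars <- apply(m, 2L, stats::var)
  K / (K - 1) * (1 - sum(item_vars) / total_var)
}

#' Corrected item-total correlations
#'
#' For each item, the Pearson correlation between its scores and the sum of
#' all *other* items (the total excluding the item itself). Items with zero
#' variance, or whose rest-total has zero variance, get `NA`.
#'
#' @param m users x items numeric matrix (>= 3 users).
#' @return numeric vector, one value per item.
#' @export
item_total_correlations <- function(m) {
  check_score_matrix(m, min_users = 3L)
  total <- rowSums(m)
  vapply(seq_len(ncol(m)), function(j) {
    rest <- total - m[, j]
    if (stats::var(m[, j]) == 0 || stats::var(rest) == 0) return(NA_real_)
    stats::cor(m[, j], rest)
  }, numeric(1))
}

#' Per-item mean and sample standard deviation
#'
#' @param m users x items numeric matrix.
#' @return data frame with item, mean, sd.
#' @export
item_descriptives <- function(m) {
  check_score_matrix(m)
  data.frame(
    item = colnames(m) %||% paste0("item_", seq_len(ncol(m))),
    mean = colMeans(m),
    sd = apply(m, 2L, stats::sd),
    row.names = NULL
  )
}

#' Internal-reliability report for a score matrix
#'
#' Per-item mean, SD and corrected item-total correlation, with Cronbach's
#' alpha as a footer — the standard reliability table layout.
#'
#' @param m users x items numeric matrix.
#' @return a `reliability_report`: the per-item data frame with an `alpha`
#'   attribute.
#' @export
reliability_report <- function(m) {
  tab <- item_descriptives(m)
  tab$item_total_corr <- item_total_correlations(m)
  structure(tab, alpha = cronbach_alpha(m), class = c("reliability_report", "data.frame"))
}

#' @export
print.reliability_report <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  y$mean <- round(y$mean, digits)
  y$sd <- round(y$sd, digits)
  y$item_total_corr <- round(y$item_total_corr, digits)
  print.data.frame(y, row.names = FALSE)
  cat(sprintf("Cronbach's alpha: %.2f  (%d items)\n", attr(x, "alpha"), nrow(x)))
  invisible(x)
}
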