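#' Calibration targets for the synthetic cohort generator
#'
#' The published summary statistics of the 100-user reference cohort the
#' generator emulates: posts-per-user mean/median/std, the relative
#' frequencies of the four item scores, and the severity category counts.
#'
#' @return list with `n_users`, `posts_mean`, `posts_median`, `posts_sd`,
#'   `score_marginals`, `category_counts`.
#' @export
bdi_cohort_targets <- function() {
  list(
    n_users = 100L,
    posts_mean = 274,
    posts_median = 165,
    posts_sd = 265,
    score_marginals = c(`0` = 0.25, `1` = 0.35, `2` = 0.23, `3` = 0.17),
    category_counts = c(Minimal = 10L, Mild = 17L, Moderate = 31L, Severe = 42L)
  )
}

#' Configuration of a synthetic cohort
#'
#' The generator draws, per user, a latent severity factor; item scores come
#' from a Gaussian copula (shared factor loading
#' `sqrt(inter_item_correlation)`) thresholded to match `score_marginals`
#' exactly in distribution. Post counts default to a lognormal matched to
#' the target mean and median (274 / 165), which reproduces the heavy right
#' skew of real posting histories. Each post is a *signal* post with
#' probability `signal_strength`: it is assigned to one questionnaire item
#' and its tokens are drawn from the text of that item's gold-choice (at
#' purity `signal_strength`, noise tokens otherwise). Non-signal posts are
#' pure noise tokens.
#'
#' @param n_users number of users (default 100, the reference cohort size).
#' @param score_marginals probabilities of scores 0-3 (default the
#'   reference 0.25/0.35/0.23/0.17).
#' @param signal_strength in [0, 1]; 0 plants no signal at all.
#' @param inter_item_correlation latent inter-item correlation in [0, 1).
#' @param posts_family `"lognormal"` (default) or `"fixed"`.
#' @param posts_mean,posts_median lognormal calibration (mean 274,
#'   median 165 by default).
#' @param posts_fixed post count per user when `posts_family = "fixed"`.
#' @param tokens_per_post integer range (min, max) of tokens per post.
#' @param vocabulary_size number of distinct noise tokens.
#' @param seed integer seed; the cohort is a deterministic function of the
#'   full configuration.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_users = 100L,
                          score_marginals = c(0.25, 0.35, 0.23, 0.17),
                          signal_strength = 0.8,
                          inter_item_correlation = 0.6,
                          posts_family = c("lognormal", "fixed"),
                          posts_mean = 274, posts_median = 165,
                          posts_fixed = 30L,
                          tokens_per_post = c(8L, 16L),
                          vocabulary_size = 1000L,
                          seed = 1L) {
  posts_family <- match.arg(posts_family)
  if (length(score_marginals) != 4L || any(score_marginals < 0) ||
      abs(sum(score_marginals) - 1) > 1e-9) {
    stop("score_marginals must be 4 non-negative probabilities summing to 1")
  }
  if (signal_strength < 0 || signal_strength > 1) stop("signal_strength must be in [0, 1]")
  if (inter_item_correlation < 0 || inter_item_correlation >= 1) {
    stop("inter_item_correlation must be in [0, 1)")
  }
  if (posts_family == "lognormal" && posts_mean < posts_median) {
    stop("lognormal post counts require mean >= median")
  }
  stopifnot(n_users >= 1L, vocabulary_size >= 10L,
            length(tokens_per_post) == 2L, tokens_per_post[1] >= 3L)
  structure(as.list(environment()), class = "cohort_config")
}

#' Synthetic questionnaire with item-specific token vocabularies
#'
#' A questionnaire whose descriptions and choice texts are synthetic token
#' sequences: each item owns four topic tokens (its description; two of
#' them recur in every choice, which is what makes signal posts retrievable
#' by the item description), and each choice adds four choice-specific
#' tokens (which is what makes the gold choice identifiable). This gives
#' the generator full control over the semantic geometry that the mock
#' embedder turns into vector geometry.
#'
#' @param n_items number of items (default 21).
#' @return a `questionnaire` object.
#' @export
synthetic_questionnaire <- function(n_items = 21L) {
  items <- lapply(seq_len(n_items), function(j) {
    topic <- sprintf("i%dt%d", j, 1:4)
    list(
      item_id = as.integer(j),
      name = paste("Synthetic item", j),
      description = paste(topic, collapse = " "),
      choices = lapply(0:3, function(s) {
        list(score = as.integer(s),
             text = paste(c(topic[1:2], sprintf("i%dc%dt%d", j, s, 1:4)),
                          collapse = " "))
      })
    )
  })
  structure(list(name = "synthetic", items = items), class = "questionnaire")
}

# Lognormal (meanlog, sdlog) matched to a target mean and median:
# median = exp(mu), mean = exp(mu + s^2/2)  =>  s^2 = 2 log(mean/median).
lognormal_match <- function(mean, median) {
  list(meanlog = log(median), sdlog = sqrt(2 * log(mean / median)))
}

#' Generate a synthetic cohort
#'
#' Draws per-user latent severity, correlated item scores (Gaussian copula
#' thresholded to the configured marginals), post counts, and post texts
#' with a planted semantic link between signal posts and the user's gold
#' choice per item. Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param questionnaire the instrument providing choice texts for signal
#'   posts; default [synthetic_questionnaire()].
#' @return a `synthetic_cohort`: list with `corpora` (named list of
#'   `user_corpus` with gold scores), `provenance` (data frame: user_id,
#'   post_id, signal_item — `NA` for noise posts), `questionnaire`, and
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            questionnaire = synthetic_questionnaire()) {
  stopifnot(inherits(config, "cohort_config"), inherits(questionnaire, "questionnaire"))
  n_items <- length(questionnaire$items)
  if (n_items != 21L) stop("cohort generation requires a 21-item instrument")
  # token pools of each item's choices, by [item][score + 1]
  pools <- lapply(questionnaire$items, function(it) {
    lapply(it$choices, function(ch) tokenize(ch$text)[[1]])
  })
  noise_vocab <- sprintf("w%d", seq_len(config$vocabulary_size))
  thresholds <- stats::qnorm(cumsum(config$score_marginals))[1:3]
  rho <- config$inter_item_correlation

  with_seed(config$seed, {
    z <- stats::rnorm(config$n_users)
    eps <- matrix(stats::rnorm(config$n_users * n_items), config$n_users, n_items)
    latent <- sqrt(rho) * z + sqrt(1 - rho) * eps
    scores <- matrix(findInterval(latent, thresholds), config$n_users, n_items)

    counts <- if (config$posts_family == "fixed") {
      rep.int(config$posts_fixed, config$n_users)
    } else {
      lp <- lognormal_match(config$posts_mean, config$posts_median)
      pmax(1L, as.integer(round(stats::rlnorm(config$n_users, lp$meanlog, lp$sdlog))))
    }

    corpora <- vector("list", config$n_users)
    prov <- vector("list", config$n_users)
    uids <- sprintf("user%03d", seq_len(config$n_users))
    for (u in seq_len(config$n_users)) {
      n_p <- counts[u]
      len <- sample(config$tokens_per_post[1]:config$tokens_per_post[2],
                    n_p, replace = TRUE)
      is_signal <- stats::runif(n_p) < config$signal_strength
      sig_item <- ifelse(is_signal, sample.int(n_items, n_p, replace = TRUE),
                         NA_integer_)
      texts <- character(n_p)
      for (p in seq_len(n_p)) {
        if (is_signal[p]) {
          pool <- pools[[sig_item[p]]][[scores[u, sig_item[p]] + 1L]]
          from_pool <- stats::runif(len[p]) < config$signal_strength
          toks <- ifelse(from_pool,
                         sample(pool, len[p], replace = TRUE),
                         sample(noise_vocab, len[p], replace = TRUE))
        } else {
          toks <- sample(noise_vocab, len[p], replace = TRUE)
        }
        texts[p] <- paste(toks, collapse = " ")
      }
      corpora[[u]] <- user_corpus(uids[u], data.frame(text = texts),
                                  gold_scores = scores[u, ])
      prov[[u]] <- data.frame(user_id = uids[u], post_id = seq_len(n_p),
                              signal_item = sig_item, stringsAsFactors = FALSE)
    }
    structure(
      list(corpora = stats::setNames(corpora, uids),
           provenance = do.call(rbind, prov),
           questionnaire = questionnaire,
           config = config),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$corpora), " users, ",
      nrow(x$provenance), " posts (signal fraction ",
      round(mean(!is.na(x$provenance$signal_item)), 2), ")\n", sep = "")
  invisible(x)
}

#' Compare a cohort's empirical statistics to calibration targets
#'
#' Checks posts-per-user mean/median/sd, score marginals and category
#' proportions against a target list (default [bdi_cohort_targets()]).
#' Tolerances are relative for the post-count statistics and absolute for
#' proportions; the sd tolerance is wide because a two-parameter lognormal
#' matched to the target mean and median implies a larger sd than the
#' target's (a documented limitation of the post-count model). Category
#' proportions under the single-factor copula approximate, but do not
#' exactly reproduce, the target's empirical imbalance.
#'
#' @param cohort a `synthetic_cohort` (or list of `user_corpus`).
#' @param targets list shaped like [bdi_cohort_targets()].
#' @param tol named list of tolerances: `posts_mean`, `posts_median`
#'   (relative), `posts_sd` (relative), `marginal` (absolute, per score),
#'   `category` (absolute, per category proportion).
#' @return a `fidelity_report` data frame: statistic, observed, target,
#'   tolerance, pass.
#' @export
cohort_fidelity <- function(cohort, targets = bdi_cohort_targets(),
                            tol = list(posts_mean = 0.25, posts_median = 0.25,
                                       posts_sd = 0.75, marginal = 0.05,
                                       category = 0.15)) {
  corpora <- if (inherits(cohort, "synthetic_cohort")) cohort$corpora else cohort
  stats <- summarize_corpus(corpora)
  rows <- list(
    data.frame(statistic = "posts_mean", observed = stats$posts_per_user_mean,
               target = targets$posts_mean, tolerance = tol$posts_mean,
               pass = rel_ok(stats$posts_per_user_mean, targets$posts_mean, tol$posts_mean)),
    data.frame(statistic = "posts_median", observed = stats$posts_per_user_median,
               target = targets$posts_median, tolerance = tol$posts_median,
               pass = rel_ok(stats$posts_per_user_median, targets$posts_median, tol$posts_median)),
    data.frame(statistic = "posts_sd", observed = stats$posts_per_user_sd,
               target = targets$posts_sd, tolerance = tol$posts_sd,
               pass = rel_ok(stats$posts_per_user_sd, targets$posts_sd, tol$posts_sd))
  )
  for (s in 1:4) {
    obs <- stats$score_marginals[s]
    tgt <- targets$score_marginals[s]
    rows[[length(rows) + 1L]] <- data.frame(
      statistic = paste0("marginal_score_", s - 1L), observed = obs,
      target = tgt, tolerance = tol$marginal, pass = abs(obs - tgt) <= tol$marginal)
  }
  tgt_prop <- targets$category_counts / sum(targets$category_counts)
  obs_prop <- stats$category_counts / sum(stats$category_counts)
  for (s in 1:4) {
    rows[[length(rows) + 1L]] <- data.frame(
      statistic = paste0("category_prop_", severity_labels()[s]),
      observed = obs_prop[s], target = tgt_prop[s], tolerance = tol$category,
      pass = abs(obs_prop[s] - tgt_prop[s]) <= tol$category)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fidelity_report", "data.frame")
  out
}

rel_ok <- function(obs, tgt, tol) abs(obs - tgt) <= tol * abs(tgt)

#' Write a cohort to the corpus file formats
#'
#' Emits the line-delimited post file, the gold-score CSV, and the
#' provenance CSV readable by [read_posts()] / [read_gold_scores()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  posts_path <- file.path(dir, "posts.jsonl")
  con <- file(posts_path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (u in cohort$corpora) {
    for (i in seq_len(nrow(u$posts))) {
      writeLines(jsonlite::toJSON(
        list(user_id = u$user_id, post_id = u$posts$post_id[i],
             text = u$posts$text[i]),
        auto_unbox = TRUE), con)
    }
  }
  scores_path <- file.path(dir, "gold_scores.csv")
  sm <- score_matrix(cohort$corpora, item_names = paste0("item_", seq_len(21)))
  utils::write.csv(data.frame(user_id = rownames(sm), sm, check.names = FALSE,
                              row.names = NULL),
                   scores_path, row.names = FALSE)
  prov_path <- file.path(dir, "provenance.csv")
  utils::write.csv(cohort$provenance, prov_path, row.names = FALSE)
  invisible(c(posts = posts_path, scores = scores_path, provenance = prov_path))
}
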