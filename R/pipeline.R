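#' Build head instances for every (user, item) pair
#'
#' Filters each user's posts, embeds them, retrieves the top-k posts per
#' questionnaire item and assembles [item_instance()] objects (with gold
#' scores when the corpus carries them). Users left with zero posts after
#' filtering are skipped with a warning.
#'
#' @param corpora named list of `user_corpus`.
#' @param questionnaire a `questionnaire`.
#' @param backend an `embedding_backend`.
#' @param k retrieval size.
#' @param min_words post length filter threshold.
#' @return list of `item_instance` objects.
#' @export
build_instances <- function(corpora, questionnaire, backend, k = 20L,
                            min_words = 3L) {
  qe <- embed_questionnaire(questionnaire, backend)
  n_items <- length(questionnaire$items)
  out <- list()
  for (u in corpora) {
    u <- filter_short_posts(u, min_words)
    if (nrow(u$posts) == 0L) {
      warning("user ", u$user_id, " has no usable posts; skipped")
      next
    }
    post_emb <- embed_texts(backend, u$posts$text)
    for (j in seq_len(n_items)) {
      rs <- retrieve_top_k(post_emb, qe$descriptions[j, ], k = k,
                           post_ids = u$posts$post_id)
      out[[length(out) + 1L]] <- item_instance(
        qe$descriptions[j, ], qe$choices[[j]], rs$embeddings,
        gold_score = if (is.null(u$gold_scores)) NULL else u$gold_scores[j],
        item_id = j, user_id = u$user_id
      )
    }
  }
  out
}

# Predict item scores for a set of instances with a trained head, grouped
# by user.
predict_instances <- function(instances, params) {
  users <- unique(vapply(instances, `[[`, "", "user_id"))
  preds <- stats::setNames(vector("list", length(users)), users)
  for (ins in instances) {
    p <- forward_head(ins, params)
    preds[[ins$user_id]][ins$item_id] <- p$predicted_score
  }
  preds
}

#' Run the full retrieve-train-predict-evaluate experiment
#'
#' End-to-end orchestration: filter posts, split users (user-level holdout,
#' never post-level), embed with a frozen backend, retrieve the top-k posts
#' per (user, item), train the head on the training users, predict the test
#' users, and evaluate at item, overall and category granularity against
#' the gold scores. Also computes the majority-class baseline (modal train
#' category, scored on test). Fully deterministic given the seeds in the
#' configuration.
#'
#' @param corpora named list of `user_corpus` with gold scores.
#' @param questionnaire a `questionnaire` (default the bundled BDI-II).
#' @param backend embedding backend (default [mock_backend()]).
#' @param k retrieval size (default 20).
#' @param test_fraction user-level holdout fraction (default 0.2).
#' @param split_seed seed of the user split.
#' @param train a [train_config()].
#' @param min_words post length filter threshold.
#' @return list with `report` (an `evaluation_report` on the test users),
#'   `baseline` (majority-class), `params` (trained head), `predictions`
#'   (per test user), `gold` (per test user), and `manifest` (config echo,
#'   seeds, sizes, timings).
#' @export
run_experiment <- function(corpora, questionnaire = bdi2(),
                           backend = mock_backend(), k = 20L,
                           test_fraction = 0.2, split_seed = 1L,
                           train = train_config(), min_words = 3L) {
  t0 <- Sys.time()
  if (any(vapply(corpora, function(u) is.null(u$gold_scores), logical(1)))) {
    stop("every user needs gold scores to run the experiment")
  }
  split <- split_users(corpora, test_fraction, split_seed)
  stopifnot(length(intersect(names(split$train), names(split$test))) == 0L)

  train_ins <- build_instances(split$train, questionnaire, backend, k, min_words)
  params <- train_head(train_ins, config = train, k = k)
  params$backend_id <- backend$id

  test_ins <- build_instances(split$test, questionnaire, backend, k, min_words)
  pred <- predict_instances(test_ins, params)
  gold <- lapply(split$test[names(pred)], `[[`, "gold_scores")

  report <- evaluate_predictions(gold, pred)
  train_cats <- categorize_overall(
    vapply(split$train, function(u) sum(u$gold_scores), numeric(1)))
  test_cats <- categorize_overall(vapply(gold, sum, numeric(1)))
  baseline <- majority_baseline(train_cats, test_cats)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ensembert")),
    backend_id = backend$id, d = backend$dim, k = as.integer(k),
    min_words = as.integer(min_words),
    test_fraction = test_fraction, split_seed = split_seed,
    train_config = unclass(train),
    n_users_train = length(split$train), n_users_test = length(split$test),
    n_instances_train = length(train_ins), n_instances_test = length(test_ins),
    best_epoch = attr(params, "best_epoch"),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  list(report = report, baseline = baseline, params = params,
       predictions = pred, gold = gold, manifest = manifest)
}
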