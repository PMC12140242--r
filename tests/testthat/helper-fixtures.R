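# Small fixtures shared across test files; everything is built in code.

toy_corpus <- function(user_id = "u1", texts = c("I feel sad today",
                                                 "great game last night",
                                                 "ok"),
                       gold = NULL) {
  user_corpus(user_id, data.frame(text = texts), gold_scores = gold)
}

# n users with fixed post counts and gold scores drawn under a seed
toy_corpora <- function(n = 6, seed = 1) {
  with_seed <- get("with_seed", asNamespace("ensembert"))
  with_seed(seed, {
    out <- lapply(seq_len(n), function(i) {
      texts <- replicate(5, paste(sample(letters, 4, replace = TRUE), collapse = " "))
      user_corpus(paste0("u", i), data.frame(text = texts),
                  gold_scores = sample(0:3, 21, replace = TRUE))
    })
    stats::setNames(out, paste0("u", seq_len(n)))
  })
}

# a tiny instance with controllable geometry
toy_instance <- function(d = 6, kp = 3, gold = 1, seed = 42) {
  set.seed(seed)
  norm1 <- function(v) v / sqrt(sum(v^2))
  D <- norm1(rnorm(d))
  C <- t(apply(matrix(rnorm(4 * d), 4), 1, norm1))
  RP <- t(apply(matrix(rnorm(kp * d), kp), 1, norm1))
  item_instance(D, C, RP, gold_score = gold, item_id = 1L, user_id = "u1")
}

small_cohort <- function(n_users = 20, signal = 0.9, corr = 0.5, seed = 5,
                         posts = 40) {
  generate_cohort(cohort_config(
    n_users = n_users, signal_strength = signal,
    inter_item_correlation = corr, posts_family = "fixed",
    posts_fixed = posts, seed = seed
  ))
}
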