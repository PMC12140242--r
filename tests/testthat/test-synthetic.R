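test_that("cohort generation is deterministic and respects its configuration", {
  cfg <- cohort_config(n_users = 12, posts_family = "fixed", posts_fixed = 15,
                       seed = 31)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(lapply(a$corpora, `[[`, "posts"),
                   lapply(b$corpora, `[[`, "posts"))
  expect_identical(score_matrix(a$corpora), score_matrix(b$corpora))
  expect_length(a$corpora, 12L)
  expect_true(all(vapply(a$corpora, function(u) nrow(u$posts), numeric(1)) == 15))
  expect_true(all(score_matrix(a$corpora) %in% 0:3))
  # provenance covers every post
  expect_equal(nrow(a$provenance), 12L * 15L)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(score_marginals = c(0.5, 0.5, 0.2, 0.1)), "summing to 1")
  expect_error(cohort_config(signal_strength = 1.2), "signal_strength")
  expect_error(cohort_config(inter_item_correlation = 1), "inter_item_correlation")
  expect_error(cohort_config(posts_mean = 100, posts_median = 200), "mean >= median")
  expect_error(generate_cohort(cohort_config(n_users = 3),
                               synthetic_questionnaire(5)), "21-item")
})

test_that("score marginals match the configured frequencies across seeds", {
  # seed-averaged empirical frequencies within 3 percentage points of target
  target <- c(0.25, 0.35, 0.23, 0.17)
  freqs <- sapply(1:10, function(s) {
    co <- generate_cohort(cohort_config(n_users = 100, posts_family = "fixed",
                                        posts_fixed = 1, seed = s))
    tabulate(score_matrix(co$corpora) + 1L, 4L) / 2100
  })
  expect_true(all(abs(rowMeans(freqs) - target) < 0.03))
})

test_that("zero signal strength plants no choice text in any post", {
  co <- generate_cohort(cohort_config(n_users = 5, signal_strength = 0,
                                      posts_family = "fixed", posts_fixed = 20,
                                      seed = 2))
  expect_true(all(is.na(co$provenance$signal_item)))
  choice_tokens <- unique(unlist(lapply(co$questionnaire$items, function(it) {
    unlist(lapply(it$choices, function(ch) tokenize(ch$text)[[1]]))
  })))
  post_tokens <- unique(unlist(tokenize(
    unlist(lapply(co$corpora, function(u) u$posts$text)))))
  expect_length(intersect(post_tokens, choice_tokens), 0L)
})

test_that("inter-item correlation raises pairwise correlation and alpha", {
  alpha_at <- function(rho, seed) {
    co <- generate_cohort(cohort_config(n_users = 150, posts_family = "fixed",
                                        posts_fixed = 1,
                                        inter_item_correlation = rho,
                                        seed = seed))
    cronbach_alpha(score_matrix(co$corpora))
  }
  lo <- mean(vapply(1:3, function(s) alpha_at(0.1, s), numeric(1)))
  hi <- mean(vapply(1:3, function(s) alpha_at(0.7, s), numeric(1)))
  expect_gt(hi, lo)
  expect_gt(hi, 0.9)
})

test_that("high signal strength makes retrieval hit the planted posts", {
  co <- generate_cohort(cohort_config(n_users = 4, signal_strength = 0.95,
                                      posts_family = "fixed", posts_fixed = 200,
                                      seed = 8))
  be <- mock_backend(dim = 256)
  qe <- embed_questionnaire(co$questionnaire, be)
  hits <- total <- top1 <- n_checks <- 0
  for (u in co$corpora) {
    emb <- embed_texts(be, u$posts$text)
    prov <- co$provenance[co$provenance$user_id == u$user_id, ]
    for (j in c(1, 7, 21)) {
      rs <- retrieve_top_k(emb, qe$descriptions[j, ], k = 3)
      planted <- prov$post_id[!is.na(prov$signal_item) & prov$signal_item == j]
      top1 <- top1 + (rs$post_indices[1] %in% planted)
      hits <- hits + sum(rs$post_indices %in% planted)
      total <- total + length(rs$post_indices)
      n_checks <- n_checks + 1
    }
  }
  # planted posts are ~5% of the pool, so chance hit rate is ~0.05
  expect_gt(hits / total, 0.9)
  expect_equal(top1, n_checks)
})

test_that("fidelity report passes on a cohort generated at the default targets", {
  co <- generate_cohort(cohort_config(n_users = 100, seed = 17))
  rep_ <- cohort_fidelity(co)
  expect_s3_class(rep_, "data.frame")
  expect_true(all(rep_$pass[grepl("marginal|posts_mean|posts_median", rep_$statistic)]))
})

test_that("fidelity report flags deliberately skewed marginals", {
  co <- generate_cohort(cohort_config(n_users = 100,
                                      score_marginals = c(0.85, 0.05, 0.05, 0.05),
                                      posts_family = "fixed", posts_fixed = 2,
                                      seed = 3))
  rep_ <- cohort_fidelity(co)
  marg <- rep_[grepl("marginal", rep_$statistic), ]
  expect_false(all(marg$pass))
})

test_that("cohorts round-trip through the corpus file formats", {
  co <- generate_cohort(cohort_config(n_users = 4, posts_family = "fixed",
                                      posts_fixed = 6, seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  cs <- read_posts(paths["posts"])
  cs <- read_gold_scores(cs, paths["scores"])
  expect_length(cs, 4L)
  expect_identical(lapply(cs, function(u) u$posts$text),
                   lapply(co$corpora, function(u) u$posts$text))
  expect_identical(lapply(cs, `[[`, "gold_scores"),
                   lapply(co$corpora, `[[`, "gold_scores"))
})
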