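# independent oracle for any affine + softmax stage
softmax_oracle <- function(x) exp(x) / sum(exp(x))
linsoft_oracle <- function(W, b, x) softmax_oracle(as.numeric(t(W) %*% x + b))

test_that("cross-attention reproduces hand-computed closed forms", {
  # single post: alpha = 1, CA = the post
  one <- cross_attention(c(1, 0), rbind(c(0.3, 0.4)))
  expect_equal(one$alpha, 1)
  expect_equal(one$CA, c(0.3, 0.4))

  # equal logits: uniform alpha, CA = row mean
  RP <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  eq <- cross_attention(c(0, 0, 0), RP)
  expect_equal(eq$alpha, rep(1 / 3, 3))
  expect_equal(eq$CA, colMeans(RP))

  # D = (1,0), RP = I2: logits (1, 0), alpha = (e, 1)/(e + 1)
  a <- exp(1) / (exp(1) + 1)
  out <- cross_attention(c(1, 0), diag(2))
  expect_equal(out$alpha, c(a, 1 - a), tolerance = 1e-9)
  expect_equal(out$CA, c(a, 1 - a), tolerance = 1e-9)
  expect_equal(sum(out$alpha), 1, tolerance = 1e-9)

  expect_error(cross_attention(c(NaN, 1), diag(2)), "non-finite")
  expect_error(cross_attention(c(1, 0, 0), diag(2)), "dimension")
})

test_that("choice similarities are cosines in [-1, 1]", {
  C <- rbind(c(2, 0), c(0, 5), c(-1, 0), c(1, 1))
  cs <- choice_similarities(c(3, 0), C)
  expect_equal(cs, c(1, 0, -1, 1 / sqrt(2)), tolerance = 1e-9)
  expect_error(choice_similarities(c(0, 0), C), "zero-norm")
  expect_error(choice_similarities(c(1, 0), rbind(C[1:3, ], c(0, 0))), "zero-norm")
})

test_that("sub-model A is a shift-invariant softmax over the cosines", {
  expect_equal(submodel_A(rep(0.4, 4)), rep(0.25, 4))
  e <- exp(1)
  expect_equal(submodel_A(c(1, 0, 0, 0)), c(e, 1, 1, 1) / (e + 3), tolerance = 1e-9)
  expect_equal(submodel_A(c(1, 2, 3, 4)), submodel_A(c(1, 2, 3, 4) + 7), tolerance = 1e-12)
  # temperature sharpens but preserves the argmax
  expect_equal(which.max(submodel_A(c(0.1, 0.5, 0.2, 0.3), temperature = 0.1)), 2L)
  expect_gt(max(submodel_A(c(0.1, 0.5, 0.2, 0.3), temperature = 0.1)),
            max(submodel_A(c(0.1, 0.5, 0.2, 0.3))))
})

test_that("the combined representation follows the weighted-sum formula", {
  C <- diag(4)
  # one-hot selections
  expect_equal(combine(c(0, 1, 0, 0), C, alpha = 1, RP = rbind(c(1, 1, 0, 0))),
               c(1, 2, 0, 0))
  # all choices identical: choice term is that vector regardless of weights
  Cc <- rbind(c(1, 2, 0, 0), c(1, 2, 0, 0), c(1, 2, 0, 0), c(1, 2, 0, 0))
  expect_equal(combine(c(0.1, 0.2, 0.3, 0.4), Cc, alpha = c(1, 0),
                       RP = rbind(c(0, 0, 0, 0), c(5, 5, 5, 5))),
               c(1, 2, 0, 0))
  # hand-computed mixed case, k' = 1
  expect_equal(combine(c(0.5, 0.5, 0, 0), C, alpha = 1, RP = rbind(c(1, 1, 0, 0))),
               c(1.5, 1.5, 0, 0))
  # the fixed-k denominator divides the post term by k, not k'
  expect_equal(combine(c(1, 0, 0, 0), C, alpha = 1, RP = rbind(c(2, 0, 0, 0)),
                       denominator = "fixed_k", k = 20),
               c(1 + 2 / 20, 0, 0, 0))
  # cosine weighting uses raw CS
  expect_equal(combine(c(0.25, 0.25, 0.25, 0.25), C, alpha = 1,
                       RP = rbind(rep(0, 4)), CS = c(2, 0, 0, 0),
                       weights = "cosine"),
               c(2, 0, 0, 0))
})

test_that("sub-model B and the ensemble match an independent matrix-product oracle", {
  set.seed(33)
  for (rep in 1:100) {
    d <- sample(2:10, 1)
    params <- init_head(d, seed = rep)
    x <- rnorm(d)
    expect_equal(submodel_B(x, params), linsoft_oracle(params$W_B, params$b_B, x),
                 tolerance = 1e-9)
    pA <- softmax_oracle(rnorm(4)); pB <- softmax_oracle(rnorm(4))
    expect_equal(ensemble(pA, pB, params),
                 linsoft_oracle(params$W_E, params$b_E, c(pA, pB)),
                 tolerance = 1e-9)
  }
})

test_that("zero weights give uniform outputs; ensemble is A/B symmetric under symmetric weights", {
  params <- init_head(4, seed = 1)
  params$W_B[] <- 0; params$b_B[] <- 0
  params$W_E[] <- 0; params$b_E[] <- 0
  expect_equal(submodel_B(rnorm(4), params), rep(0.25, 4))
  expect_equal(ensemble(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.1, 0.1, 0.7), params),
               rep(0.25, 4))
  # symmetric weights: swapping the two sub-model inputs leaves output unchanged
  W <- matrix(rnorm(16), 4, 4)
  params$W_E <- rbind(W, W)
  pA <- softmax_oracle(rnorm(4)); pB <- softmax_oracle(rnorm(4))
  expect_equal(ensemble(pA, pB, params), ensemble(pB, pA, params), tolerance = 1e-12)
})

test_that("the forward pass composes the stages and is a pure function", {
  ins <- toy_instance(d = 8, kp = 4, gold = 2)
  params <- init_head(8, seed = 2)
  p1 <- forward_head(ins, params)
  p2 <- forward_head(ins, params)
  expect_identical(p1, p2)
  for (v in list(p1$probs_A, p1$probs_B, p1$probs_final)) {
    expect_equal(sum(v), 1, tolerance = 1e-6)
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_equal(sum(p1$alpha), 1, tolerance = 1e-6)
  expect_identical(p1$predicted_score, which.max(p1$probs_final) - 1L)

  # single post aligned with choice 1 (score 0): sub-model A peaks at score 0
  d <- 8
  post <- c(1, rep(0, d - 1))
  C <- rbind(post, diag(d)[2:4, ])
  aligned <- item_instance(D = post, C = C, RP = rbind(post))
  pa <- forward_head(aligned, params)$probs_A
  expect_identical(unname(which.max(pa)), 1L)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(77)
  instances <- lapply(1:6, function(i) toy_instance(d = 5, kp = 3,
                                                    gold = sample(0:3, 1),
                                                    seed = i))
  cfg <- train_config(seed = 1, lambda_A = 0.7, lambda_final = 1.3,
                      train_temperature = TRUE)
  params <- init_head(5, seed = 3)
  params$temperature <- 1.3
  feat <- ensembert:::featurize_instances(instances, params)
  idx <- seq_along(instances)
  fw <- ensembert:::head_forward_batch(feat, idx, params)
  gr <- ensembert:::head_backward_batch(feat, idx, fw, params, cfg)

  loss_at <- function(p) {
    f <- ensembert:::head_forward_batch(feat, idx, p)
    ensembert:::head_loss_batch(f, feat$gold[idx], cfg)
  }
  eps <- 1e-6
  for (nm in c("W_B", "b_B", "W_E", "b_E")) {
    sel <- sample(length(params[[nm]]), min(5, length(params[[nm]])))
    for (s in sel) {
      up <- params; up[[nm]][s] <- up[[nm]][s] + eps
      dn <- params; dn[[nm]][s] <- dn[[nm]][s] - eps
      expect_equal(gr[[nm]][s], (loss_at(up) - loss_at(dn)) / (2 * eps),
                   tolerance = 1e-4, info = nm)
    }
  }
  # log-temperature gradient
  up <- params; up$temperature <- exp(log(params$temperature) + eps)
  dn <- params; dn$temperature <- exp(log(params$temperature) - eps)
  expect_equal(gr$log_tau, (loss_at(up) - loss_at(dn)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("training reduces the loss and recovers a planted signal", {
  co <- small_cohort(n_users = 16, signal = 0.95, seed = 21, posts = 150)
  be <- mock_backend(dim = 128)
  ins <- build_instances(co$corpora, co$questionnaire, be, k = 8)
  params <- train_head(ins, train_config(epochs = 60, seed = 4, val_fraction = 0))
  log <- attr(params, "training_log")
  expect_gt(nrow(log), 5)
  # loss decreases overall (monitored on the full train set)
  expect_lt(log$train_loss[nrow(log)], log$train_loss[1])
  # train accuracy on a strongly aligned cohort is high
  pred <- vapply(ins, function(i) forward_head(i, params)$predicted_score, integer(1))
  gold <- vapply(ins, `[[`, integer(1), "gold_score")
  expect_gt(mean(pred == gold), 0.9)
})

test_that("training is deterministic given the seed", {
  co <- small_cohort(n_users = 8, seed = 2, posts = 30)
  be <- mock_backend(dim = 32)
  ins <- build_instances(co$corpora, co$questionnaire, be, k = 5)
  p1 <- train_head(ins, train_config(epochs = 10, seed = 9))
  p2 <- train_head(ins, train_config(epochs = 10, seed = 9))
  expect_identical(p1$W_B, p2$W_B)
  expect_identical(p1$W_E, p2$W_E)
  expect_identical(p1$temperature, p2$temperature)
})

test_that("parameters round-trip through serialization with identical predictions", {
  co <- small_cohort(n_users = 6, seed = 3, posts = 20)
  be <- mock_backend(dim = 16)
  ins <- build_instances(co$corpora, co$questionnaire, be, k = 5)
  params <- train_head(ins, train_config(epochs = 5, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  save_head_params(params, path)
  reloaded <- load_head_params(path)
  for (i in ins[1:10]) {
    expect_identical(forward_head(i, params)$probs_final,
                     forward_head(i, reloaded)$probs_final)
  }
})

test_that("per-user prediction aggregates items into overall score and category", {
  co <- small_cohort(n_users = 10, signal = 0.95, seed = 13, posts = 60)
  be <- mock_backend(dim = 64)
  ins <- build_instances(co$corpora, co$questionnaire, be, k = 10)
  params <- train_head(ins, train_config(epochs = 30, seed = 2))
  u <- co$corpora[[1]]
  out <- predict_user(u, co$questionnaire, params, be, k = 10)
  expect_length(out$item_scores, 21L)
  expect_equal(out$overall, sum(out$item_scores))
  expect_equal(as.integer(out$category),
               as.integer(categorize_overall(out$overall)))
  # attention report rows sum to 1 per item
  s <- tapply(out$attention_report$alpha, out$attention_report$item_id, sum)
  expect_equal(unname(as.numeric(s)), rep(1, 21), tolerance = 1e-6)
  # user with no usable posts errors
  short <- user_corpus("s", data.frame(text = c("hi", "no")), gold_scores = rep(0L, 21))
  expect_error(predict_user(short, co$questionnaire, params, be), "no usable posts")
})
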