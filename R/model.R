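#' One (user, item) model instance
#'
#' Bundles the frozen embeddings the head consumes for a single user-item
#' pair: the item description vector `D`, the four choice embeddings `C`
#' (rows ordered by score 0..3), the retrieved post embeddings `RP`
#' (k' x d, k' >= 1) and, when available, the gold item score.
#'
#' @param D length-d description embedding.
#' @param C 4 x d choice embedding matrix, row l is the choice scored l-1.
#' @param RP k' x d retrieved-post embedding matrix.
#' @param gold_score optional integer in 0-3.
#' @param item_id,user_id optional identifiers carried through to reports.
#' @return an `item_instance`.
#' @export
item_instance <- function(D, C, RP, gold_score = NULL, item_id = NA_integer_,
                          user_id = NA_character_) {
  if (!is.matrix(RP)) RP <- rbind(RP)
  stopifnot(is.matrix(C), nrow(C) == 4L, ncol(C) == length(D),
            ncol(RP) == length(D), nrow(RP) >= 1L)
  if (!is.null(gold_score)) stopifnot(gold_score %in% 0:3)
  structure(
    list(D = as.numeric(D), C = C, RP = RP,
         gold_score = if (is.null(gold_score)) NULL else as.integer(gold_score),
         item_id = as.integer(item_id), user_id = as.character(user_id)),
    class = "item_instance"
  )
}

#' Cross-attention of an item description over retrieved posts
#'
#' Attention logits are the raw dot products `D . RP_i` (no scaling);
#' `alpha = softmax(logits)` and the attended representation is
#' `CA = sum_i alpha_i RP_i`. With a single post this degenerates to
#' `alpha = 1`, `CA = RP_1`; with equal logits `CA` is the row mean.
#'
#' @param D length-d description embedding.
#' @param RP k' x d retrieved-post embedding matrix.
#' @param temperature optional positive divisor of the logits (default 1,
#'   the plain unscaled form).
#' @return list with `CA` (length-d) and `alpha` (length k', sums to 1).
#' @export
cross_attention <- function(D, RP, temperature = 1) {
  if (!is.matrix(RP)) RP <- rbind(RP)
  if (ncol(RP) != length(D)) stop("dimension mismatch between D and RP")
  if (!all(is.finite(D)) || !all(is.finite(RP))) stop("non-finite embeddings")
  stopifnot(temperature > 0)
  alpha <- softmax(drop(RP %*% D) / temperature)
  list(CA = drop(alpha %*% RP), alpha = alpha)
}

#' Cosine similarity of the attended representation to each choice
#'
#' `CS_l = cos(CA, C_l) = (CA . C_l) / (||CA|| ||C_l||)`, each in [-1, 1].
#'
#' @param CA length-d attended representation.
#' @param C 4 x d choice embedding matrix.
#' @return numeric vector of 4 cosines.
#' @export
choice_similarities <- function(CA, C) {
  stopifnot(is.matrix(C), ncol(C) == length(CA))
  nca <- sqrt(sum(CA^2))
  nc <- sqrt(rowSums(C^2))
  if (nca == 0 || any(nc == 0)) stop("cosine undefined for zero-norm vector")
  drop(C %*% CA) / (nca * nc)
}

#' Sub-model A: softmax over the four choice similarities
#'
#' `S = softmax([CS_1, ..., CS_4])`, optionally tempered
#' (`softmax(CS / tau)`); the temperature is the model's only trainable
#' scalar on this path since all embeddings are frozen.
#'
#' @param CS numeric vector of 4 choice similarities.
#' @param temperature positive scalar (default 1).
#' @return probability vector over scores 0-3.
#' @export
submodel_A <- function(CS, temperature = 1) {
  stopifnot(length(CS) == 4L, temperature > 0)
  softmax(CS / temperature)
}

#' Combined representation of choices and attended posts
#'
#' `combined = sum_l w_l C_l + (1/k') sum_i alpha_i RP_i`, where the choice
#' weights `w` are the softmax-normalized similarity scores `S` (probs_A).
#' Two documented alternatives: `weights = "cosine"` uses the raw cosines
#' `CS_l` as weights, and `denominator = "fixed_k"` divides the post term by
#' the configured `k` instead of the retrieved count `k'`.
#'
#' @param probs_A sub-model A probabilities (the weights under the default).
#' @param C 4 x d choice embedding matrix.
#' @param alpha attention weights (length k').
#' @param RP k' x d retrieved-post matrix.
#' @param CS raw cosines, required when `weights = "cosine"`.
#' @param weights `"softmax"` (default) or `"cosine"`.
#' @param denominator `"retrieved"` (default, k') or `"fixed_k"`.
#' @param k the configured retrieval size, used only for `"fixed_k"`.
#' @return length-d combined representation.
#' @export
combine <- function(probs_A, C, alpha, RP, CS = NULL,
                    weights = c("softmax", "cosine"),
                    denominator = c("retrieved", "fixed_k"), k = 20L) {
  weights <- match.arg(weights)
  denominator <- match.arg(denominator)
  if (!is.matrix(RP)) RP <- rbind(RP)
  stopifnot(is.matrix(C), nrow(C) == 4L, length(alpha) == nrow(RP),
            ncol(C) == ncol(RP))
  w <- if (weights == "softmax") probs_A else {
    if (is.null(CS)) stop("CS required for cosine weighting")
    CS
  }
  denom <- if (denominator == "retrieved") nrow(RP) else k
  drop(w %*% C) + drop(alpha %*% RP) / denom
}

#' Sub-model B: linear + softmax over the combined representation
#'
#' @param combined length-d vector.
#' @param params head parameters (uses `W_B` (d x 4) and `b_B`).
#' @return probability vector over scores 0-3.
#' @export
submodel_B <- function(combined, params) {
  softmax(drop(combined %*% params$W_B) + params$b_B)
}

#' Ensemble layer over the two sub-model outputs
#'
#' A single affine map plus softmax over the concatenation
#' `[probs_A, probs_B]`.
#'
#' @param probs_A,probs_B probability vectors over scores 0-3.
#' @param params head parameters (uses `W_E` (8 x 4) and `b_E`).
#' @return final probability vector over scores 0-3.
#' @export
ensemble <- function(probs_A, probs_B, params) {
  softmax(drop(c(probs_A, probs_B) %*% params$W_E) + params$b_E)
}

#' Full forward pass of the head for one instance
#'
#' Composes cross-attention, choice cosine scoring, sub-model A, the
#' combined representation, sub-model B and the ensemble layer, exposing
#' the attention weights and choice similarities for interpretability.
#' The predicted score is `argmax(probs_final)` with ties broken toward the
#' lowest score.
#'
#' @param instance an [item_instance()].
#' @param params head parameters from [init_head()] or [train_head()].
#' @return a `prediction`: list with `probs_A`, `probs_B`, `probs_final`,
#'   `predicted_score`, `alpha`, `CS`.
#' @export
forward_head <- function(instance, params) {
  stopifnot(inherits(instance, "item_instance"))
  att <- cross_attention(instance$D, instance$RP)
  CS <- choice_similarities(att$CA, instance$C)
  pA <- submodel_A(CS, temperature = params$temperature)
  comb <- combine(pA, instance$C, att$alpha, instance$RP, CS = CS,
                  weights = params$combine_weights,
                  denominator = params$combine_denominator, k = params$k)
  pB <- submodel_B(comb, params)
  pF <- ensemble(pA, pB, params)
  structure(
    list(probs_A = pA, probs_B = pB, probs_final = pF,
         predicted_score = which.max(pF) - 1L,  # which.max takes first max
         alpha = att$alpha, CS = CS,
         item_id = instance$item_id, user_id = instance$user_id),
    class = "prediction"
  )
}

#' Initialize head parameters
#'
#' Small random-normal weights (symmetry breaking for sub-model B), zero
#' biases, temperature 1.
#'
#' @param d embedding dimension.
#' @param seed RNG seed.
#' @param init_sd standard deviation of the weight initialization.
#' @param k configured retrieval size (echoed for the combine step).
#' @param combine_weights,combine_denominator combine-step variants, see
#'   [combine()].
#' @param backend_id optional backend identifier echo.
#' @return a `head_params` list.
#' @export
init_head <- function(d, seed = 1L, init_sd = 0.01, k = 20L,
                      combine_weights = "softmax",
                      combine_denominator = "retrieved",
                      backend_id = NA_character_) {
  with_seed(seed, {
    structure(
      list(
        W_B = matrix(stats::rnorm(d * 4L, sd = init_sd), d, 4L),
        b_B = numeric(4L),
        W_E = matrix(stats::rnorm(8L * 4L, sd = init_sd), 8L, 4L),
        b_E = numeric(4L),
        temperature = 1,
        d = as.integer(d), k = as.integer(k),
        combine_weights = combine_weights,
        combine_denominator = combine_denominator,
        backend_id = backend_id
      ),
      class = "head_params"
    )
  })
}

#' Training configuration for the head
#'
#' All stochastic choices (initialization, mini-batch shuffling, validation
#' split) are fixed by `seed`. The loss is
#' `lambda_A * CE(probs_A, gold) + lambda_final * CE(probs_final, gold)`;
#' since the embeddings are frozen, the `lambda_A` term only trains the
#' sub-model A temperature (when `train_temperature = TRUE`).
#'
#' @param epochs,batch_size,lr,momentum mini-batch SGD hyperparameters.
#' @param seed integer seed for all stochastic choices.
#' @param lambda_A,lambda_final loss weights.
#' @param patience early-stopping patience (epochs without validation
#'   improvement); `val_fraction` of training users are held out to monitor.
#' @param val_fraction fraction of instances held out for early stopping.
#' @param train_temperature train the sub-model A temperature scalar.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 150L, batch_size = 64L, lr = 0.5,
                         momentum = 0.9, seed = 1L, lambda_A = 1,
                         lambda_final = 1, patience = 15L,
                         val_fraction = 0.1, train_temperature = TRUE) {
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0, momentum >= 0,
            momentum < 1, lambda_A >= 0, lambda_final >= 0, patience >= 1L,
            val_fraction >= 0, val_fraction < 1)
  structure(as.list(environment()), class = "train_config")
}

# Precompute the frozen per-instance features the trainable parameters act
# on: choice cosines S, the fixed post term r of the combined
# representation, and the four choice-embedding rows.
featurize_instances <- function(instances, params) {
  n <- length(instances)
  d <- params$d
  S <- matrix(0, n, 4L)
  R <- matrix(0, n, d)
  CL <- lapply(1:4, function(l) matrix(0, n, d))
  gold <- integer(n)
  for (i in seq_len(n)) {
    ins <- instances[[i]]
    if (is.null(ins$gold_score)) stop("instance ", i, " has no gold score")
    att <- cross_attention(ins$D, ins$RP)
    S[i, ] <- choice_similarities(att$CA, ins$C)
    denom <- if (params$combine_denominator == "retrieved") nrow(ins$RP) else params$k
    R[i, ] <- drop(att$alpha %*% ins$RP) / denom
    for (l in 1:4) CL[[l]][i, ] <- ins$C[l, ]
    gold[i] <- ins$gold_score
  }
  list(S = S, R = R, CL = CL, gold = gold)
}

# Vectorized forward pass over featurized instances. Returns everything the
# backward pass needs.
head_forward_batch <- function(feat, idx, params) {
  S <- feat$S[idx, , drop = FALSE]
  PA <- softmax_rows(S / params$temperature)
  if (params$combine_weights == "cosine") {
    W <- S
  } else {
    W <- PA
  }
  combined <- feat$R[idx, , drop = FALSE]
  for (l in 1:4) combined <- combined + W[, l] * feat$CL[[l]][idx, , drop = FALSE]
  ZB <- sweep(combined %*% params$W_B, 2L, params$b_B, "+")
  PB <- softmax_rows(ZB)
  ZF <- sweep(cbind(PA, PB) %*% params$W_E, 2L, params$b_E, "+")
  PF <- softmax_rows(ZF)
  list(S = S, PA = PA, PB = PB, PF = PF, combined = combined)
}

head_loss_batch <- function(fw, gold, config) {
  n <- nrow(fw$PA)
  g <- cbind(seq_len(n), gold + 1L)
  mean(config$lambda_A * (-log(pmax(fw$PA[g], 1e-12))) +
         config$lambda_final * (-log(pmax(fw$PF[g], 1e-12))))
}

# Analytic gradients of the mean batch loss w.r.t. W_B, b_B, W_E, b_E and
# (optionally) the log-temperature of sub-model A.
head_backward_batch <- function(feat, idx, fw, params, config) {
  n <- length(idx)
  gold <- feat$gold[idx]
  G <- matrix(0, n, 4L); G[cbind(seq_len(n), gold + 1L)] <- 1

  dZF <- config$lambda_final * (fw$PF - G) / n
  dW_E <- crossprod(cbind(fw$PA, fw$PB), dZF)
  db_E <- colSums(dZF)

  dPB <- dZF %*% t(params$W_E[5:8, , drop = FALSE])
  dZB <- fw$PB * (dPB - rowSums(fw$PB * dPB))
  dW_B <- crossprod(fw$combined, dZB)
  db_B <- colSums(dZB)

  grads <- list(W_B = dW_B, b_B = db_B, W_E = dW_E, b_E = db_E, log_tau = 0)

  if (isTRUE(config$train_temperature) && params$combine_weights == "softmax") {
    dcombined <- dZB %*% t(params$W_B)
    # three routes into sub-model A's logits a = S / tau
    da <- config$lambda_A * (fw$PA - G) / n                         # CE_A
    dPA_ens <- dZF %*% t(params$W_E[1:4, , drop = FALSE])           # ensemble input
    da <- da + fw$PA * (dPA_ens - rowSums(fw$PA * dPA_ens))
    dPA_comb <- matrix(0, n, 4L)                                    # combine weights
    for (l in 1:4) dPA_comb[, l] <- rowSums(dcombined * feat$CL[[l]][idx, , drop = FALSE])
    da <- da + fw$PA * (dPA_comb - rowSums(fw$PA * dPA_comb))
    # a = S * exp(-u) with u = log tau; da/du = -a
    grads$log_tau <- -sum(da * fw$S) / params$temperature
  }
  grads
}

#' Train the head by mini-batch gradient descent
#'
#' Jointly minimizes the weighted categorical cross-entropies of sub-model A
#' and the ensemble output over the trainable parameters (sub-model B's
#' affine map, the ensemble affine map and, optionally, sub-model A's
#' temperature). Embeddings are frozen throughout. A `val_fraction` slice of
#' instances is held out for early stopping; the parameters returned are the
#' ones with the best validation loss. Deterministic given `config$seed`.
#'
#' @param instances list of [item_instance()] objects, all with gold scores.
#' @param config a [train_config()].
#' @param params optional pre-initialized head (default [init_head()] with
#'   the instance dimension and `config$seed`).
#' @param k configured retrieval size echo (when `params` not supplied).
#' @param quiet suppress per-epoch messages.
#' @return trained `head_params`, with a `training_log` attribute (data
#'   frame of epoch, train loss, validation loss).
#' @export
train_head <- function(instances, config = train_config(), params = NULL,
                       k = 20L, quiet = TRUE) {
  stopifnot(length(instances) >= 2L)
  d <- length(instances[[1]]$D)
  if (is.null(params)) params <- init_head(d, seed = config$seed, k = k)
  feat <- featurize_instances(instances, params)
  n <- length(instances)

  with_seed(config$seed + 1L, {
    n_val <- floor(n * config$val_fraction)
    val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
    train_idx <- setdiff(seq_len(n), val_idx)

    vel <- list(W_B = params$W_B * 0, b_B = params$b_B * 0,
                W_E = params$W_E * 0, b_E = params$b_E * 0, log_tau = 0)
    log_tau <- log(params$temperature)
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    log_rows <- vector("list", config$epochs)

    for (epoch in seq_len(config$epochs)) {
      perm <- sample(train_idx)
      for (start in seq(1L, length(perm), by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1L, length(perm))]
        fw <- head_forward_batch(feat, idx, params)
        gr <- head_backward_batch(feat, idx, fw, params, config)
        if (!all(vapply(gr, function(g) all(is.finite(g)), logical(1)))) {
          stop("non-finite gradient at epoch ", epoch, "; try a lower learning rate")
        }
        for (nm in c("W_B", "b_B", "W_E", "b_E")) {
          vel[[nm]] <- config$momentum * vel[[nm]] - config$lr * gr[[nm]]
          params[[nm]] <- params[[nm]] + vel[[nm]]
        }
        if (isTRUE(config$train_temperature)) {
          vel$log_tau <- config$momentum * vel$log_tau - config$lr * gr$log_tau
          log_tau <- log_tau + vel$log_tau
          params$temperature <- exp(max(min(log_tau, 5), -5))
        }
      }
      fw_tr <- head_forward_batch(feat, train_idx, params)
      loss_tr <- head_loss_batch(fw_tr, feat$gold[train_idx], config)
      loss_val <- if (length(val_idx)) {
        fw_v <- head_forward_batch(feat, val_idx, params)
        head_loss_batch(fw_v, feat$gold[val_idx], config)
      } else loss_tr
      if (!is.finite(loss_tr)) stop("non-finite training loss at epoch ", epoch)
      log_rows[[epoch]] <- data.frame(epoch = epoch, train_loss = loss_tr,
                                      val_loss = loss_val)
      if (!quiet) message(sprintf("epoch %3d  train %.4f  val %.4f",
                                  epoch, loss_tr, loss_val))
      if (loss_val < best$loss - 1e-6) {
        best <- list(loss = loss_val, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  out <- best$params
  attr(out, "training_log") <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))])
  attr(out, "best_epoch") <- best$epoch
  out
}

#' Predict all 21 item scores, the overall score and the severity category
#' for one user
#'
#' Runs the retrieve-then-predict pipeline for every questionnaire item:
#' filter short posts, embed, retrieve the top-k posts per item, run the
#' head, take `argmax(probs_final)` per item (ties toward the lower score),
#' sum to the overall score and band it into a severity category. The
#' attention report lists, per item, each retrieved post with its retrieval
#' similarity and attention weight.
#'
#' @param corpus a `user_corpus`.
#' @param questionnaire a `questionnaire`.
#' @param params trained `head_params`.
#' @param backend the embedding backend (must match training).
#' @param k retrieval size (default the one echoed in `params`).
#' @param min_words post length filter threshold.
#' @return list with `item_scores` (21 integers), `probs` (21 x 4 matrix),
#'   `overall`, `category` (code, with label attribute), and
#'   `attention_report` (data frame).
#' @export
predict_user <- function(corpus, questionnaire, params, backend,
                         k = params$k, min_words = 3L) {
  stopifnot(inherits(corpus, "user_corpus"), inherits(questionnaire, "questionnaire"))
  corpus <- filter_short_posts(corpus, min_words)
  if (nrow(corpus$posts) == 0L) {
    stop("user ", corpus$user_id, ": no usable posts after filtering")
  }
  qe <- embed_questionnaire(questionnaire, backend)
  post_emb <- embed_texts(backend, corpus$posts$text)
  n_items <- length(questionnaire$items)
  scores <- integer(n_items)
  probs <- matrix(0, n_items, 4L, dimnames = list(NULL, paste0("p", 0:3)))
  att_rows <- vector("list", n_items)
  for (j in seq_len(n_items)) {
    rs <- retrieve_top_k(post_emb, qe$descriptions[j, ], k = k,
                         post_ids = corpus$posts$post_id)
    ins <- item_instance(qe$descriptions[j, ], qe$choices[[j]], rs$embeddings,
                         item_id = j, user_id = corpus$user_id)
    pred <- forward_head(ins, params)
    scores[j] <- pred$predicted_score
    probs[j, ] <- pred$probs_final
    att_rows[[j]] <- data.frame(
      user_id = corpus$user_id, item_id = j,
      rank = seq_along(rs$post_ids), post_id = rs$post_ids,
      similarity = rs$similarities, alpha = pred$alpha,
      stringsAsFactors = FALSE
    )
  }
  overall <- overall_from_items(scores, n_items = n_items)
  list(
    user_id = corpus$user_id,
    item_scores = scores,
    probs = probs,
    overall = overall,
    category = categorize_overall(overall),
    attention_report = do.call(rbind, att_rows)
  )
}

#' Embed a questionnaire's descriptions and choices
#'
#' @param questionnaire a `questionnaire`.
#' @param backend an `embedding_backend`.
#' @return list with `descriptions` (n_items x d matrix) and `choices`
#'   (list of 4 x d matrices, rows in score order).
#' @export
embed_questionnaire <- function(questionnaire, backend) {
  desc <- embed_texts(backend, vapply(questionnaire$items, `[[`, "",
                                      "description"))
  choices <- lapply(questionnaire$items, function(it) {
    embed_texts(backend, vapply(it$choices, `[[`, "", "text"))
  })
  list(descriptions = desc, choices = choices)
}

#' Save head parameters to a JSON file
#'
#' Full-precision serialization: reloading yields bitwise-identical
#' predictions.
#' @param params a `head_params`.
#' @param path output path.
#' @export
save_head_params <- function(params, path) {
  obj <- unclass(params)
  # hex-float encoding round-trips doubles exactly
  for (nm in c("W_B", "b_B", "W_E", "b_E", "temperature")) {
    obj[[nm]] <- sprintf("%a", as.vector(obj[[nm]]))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load head parameters saved by [save_head_params()]
#' @param path JSON path.
#' @return a `head_params`.
#' @export
load_head_params <- function(path) {
  obj <- jsonlite::fromJSON(path)
  for (nm in c("W_B", "b_B", "W_E", "b_E", "temperature")) {
    obj[[nm]] <- as.numeric(obj[[nm]])
  }
  obj$W_B <- matrix(obj$W_B, obj$d, 4L)
  obj$W_E <- matrix(obj$W_E, 8L, 4L)
  obj$d <- as.integer(obj$d); obj$k <- as.integer(obj$k)
  structure(obj, class = "head_params")
}
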