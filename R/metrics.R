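#' Item-level error metrics
#'
#' Mean absolute and mean squared error over aligned (user, item) score
#' pairs.
#'
#' @param true,pred integer vectors of item scores (0-3), aligned. When
#'   named, names must match; misaligned names are an error.
#' @return list with `mae_item` and `mse_item`.
#' @export
item_level <- function(true, pred) {
  check_aligned(true, pred)
  list(mae_item = mean(abs(true - pred)), mse_item = mean((true - pred)^2))
}

#' Overall-score error metrics
#'
#' Per-user mean absolute error and root mean squared error of the overall
#' (summed) score.
#'
#' @param true,pred numeric vectors of per-user overall scores, aligned.
#' @return list with `mae_overall` and `rmse_overall`.
#' @export
overall_level <- function(true, pred) {
  check_aligned(true, pred)
  list(mae_overall = mean(abs(true - pred)),
       rmse_overall = sqrt(mean((true - pred)^2)))
}

check_aligned <- function(true, pred) {
  if (length(true) != length(pred)) stop("true and pred have different lengths")
  if (!is.null(names(true)) && !is.null(names(pred)) &&
      !identical(names(true), names(pred))) {
    stop("true and pred keys are misaligned")
  }
  if (!length(true)) stop("empty input")
  invisible(TRUE)
}

#' Category-level classification metrics
#'
#' Accuracy, support-weighted F1 across the four severity categories,
#' the category-level mean squared error `mean((c - c_hat)^2)` on the
#' 0-3 category codes, the 4 x 4 confusion matrix (rows = true), and
#' per-class precision/recall/F1. Per-class F1 is defined as 0 when
#' precision + recall is 0. `f1_average = "macro"` gives the unweighted
#' mean instead of support weighting.
#'
#' @param true,pred integer vectors of category codes (0-3), aligned.
#' @param f1_average `"weighted"` (default) or `"macro"`.
#' @return list with `acc_category`, `f1_category`, `mse_category`,
#'   `confusion`, `per_class` (data frame).
#' @export
category_level <- function(true, pred, f1_average = c("weighted", "macro")) {
  f1_average <- match.arg(f1_average)
  check_aligned(true, pred)
  stopifnot(all(true %in% 0:3), all(pred %in% 0:3))
  lv <- factor(0:3, levels = 0:3)
  confusion <- table(true = factor(true, levels = 0:3),
                     pred = factor(pred, levels = 0:3))
  tp <- diag(confusion)
  support <- rowSums(confusion)
  predicted <- colSums(confusion)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  f1_agg <- if (f1_average == "weighted") {
    sum(f1 * support) / sum(support)
  } else {
    mean(f1[support > 0])
  }
  list(
    acc_category = mean(true == pred),
    f1_category = f1_agg,
    mse_category = mean((true - pred)^2),
    confusion = unclass(confusion),
    per_class = data.frame(
      category = severity_labels(), support = as.integer(support),
      precision = as.numeric(precision), recall = as.numeric(recall),
      f1 = as.numeric(f1)
    )
  )
}

#' Majority-class constant baseline
#'
#' Predicts the modal category of the reference labels for everyone; its
#' accuracy on labels with the same distribution equals the modal relative
#' frequency. Ties in the mode are broken toward the lower (less severe)
#' category.
#'
#' @param train_cats category codes used to pick the mode.
#' @param test_cats optional codes to score against (default `train_cats`).
#' @return list with `category` (the constant prediction) and `accuracy`.
#' @export
majority_baseline <- function(train_cats, test_cats = train_cats) {
  stopifnot(length(train_cats) >= 1L)
  counts <- table(factor(train_cats, levels = 0:3))
  mode_cat <- as.integer(names(counts)[which.max(counts)])  # first max = lowest code
  list(category = mode_cat, accuracy = mean(test_cats == mode_cat))
}

#' Full evaluation report across the three granularities
#'
#' @param gold named list (by user) of length-21 gold score vectors.
#' @param pred named list (by user) of length-21 predicted score vectors,
#'   same users.
#' @param f1_average passed to [category_level()].
#' @return an `evaluation_report` list with item-, overall- and
#'   category-level metrics, the confusion matrix, and counts.
#' @export
evaluate_predictions <- function(gold, pred, f1_average = "weighted") {
  users <- names(gold)
  if (!setequal(users, names(pred))) stop("gold and pred cover different users")
  pred <- pred[users]
  t_items <- unlist(gold, use.names = FALSE)
  p_items <- unlist(pred, use.names = FALSE)
  t_overall <- vapply(gold, sum, numeric(1))
  p_overall <- vapply(pred, sum, numeric(1))
  t_cat <- categorize_overall(t_overall)
  p_cat <- categorize_overall(p_overall)
  cl <- category_level(t_cat, p_cat, f1_average)
  structure(
    c(item_level(t_items, p_items),
      overall_level(t_overall, p_overall),
      cl,
      list(n_users = length(users), n_item_pairs = length(t_items))),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat("<evaluation_report> ", x$n_users, " users, ", x$n_item_pairs,
      " (user, item) pairs\n", sep = "")
  cat(sprintf("  MAE_item %.*f  MSE_item %.*f\n", digits, x$mae_item,
              digits, x$mse_item))
  cat(sprintf("  MAE_overall %.*f  RMSE_overall %.*f\n", digits,
              x$mae_overall, digits, x$rmse_overall))
  cat(sprintf("  ACC_category %.*f  F1_category %.*f  MSE_category %.*f\n",
              digits, x$acc_category, digits, x$f1_category, digits,
              x$mse_category))
  invisible(x)
}
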