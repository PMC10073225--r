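#' Per-class precision and recall from a confusion matrix
#'
#' Precision is TP / (TP + FP); recall is TP / (TP + FN). Both are computed
#' for each class in turn, with the other class as the negative. A 0/0 ratio
#' is reported as `NA` with `undefined = TRUE`, never silently as zero.
#'
#' @param confusion Named numeric vector or list with `tp`, `fp`, `fn`, `tn`
#'   counted with class 1 (obese) as positive.
#' @return Tibble with one row per class: `class`, `precision`, `recall`,
#'   `precision_undefined`, `recall_undefined`.
#' @export
precision_recall <- function(confusion) {
  cf <- as.list(confusion)
  need <- c("tp", "fp", "fn", "tn")
  if (!all(need %in% names(cf))) abort("confusion must contain tp, fp, fn, tn.")
  if (any(unlist(cf[need]) < 0)) abort("Confusion counts must be >= 0.")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  # class 0 treats overweight as positive: its TP are the class-1 TN etc.
  by_class <- list(
    `1` = list(tp = cf$tp, fp = cf$fp, fn = cf$fn),
    `0` = list(tp = cf$tn, fp = cf$fn, fn = cf$fp)
  )
  bind_rows(lapply(names(by_class), function(cl) {
    b <- by_class[[cl]]
    tibble(
      class = as.integer(cl),
      precision = ratio(b$tp, b$tp + b$fp),
      recall = ratio(b$tp, b$tp + b$fn),
      precision_undefined = (b$tp + b$fp) == 0,
      recall_undefined = (b$tp + b$fn) == 0
    )
  })) %>% arrange(.data$class)
}

confusion_counts <- function(truth, predicted) {
  c(tp = sum(truth == 1 & predicted == 1),
    fp = sum(truth == 0 & predicted == 1),
    fn = sum(truth == 1 & predicted == 0),
    tn = sum(truth == 0 & predicted == 0))
}

#' Leave-one-out evaluation of a final classifier
#'
#' For each subject the model is refit on the remaining n-1 subjects —
#' including the feature standardization, so no statistic of the held-out
#' subject influences its own prediction — and the held-out subject is
#' predicted. The n held-out predictions are aggregated into a confusion
#' matrix, accuracy, per-class precision/recall, and an ROC curve over the
#' held-out decision scores.
#'
#' By default the feature subset in `selected` is taken as given, mirroring
#' the protocol in which selection is performed once on all subjects and the
#' final model is then assessed by LOO; the report carries an annotation
#' saying so, because the selection step has seen every subject. With
#' `nested = TRUE` the selection itself is redone inside every training
#' fold via `selector`, giving an honest generalization estimate.
#'
#' @param data A feature table (see [feature_names()]).
#' @param selected Selected feature names (ignored when `nested = TRUE`).
#' @param block `"brain"`, `"metabolite"`, or `"combined"` (controls the
#'   covariates; see [assemble_design()]).
#' @param family `"svm"`, `"ridge"`, or `"logistic"`.
#' @param cost,lambda Passed to [train_linear()].
#' @param nested Redo feature selection inside each LOO training set.
#' @param selector When `nested = TRUE`: a function
#'   `function(train_data) -> character` returning the selected feature
#'   names for one training fold.
#' @return An `evaluation_report`: confusion, accuracy, per-class
#'   precision/recall, ROC points and AUC, per-subject predictions, and the
#'   selection-protocol annotation.
#' @export
loo_evaluate <- function(data, selected, block = c("brain", "metabolite", "combined"),
                         family = c("svm", "ridge", "logistic"),
                         cost = 1, lambda = 1,
                         nested = FALSE, selector = NULL) {
  block <- match.arg(block)
  family <- match.arg(family)
  n <- nrow(data)
  if (n < 3) abort("Leave-one-out evaluation needs at least 3 subjects.")
  if (nested && !is.function(selector)) {
    abort("nested = TRUE requires a selector function.")
  }
  y <- check_labels(data$label)

  score <- numeric(n)
  pred <- integer(n)
  for (i in seq_len(n)) {
    train <- data[-i, , drop = FALSE]
    sel_i <- if (nested) selector(train) else selected
    des <- assemble_design(train, sel_i, block)
    fit <- train_linear(des$x, des$y, family = family, cost = cost, lambda = lambda)
    x_new <- cbind(feature_matrix(data[i, , drop = FALSE], sel_i),
                   as.matrix(data[i, des$covariate_cols, drop = FALSE]))
    score[i] <- predict(fit, x_new, type = "score")
    pred[i] <- as.integer(predict(fit, x_new, type = "class"))
  }

  evaluation_report(
    truth = y, predicted = pred, scores = score,
    family = family, block = block,
    protocol = if (nested) "nested (selection refit inside every LOO split)"
               else "feature subset selected on all subjects; LOO refits the final model only (selection not nested)"
  )
}

#' Build an evaluation report from held-out predictions
#'
#' @param truth Binary labels.
#' @param predicted Predicted classes (0/1).
#' @param scores Decision scores (for the ROC).
#' @param family,block,protocol Annotations carried in the report.
#' @return An `evaluation_report`.
#' @export
evaluation_report <- function(truth, predicted, scores,
                              family = NA_character_, block = NA_character_,
                              protocol = NA_character_) {
  truth <- check_labels(truth)
  cf <- confusion_counts(truth, predicted)
  roc <- roc_points(scores, truth)
  structure(
    list(
      confusion = cf,
      accuracy = unname((cf["tp"] + cf["tn"]) / sum(cf)),
      precision_recall = precision_recall(cf),
      roc = roc,
      auc = roc$auc,
      predictions = tibble(truth = truth, predicted = as.integer(predicted),
                           score = scores),
      n = length(truth),
      family = family, block = block, protocol = protocol
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s model, %s block, n = %d\n",
              x$family, x$block, x$n))
  cat(sprintf("  accuracy %.4f | AUC %.4f\n", x$accuracy, x$auc))
  cat(sprintf("  confusion: TP %d FP %d FN %d TN %d\n",
              x$confusion["tp"], x$confusion["fp"], x$confusion["fn"],
              x$confusion["tn"]))
  pr <- x$precision_recall
  for (i in seq_len(nrow(pr))) {
    cat(sprintf("  class %d: precision %.3f, recall %.3f\n",
                pr$class[i], pr$precision[i], pr$recall[i]))
  }
  cat("  protocol:", x$protocol, "\n")
  invisible(x)
}

#' @export
tidy.evaluation_report <- function(x, ...) {
  x$precision_recall %>%
    mutate(accuracy = x$accuracy, auc = x$auc)
}

#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(family = x$family, block = x$block, n = x$n,
         accuracy = x$accuracy, auc = x$auc,
         tp = unname(x$confusion["tp"]), fp = unname(x$confusion["fp"]),
         fn = unname(x$confusion["fn"]), tn = unname(x$confusion["tn"]))
}

#' @export
#' @rdname plot_braingut
autoplot.evaluation_report <- function(object, ...) {
  autoplot(object$roc) +
    ggplot2::labs(title = sprintf("%s / %s: accuracy %.3f, AUC %.3f",
                                  object$family, object$block,
                                  object$accuracy, object$auc))
}

# stratified k-fold CV accuracy of a final model on a fixed feature subset;
# used by the permutation test. Fold draw controlled by the caller's RNG.
cv_accuracy <- function(data, selected, block, family, n_folds = 10,
                        cost = 1, lambda = 1) {
  y <- check_labels(data$label)
  folds <- make_folds(y, n_folds)
  correct <- 0L
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    des <- assemble_design(data[tr, , drop = FALSE], selected, block)
    fit <- train_linear(des$x, des$y, family = family, cost = cost, lambda = lambda)
    test <- data[!tr, , drop = FALSE]
    x_new <- cbind(feature_matrix(test, selected),
                   as.matrix(test[des$covariate_cols]))
    correct <- correct + sum(predict(fit, x_new, type = "class") == y[!tr])
  }
  correct / length(y)
}
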