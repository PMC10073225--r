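#' Label-permutation validation of a final model
#'
#' Shuffles the group labels uniformly at random, retrains the final model on
#' the selected features and re-evaluates it by stratified ten-fold
#' cross-validation, and repeats `R` times. The observed accuracy is the same
#' ten-fold CV on the unshuffled labels. The empirical p-value is
#' `(1 + #\{permuted >= observed\}) / (R + 1)`. A model that has learned a
#' real feature-label relationship scores far above its permuted accuracies,
#' which concentrate around the majority-class rate.
#'
#' @param data A feature table (see [feature_names()]).
#' @param selected Selected feature names for the model under test.
#' @param block `"brain"`, `"metabolite"`, or `"combined"`.
#' @param family `"svm"`, `"ridge"`, or `"logistic"`.
#' @param R Number of permutation replicates (>= 1).
#' @param seed Integer seed; fixed seed reproduces the permuted accuracies
#'   exactly. Fold assignment is re-drawn (stratified on the shuffled labels)
#'   for every replicate.
#' @param n_folds CV folds for each evaluation.
#' @param cost,lambda Passed to [train_linear()].
#' @return A `permutation_result`: `observed_accuracy`,
#'   `permuted_accuracies` (length R), `empirical_p`, `seed`.
#' @export
permutation_test <- function(data, selected, block = c("brain", "metabolite", "combined"),
                             family = c("svm", "ridge", "logistic"),
                             R = 199, seed = 1L, n_folds = 10,
                             cost = 1, lambda = 1) {
  block <- match.arg(block)
  family <- match.arg(family)
  if (R < 1) abort("R must be >= 1.")
  y <- check_labels(data$label)

  withr::with_seed(as.integer(seed), {
    observed <- cv_accuracy(data, selected, block, family, n_folds, cost, lambda)
    permuted <- vapply(seq_len(R), function(r) {
      shuffled <- data
      shuffled$label <- sample(y)
      cv_accuracy(shuffled, selected, block, family, n_folds, cost, lambda)
    }, numeric(1))
  })

  structure(
    list(
      observed_accuracy = observed,
      permuted_accuracies = permuted,
      empirical_p = (1 + sum(permuted >= observed)) / (R + 1),
      R = as.integer(R), seed = as.integer(seed),
      family = family, block = block
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s / %s: observed %.4f, mean permuted %.4f, p = %.4g (R = %d)\n",
              x$family, x$block, x$observed_accuracy,
              mean(x$permuted_accuracies), x$empirical_p, x$R))
  invisible(x)
}

#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(replicate = seq_len(x$R), permuted_accuracy = x$permuted_accuracies)
}

#' @export
glance.permutation_result <- function(x, ...) {
  tibble(family = x$family, block = x$block,
         observed_accuracy = x$observed_accuracy,
         mean_permuted_accuracy = mean(x$permuted_accuracies),
         empirical_p = x$empirical_p, R = x$R)
}

#' @export
#' @rdname plot_braingut
autoplot.permutation_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$permuted_accuracy)) +
    ggplot2::geom_histogram(bins = 25, fill = "grey70", color = "white") +
    ggplot2::geom_vline(xintercept = object$observed_accuracy,
                        color = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "ten-fold CV accuracy under shuffled labels", y = "count",
                  title = sprintf("Permutation null (p = %.3g)", object$empirical_p)) +
    ggplot2::theme_minimal()
}
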