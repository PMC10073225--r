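#' Leave-one-out search for the optimal number of features
#'
#' For each candidate subset size k, every subject is held out in turn:
#' recursive feature elimination runs on the remaining subjects only, a
#' linear SVM is trained on that split's top-k features, and the held-out
#' subject is predicted. The curve value at k is the mean held-out accuracy;
#' the optimal k attains the curve's maximum, with ties broken toward the
#' smallest k.
#'
#' Within each split a single elimination path is computed and every
#' candidate k reads off its own top-k survivors — with single-feature
#' elimination steps this is identical to running RFE to each k separately,
#' because stepwise elimination is nested.
#'
#' @param data A feature table (see [feature_names()]).
#' @param config An [rfe_config()]; `config$k_grid` controls the candidates.
#' @return An `rfe_curve` object: `curve` (tibble of `k`, `accuracy`),
#'   `optimal_k`, and the config.
#' @export
optimal_k_search <- function(data, config = rfe_config()) {
  xy <- as_xy(data)
  x <- warn_constant_once(xy$x)
  y <- xy$y
  n <- nrow(x)
  k_grid <- resolve_k_grid(config$k_grid, ncol(x))

  shared_path <- if (config$refit == "once") rfe_path(x, y, config, quiet = TRUE) else NULL

  correct <- matrix(NA, n, length(k_grid))
  for (i in seq_len(n)) {
    x_tr <- x[-i, , drop = FALSE]
    y_tr <- y[-i]
    path <- if (is.null(shared_path)) rfe_path(x_tr, y_tr, config, quiet = TRUE)
            else shared_path
    for (j in seq_along(k_grid)) {
      feats <- utils::tail(path, k_grid[j])
      correct[i, j] <- predict_holdout(x_tr[, feats, drop = FALSE], y_tr,
                                       x[i, feats, drop = FALSE], config) == y[i]
    }
  }
  curve <- tibble(k = k_grid, accuracy = colMeans(correct))
  structure(
    list(curve = curve,
         optimal_k = curve$k[which.max(curve$accuracy)],
         config = config, n = n),
    class = "rfe_curve"
  )
}

# train on (x_tr, y_tr), return predicted class for x_new (1 row)
predict_holdout <- function(x_tr, y_tr, x_new, config) {
  if (config$standardize) {
    std <- standardize_fit(x_tr)
    x_tr <- standardize_apply(x_tr, std)
    x_new <- standardize_apply(x_new, std)
  }
  fit <- fit_svm_linear(x_tr, y_tr, cost = config$cost)
  as.integer(drop(x_new %*% fit$weights) + fit$intercept > 0)
}

#' @export
print.rfe_curve <- function(x, ...) {
  cat(sprintf("<rfe_curve> %d candidate sizes, optimal k = %d (accuracy %.3f)\n",
              nrow(x$curve), x$optimal_k, max(x$curve$accuracy)))
  invisible(x)
}

#' @export
tidy.rfe_curve <- function(x, ...) x$curve

#' @export
glance.rfe_curve <- function(x, ...) {
  tibble(optimal_k = x$optimal_k, best_accuracy = max(x$curve$accuracy),
         n_candidates = nrow(x$curve), n_subjects = x$n)
}

#' @export
#' @rdname plot_braingut
autoplot.rfe_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$k, y = .data$accuracy)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::geom_vline(xintercept = object$optimal_k, linetype = 2,
                        color = "firebrick") +
    ggplot2::labs(x = "features kept", y = "mean held-out accuracy (LOO)",
                  title = sprintf("Optimal subset size: k = %d", object$optimal_k)) +
    ggplot2::theme_minimal()
}
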