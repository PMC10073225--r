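#' Fold-voting aggregation of RFE selections
#'
#' Splits subjects into label-stratified folds; within each fold's training
#' portion, recursive feature elimination keeps `target_n` features, and each
#' kept feature receives one vote. The final subset is the top `target_n`
#' features by votes; ties at the boundary are broken by larger mean absolute
#' SVM weight across the folds that selected the feature, then by name.
#'
#' @param data A feature table (see [feature_names()]).
#' @param target_n Number of features in the final subset (normally the
#'   optimal k from [optimal_k_search()]).
#' @param config An [rfe_config()]; `n_folds` and `seed` control the fold
#'   draw.
#' @return A `vote_tally` object: `tally` (tibble of `feature`, `votes`,
#'   `mean_abs_weight`), `final_features`, `n_folds`, `target_n`.
#' @export
vote_selection <- function(data, target_n, config = rfe_config()) {
  xy <- as_xy(data)
  x <- warn_constant_once(xy$x)
  y <- xy$y
  p <- ncol(x)
  if (target_n < 1 || target_n > p) abort("target_n must lie in [1, n_features].")

  folds <- withr::with_seed(config$seed, make_folds(y, config$n_folds))
  votes <- setNames(integer(p), colnames(x))
  wsum <- setNames(numeric(p), colnames(x))

  for (f in seq_len(config$n_folds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) {
      abort(paste0("Fold ", f, " training portion contains a single class."))
    }
    x_tr <- x[tr, , drop = FALSE]
    path <- rfe_path(x_tr, y[tr], config, k_min = target_n, quiet = TRUE)
    kept <- utils::tail(path, target_n)
    votes[kept] <- votes[kept] + 1L
    # |weights| of the kept features in this fold's final k-feature fit
    xs <- x_tr[, kept, drop = FALSE]
    if (config$standardize) xs <- standardize_apply(xs, standardize_fit(xs))
    fit <- fit_svm_linear(xs, y[tr], cost = config$cost)
    wsum[kept] <- wsum[kept] + abs(fit$weights)[kept]
  }

  tally <- tibble(
    feature = colnames(x),
    votes = as.integer(votes),
    mean_abs_weight = ifelse(votes > 0, wsum / pmax(votes, 1L), 0)
  ) %>%
    arrange(desc(.data$votes), desc(.data$mean_abs_weight), .data$feature)

  structure(
    list(tally = tally,
         final_features = tally$feature[seq_len(target_n)],
         n_folds = config$n_folds, target_n = as.integer(target_n),
         seed = config$seed),
    class = "vote_tally"
  )
}

#' @export
print.vote_tally <- function(x, ...) {
  cat(sprintf("<vote_tally> top %d of %d features over %d folds (total votes %d)\n",
              x$target_n, nrow(x$tally), x$n_folds, sum(x$tally$votes)))
  print(head(x$tally, 10))
  invisible(x)
}

#' @export
tidy.vote_tally <- function(x, ...) {
  x$tally %>% mutate(selected = .data$feature %in% x$final_features)
}

#' @export
glance.vote_tally <- function(x, ...) {
  tibble(target_n = x$target_n, n_folds = x$n_folds,
         total_votes = sum(x$tally$votes),
         unanimous = sum(x$tally$votes == x$n_folds))
}

#' @export
#' @rdname plot_braingut
autoplot.vote_tally <- function(object, ...) {
  df <- tidy(object) %>% filter(.data$votes > 0)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$votes),
    y = .data$votes, fill = .data$selected
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue", `FALSE` = "grey70")) +
    ggplot2::labs(x = NULL, y = sprintf("votes across %d folds", object$n_folds)) +
    ggplot2::theme_minimal()
}
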