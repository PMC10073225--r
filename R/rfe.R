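#' Configuration for SVM-based recursive feature elimination
#'
#' @param k_grid Candidate numbers of features for the optimal-size search:
#'   `NULL` (auto: geometric spacing densified near small k, ~15 candidates),
#'   `"full"` (every k from 1 to p), or an increasing integer vector.
#' @param step Features eliminated per RFE iteration. An integer >= 1 removes
#'   that many per round; a value in (0, 1) removes that fraction of the
#'   remaining features per round (at least one). The default of 1 is
#'   classical RFE; larger steps trade fidelity of the elimination order for
#'   speed.
#' @param cost Linear-SVM regularization constant C.
#' @param n_folds Folds for the vote-aggregation stage.
#' @param standardize Z-score features on the training data within every fit.
#'   Linear-SVM weights are scale-sensitive, so without this the elimination
#'   order is dominated by units.
#' @param refit How the optimal-k search treats each leave-one-out split:
#'   `"per_split"` (default) reruns elimination on the split's training
#'   portion; `"once"` ranks features once on all subjects and only refits
#'   the k-feature classifiers per split.
#' @param seed Integer seed for the fold draws.
#' @return An `rfe_config` object.
#' @export
rfe_config <- function(k_grid = NULL, step = 1, cost = 1, n_folds = 10,
                       standardize = TRUE, refit = c("per_split", "once"),
                       seed = 1L) {
  if (length(step) != 1 || step <= 0) abort("step must be a positive scalar.")
  if (cost <= 0) abort("cost must be > 0.")
  if (n_folds < 2) abort("n_folds must be >= 2.")
  structure(
    list(k_grid = k_grid, step = step, cost = cost,
         n_folds = as.integer(n_folds), standardize = isTRUE(standardize),
         refit = match.arg(refit), seed = as.integer(seed)),
    class = "rfe_config"
  )
}

resolve_k_grid <- function(k_grid, p) {
  if (is.null(k_grid)) k_grid <- auto_k_grid(p)
  else if (identical(k_grid, "full")) k_grid <- seq_len(p)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(k_grid) == 0) abort("Candidate k grid is empty.")
  if (min(k_grid) < 1 || max(k_grid) > p) {
    abort(paste0("Candidate k grid must lie within [1, ", p, "]."))
  }
  k_grid
}

# geometric spacing between 1 and p, densified near small k
auto_k_grid <- function(p, n = 15) {
  if (p <= n) return(seq_len(p))
  small <- 1:5
  geom <- round(exp(seq(log(6), log(p), length.out = n - 5)))
  sort(unique(c(small, geom, p)))
}

n_eliminated <- function(remaining, step) {
  if (step >= 1) as.integer(min(step, remaining)) else max(1L, floor(remaining * step))
}

# Full elimination path: repeatedly fit a linear SVM on the surviving
# features and drop the `step` with smallest |weight|, down to k_min
# survivors. Because single-step RFE is nested (eliminating to k and
# continuing equals eliminating to k' < k directly), one path serves every
# candidate k at once. Returns features ordered worst-first (eliminated
# first ... most persistent last); constant columns are dropped up front
# with a warning and rank worst.
rfe_path <- function(x, y, config, k_min = 1L, quiet = FALSE) {
  p <- ncol(x)
  feats <- colnames(x)
  if (is.null(feats)) feats <- colnames(x) <- sprintf("f%04d", seq_len(p))
  constant <- apply(x, 2, sd) == 0
  if (any(constant) && !quiet) {
    warn(paste0("Dropping constant feature(s) before RFE: ",
                paste(feats[constant], collapse = ", ")))
  }
  order_out <- feats[constant]        # constants rank worst
  surviving <- feats[!constant]
  while (length(surviving) > max(k_min, 1L)) {
    xs <- x[, surviving, drop = FALSE]
    if (config$standardize) xs <- standardize_apply(xs, standardize_fit(xs))
    fit <- fit_svm_linear(xs, y, cost = config$cost)
    drop_n <- min(n_eliminated(length(surviving), config$step),
                  length(surviving) - k_min)
    # smallest |weight| eliminated; ties broken by name for determinism
    ord <- order(abs(fit$weights), surviving)
    dropped <- surviving[ord[seq_len(drop_n)]]
    order_out <- c(order_out, dropped)
    surviving <- setdiff(surviving, dropped)
  }
  c(order_out, surviving[order(rank_final_weights(x, y, surviving, config))])
}

# rank the last survivors by their |weight| in a final fit so the path is a
# complete worst-to-best ordering
rank_final_weights <- function(x, y, surviving, config) {
  if (length(surviving) == 1) return(setNames(1, surviving))
  xs <- x[, surviving, drop = FALSE]
  if (config$standardize) xs <- standardize_apply(xs, standardize_fit(xs))
  fit <- fit_svm_linear(xs, y, cost = config$cost)
  rank(abs(fit$weights), ties.method = "first")
}

#' Rank features by SVM-based recursive feature elimination
#'
#' Trains a linear SVM on all current features, removes the configured number
#' with smallest absolute weight, and repeats until `k_target` features
#' remain. Deterministic given inputs.
#'
#' @param data A feature table (see [feature_names()]), or a numeric matrix
#'   if `labels` is supplied.
#' @param k_target Number of features to keep.
#' @param config An [rfe_config()].
#' @param labels Optional label vector when `data` is a matrix.
#' @return A list with `survivors` (the `k_target` kept feature names) and
#'   `elimination_order` (the `p - k_target` removed, worst first).
#' @export
svm_rfe_rank <- function(data, k_target, config = rfe_config(), labels = NULL) {
  xy <- as_xy(data, labels)
  p <- ncol(xy$x)
  if (k_target < 1 || k_target > p) abort("k_target must lie in [1, n_features].")
  if (k_target == p) {
    return(list(survivors = colnames(xy$x), elimination_order = character(0)))
  }
  path <- rfe_path(xy$x, xy$y, config, k_min = k_target)
  list(
    survivors = utils::tail(path, k_target),
    elimination_order = utils::head(path, p - k_target)
  )
}

# warn once about globally-constant columns and drop them; transient
# constancy inside individual training splits is handled quietly downstream
warn_constant_once <- function(x) {
  constant <- apply(x, 2, sd) == 0
  if (any(constant)) {
    warn(paste0("Dropping constant feature(s) before RFE: ",
                paste(colnames(x)[constant], collapse = ", ")))
    x <- x[, !constant, drop = FALSE]
  }
  x
}

as_xy <- function(data, labels = NULL) {
  if (is.matrix(data)) {
    if (is.null(labels)) abort("labels must be supplied when data is a matrix.")
    if (is.null(colnames(data))) colnames(data) <- sprintf("f%04d", seq_len(ncol(data)))
    list(x = data, y = check_labels(labels))
  } else {
    list(x = feature_matrix(data), y = check_labels(data$label))
  }
}
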