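#' ROC curve points and area under the curve
#'
#' Sweeps a decision threshold over the unique score values (ties grouped),
#' from "predict nobody positive" to "predict everybody positive", recording
#' the false- and true-positive rate at each step; the area is computed by
#' the trapezoidal rule. Class 1 (obese) is the positive class and higher
#' scores favor it.
#'
#' @param scores Finite numeric decision scores, one per subject.
#' @param labels Binary labels (0/1), both classes present.
#' @return A `roc_result`: `points` (tibble `threshold`, `fpr`, `tpr`,
#'   starting at (0,0) and ending at (1,1), monotone), and `auc`.
#' @export
roc_points <- function(scores, labels) {
  labels <- check_labels(labels)
  if (any(!is.finite(scores))) abort("Scores must be finite.")
  if (length(scores) != length(labels)) abort("scores and labels lengths differ.")
  pos <- sum(labels == 1)
  neg <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # group tied scores: one ROC point per distinct threshold
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l == 1); fp <- cumsum(l == 0)
  last_of_grp <- !duplicated(grp, fromLast = TRUE)
  points <- tibble(
    threshold = c(Inf, s[last_of_grp]),
    fpr = c(0, fp[last_of_grp] / neg),
    tpr = c(0, tp[last_of_grp] / pos)
  )
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + points$tpr[-1]) / 2)
  structure(list(points = points, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$points

#' @export
#' @rdname plot_braingut
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3, color = "grey60") +
    ggplot2::geom_step(color = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}
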