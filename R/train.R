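#' Train a final linear classifier
#'
#' Fits one of three linear decision rules on a design matrix: a linear-kernel
#' SVM, a ridge classifier (penalized least squares against labels coded
#' -1/+1, decision by the sign of the linear score), or logistic regression.
#' Features are z-scored on the training data before fitting; reported weights
#' are on the standardized scale, with the centering/scaling stored so the
#' model applies to raw-scale data. All fits are deterministic given inputs.
#'
#' If unpenalized logistic regression fails to converge or separates
#' perfectly, a lightly ridge-penalized logistic fit is substituted with a
#' warning.
#'
#' @param x Design matrix (subjects x predictors) with column names.
#' @param y Binary labels (0/1).
#' @param family `"svm"`, `"ridge"`, or `"logistic"`.
#' @param cost SVM regularization constant C.
#' @param lambda Ridge penalty.
#' @param standardize Z-score predictors on the training data (default TRUE).
#' @return A `linear_fit`: family, feature_names, weights (standardized
#'   scale), intercept, standardization parameters.
#' @export
train_linear <- function(x, y, family = c("svm", "ridge", "logistic"),
                         cost = 1, lambda = 1, standardize = TRUE) {
  family <- match.arg(family)
  y <- check_labels(y)
  if (is.null(colnames(x))) colnames(x) <- sprintf("x%03d", seq_len(ncol(x)))
  std <- if (standardize) standardize_fit(x) else
    list(center = setNames(rep(0, ncol(x)), colnames(x)),
         scale = setNames(rep(1, ncol(x)), colnames(x)))
  xs <- standardize_apply(x, std)

  fit <- switch(family,
    svm = fit_svm_linear(xs, y, cost = cost),
    ridge = fit_ridge_classifier(xs, y, lambda = lambda),
    logistic = fit_logistic(xs, y)
  )
  structure(
    list(family = family, feature_names = colnames(x),
         weights = fit$weights, intercept = fit$intercept,
         standardization = std,
         cost = cost, lambda = lambda),
    class = "linear_fit"
  )
}

# ridge classifier: center y in {-1,+1}, solve (Xc'Xc + lambda I) b = Xc'yc;
# intercept recovers the uncentered score. Decision is sign of the score.
fit_ridge_classifier <- function(xs, y, lambda = 1) {
  ypm <- ifelse(y == 1, 1, -1)
  xbar <- colMeans(xs)
  ybar <- mean(ypm)
  xc <- sweep(xs, 2, xbar)
  yc <- ypm - ybar
  p <- ncol(xs)
  b <- solve(crossprod(xc) + lambda * diag(p), crossprod(xc, yc))
  w <- setNames(as.numeric(b), colnames(xs))
  list(weights = w, intercept = ybar - sum(xbar * w))
}

fit_logistic <- function(xs, y) {
  df <- data.frame(xs, check.names = FALSE)
  fit <- NULL
  separated <- FALSE
  withCallingHandlers(
    fit <- glm(y ~ ., data = cbind(df, y = y), family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separated || !fit$converged || anyNA(coef(fit))) {
    warn("Logistic regression separated or failed to converge; using a ridge-penalized logistic fit.")
    gfit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                           lambda = 1e-2, standardize = FALSE)
    w <- setNames(as.numeric(gfit$beta), colnames(xs))
    return(list(weights = w, intercept = as.numeric(gfit$a0)))
  }
  cf <- coef(fit)
  list(weights = setNames(cf[-1], colnames(xs)), intercept = unname(cf[1]))
}

#' Predict from a trained linear classifier
#'
#' @param object A `linear_fit`.
#' @param newdata Raw-scale matrix with the model's predictor columns.
#' @param type `"score"` (linear decision score; for the logistic family the
#'   predicted probability of class 1), or `"class"` (0/1).
#' @param ... Unused.
#' @return Numeric vector of scores or integer classes.
#' @export
predict.linear_fit <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  newdata <- newdata[, object$feature_names, drop = FALSE]
  xs <- standardize_apply(newdata, object$standardization)
  s <- drop(xs %*% object$weights) + object$intercept
  if (type == "class") return(as.integer(s > 0))
  if (object$family == "logistic") stats::plogis(s) else s
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> family = %s, %d predictors\n",
              x$family, length(x$feature_names)))
  invisible(x)
}

#' @export
tidy.linear_fit <- function(x, ...) {
  bind_rows(
    tibble(term = "(Intercept)", estimate = x$intercept),
    tibble(term = x$feature_names, estimate = unname(x$weights))
  )
}

#' @export
glance.linear_fit <- function(x, ...) {
  tibble(family = x$family, n_predictors = length(x$feature_names),
         intercept = x$intercept)
}
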