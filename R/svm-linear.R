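# Internal linear-SVM wrapper around e1071/libsvm.
#
# Returns the primal weight vector and intercept of the separating
# hyperplane, oriented so that a positive decision score predicts class 1
# (obese). libsvm's internal sign convention depends on the order in which
# classes appear in the training data, so the orientation is checked against
# the reported decision values rather than assumed.

fit_svm_linear <- function(x, y, cost = 1) {
  y <- factor(y, levels = c(0, 1))
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # orient: positive score must favor class "1"
  dv_name <- colnames(fit$decision.values)
  if (is.null(dv_name)) {
    pred <- predict(fit, x, decision.values = TRUE)
    dv_name <- colnames(attr(pred, "decision.values"))
  }
  positive_class <- strsplit(dv_name, "/")[[1]][1]
  if (identical(positive_class, "0")) {
    w <- -w
    b <- -b
  }
  names(w) <- colnames(x)
  list(weights = w, intercept = b)
}

# z-score columns using the supplied (training) statistics; constant columns
# get scale 1 so they map to all-zero rather than NaN
standardize_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(center = center, scale = scale)
}

standardize_apply <- function(x, std) {
  scale(x, center = std$center, scale = std$scale)[, , drop = FALSE]
}
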