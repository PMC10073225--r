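#' Assemble the model design for a final classifier
#'
#' Combines the selected features with the clinical covariates: age and sex
#' always enter as predictors; habitual diet is added whenever the block
#' contains metabolite features (`"metabolite"` or `"combined"`). Covariates
#' are never candidates for feature selection; they are appended here.
#'
#' @param data A feature table (see [feature_names()]).
#' @param selected Character vector of selected feature names.
#' @param block One of `"brain"`, `"metabolite"`, `"combined"`.
#' @return A list with `x` (design matrix: selected features then
#'   covariates), `y` (labels), `feature_cols`, `covariate_cols`.
#' @export
assemble_design <- function(data, selected, block = c("brain", "metabolite", "combined")) {
  block <- match.arg(block)
  missing <- setdiff(selected, feature_names(data))
  if (length(missing) > 0) {
    abort(paste0("Selected feature(s) not in the table: ",
                 paste(missing, collapse = ", ")))
  }
  covars <- c("age", "sex", if (block %in% c("metabolite", "combined")) "diet")
  x <- cbind(feature_matrix(data, selected), as.matrix(data[covars]))
  list(x = x, y = check_labels(data$label),
       feature_cols = selected, covariate_cols = covars)
}
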