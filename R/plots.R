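#' Plot methods for braingut result objects
#'
#' `autoplot()` methods returning ggplot objects: the accuracy-vs-k curve of
#' an `rfe_curve` (with the optimal k marked), the vote distribution of a
#' `vote_tally`, the ROC curve of a `roc_result` or `evaluation_report`, and
#' the permuted-accuracy histogram of a `permutation_result` with the
#' observed accuracy marked.
#'
#' @param object A braingut result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plot_braingut
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
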