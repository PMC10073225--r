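#' Merge top-weighted features from the brain and metabolite models
#'
#' Builds the combined model's feature list by keeping, from each block's
#' final trained model, the features whose absolute standardized weight
#' ranks in the top `ceiling(fraction * block size)`; ties at the cut are
#' kept together and flagged. Covariate columns (age, sex, diet) never enter
#' the ranking. Explicit per-block counts can be supplied through
#' `count_override` to reproduce an externally fixed composition.
#'
#' @param brain_model,met_model `linear_fit` objects for the brain and
#'   metabolite blocks.
#' @param fraction Fraction of each block to keep, in (0, 1].
#' @param count_override Optional named list/vector with elements `brain`
#'   and `metabolite` giving exact per-block counts.
#' @return A `merged_features` object: `features` (tibble of `feature`,
#'   `block`, `weight`, `abs_weight`, `rank`, `kept`, `tie_at_cut`),
#'   `selected` (kept feature names), and per-block kept counts.
#' @export
merge_top_fraction <- function(brain_model, met_model, fraction = 0.9,
                               count_override = NULL) {
  if (fraction <= 0 || fraction > 1) abort("fraction must lie in (0, 1].")
  covars <- c("age", "sex", "diet")

  rank_block <- function(model, block) {
    stopifnot(inherits(model, "linear_fit"))
    w <- model$weights[setdiff(model$feature_names, covars)]
    tibble(feature = names(w), block = block,
           weight = unname(w), abs_weight = abs(unname(w))) %>%
      arrange(desc(.data$abs_weight), .data$feature) %>%
      mutate(rank = row_number())
  }

  keep_block <- function(df) {
    n_block <- nrow(df)
    if (!is.null(count_override)) {
      # exact composition requested: keep precisely k by rank (name-tiebroken)
      ko <- count_override[[df$block[1]]]
      if (is.null(ko)) abort(paste0("count_override lacks block '", df$block[1], "'."))
      if (ko > n_block) abort("count_override exceeds block size.")
      return(df %>% mutate(kept = .data$rank <= as.integer(ko), tie_at_cut = FALSE))
    }
    k <- ceiling(fraction * n_block)
    cut_val <- df$abs_weight[k]
    n_above <- sum(df$abs_weight > cut_val)
    n_at <- sum(df$abs_weight == cut_val)
    df %>% mutate(
      kept = .data$abs_weight >= cut_val,
      tie_at_cut = (n_above + n_at > k) & .data$abs_weight == cut_val
    )
  }

  blocks <- bind_rows(
    keep_block(rank_block(brain_model, "brain")),
    keep_block(rank_block(met_model, "metabolite"))
  )
  kept <- blocks %>% filter(.data$kept)
  structure(
    list(
      features = blocks,
      selected = kept$feature,
      n_brain = sum(kept$block == "brain"),
      n_metabolite = sum(kept$block == "metabolite"),
      fraction = fraction,
      count_override = count_override,
      note = paste("top fraction kept per block by |standardized weight|;",
                   "ties at the cut kept together; rounding rule: ceiling")
    ),
    class = "merged_features"
  )
}

#' @export
print.merged_features <- function(x, ...) {
  cat(sprintf("<merged_features> %d features (%d brain + %d metabolite), fraction %.2f%s\n",
              length(x$selected), x$n_brain, x$n_metabolite, x$fraction,
              if (!is.null(x$count_override)) " [count_override]" else ""))
  invisible(x)
}

#' @export
tidy.merged_features <- function(x, ...) x$features

#' @export
glance.merged_features <- function(x, ...) {
  tibble(n_selected = length(x$selected), n_brain = x$n_brain,
         n_metabolite = x$n_metabolite, fraction = x$fraction)
}
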