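#' Configure an end-to-end pipeline run
#'
#' One declarative object controls every stage: cohort generation (or a
#' pre-assembled feature table), connectome metrics, feature selection per
#' data block, final-model families, the combined-model merge, and the
#' permutation null.
#'
#' @param cohort A [cohort_spec()] (the cohort will be generated), or `NULL`
#'   if `features` supplies a ready feature table.
#' @param features Optional pre-assembled feature table (tibble) to use
#'   instead of generating a cohort.
#' @param blocks Data blocks to analyze: subset of `"brain"`,
#'   `"metabolite"`, `"combined"` (`"combined"` requires both others).
#' @param metrics Connectome nodal metrics for the brain block.
#' @param rfe An [rfe_config()].
#' @param families Final-model families to evaluate.
#' @param merge_fraction Top fraction of each block's model weights merged
#'   into the combined feature set.
#' @param permutation_R Permutation replicates (0 disables the null).
#' @param permutation_family Family used for the permutation null.
#' @param seed Master seed for all stage-level randomness.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            features = NULL,
                            blocks = c("brain", "metabolite", "combined"),
                            metrics = c("NodeBWCent", "AvPathLength"),
                            rfe = rfe_config(),
                            families = c("svm", "ridge", "logistic"),
                            merge_fraction = 0.9,
                            permutation_R = 199,
                            permutation_family = "svm",
                            seed = 1L) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  if ("combined" %in% blocks && !all(c("brain", "metabolite") %in% blocks)) {
    abort("The combined block requires both the brain and metabolite blocks.")
  }
  families <- match.arg(families, c("svm", "ridge", "logistic"), several.ok = TRUE)
  structure(
    list(cohort = cohort, features = features, blocks = blocks,
         metrics = metrics, rfe = rfe, families = families,
         merge_fraction = merge_fraction,
         permutation_R = as.integer(permutation_R),
         permutation_family = permutation_family,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full brain-gut classification pipeline
#'
#' Orchestrates the stages end to end: synthetic-cohort generation (unless a
#' feature table is supplied), connectome nodal metrics, per-block SVM-RFE
#' with the LOO optimal-k search and ten-fold vote aggregation, final linear
#' models per family evaluated by LOO, the combined model built by merging
#' top-weighted features from the brain and metabolite models, and the
#' label-permutation null. Idempotent given the seed: two runs with the same
#' config produce identical results.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log per-stage progress and timings to stderr.
#' @return A `pipeline_run`: list with `table1`, per-block `selection`
#'   (rfe_curve + vote_tally), `models` (trained `linear_fit` per block),
#'   `reports` (evaluation_report per block x family), `merged`
#'   (merged_features), `permutation` (per block), and a `manifest` holding
#'   seeds and the config.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
    say("[%s] done in %.1fs", name, as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  data_blocks <- setdiff(config$blocks, "combined")

  if (is.null(config$features)) {
    if (is.null(config$cohort)) abort("Config needs either a cohort spec or a feature table.")
    cohort <- t_stage("synthetic_cohort",
                      generate_cohort(config$cohort, blocks = data_blocks))
    block_features <- list()
    if ("brain" %in% data_blocks) {
      block_features$brain <- t_stage("connectome_features",
        cohort_features(cohort, blocks = "brain", metrics = config$metrics))
    }
    if ("metabolite" %in% data_blocks) {
      block_features$metabolite <- cohort_features(cohort, blocks = "metabolite")
    }
    covariates <- cohort$covariates
    truth <- cohort$truth
  } else {
    block_features <- split_feature_blocks(config$features, data_blocks)
    covariates <- config$features[intersect(reserved_cols, names(config$features))]
    truth <- NULL
    cohort <- NULL
  }

  # uninformative constant columns (e.g. a region with zero betweenness in
  # every subject) are removed up front rather than inside every RFE split
  for (blk in names(block_features)) {
    fn <- feature_names(block_features[[blk]])
    const <- vapply(block_features[[blk]][fn], function(v) sd(v) == 0, logical(1))
    if (any(const)) {
      say("[%s] dropping %d constant feature column(s)", blk, sum(const))
      drop <- fn[const]
      block_features[[blk]] <-
        block_features[[blk]][setdiff(names(block_features[[blk]]), drop)]
    }
  }

  tab1 <- t_stage("cohort_table", cohort_table(covariates))

  selection <- list(); models <- list(); reports <- list(); perms <- list()
  for (blk in data_blocks) {
    feats <- block_features[[blk]]
    rfe_cfg <- config$rfe
    rfe_cfg$seed <- config$seed + match(blk, c("brain", "metabolite"))
    curve <- t_stage(paste0("optimal_k_search/", blk), optimal_k_search(feats, rfe_cfg))
    tally <- t_stage(paste0("vote_selection/", blk),
                     vote_selection(feats, curve$optimal_k, rfe_cfg))
    selection[[blk]] <- list(curve = curve, tally = tally)

    des <- assemble_design(feats, tally$final_features, blk)
    models[[blk]] <- train_linear(des$x, des$y, family = "svm", cost = rfe_cfg$cost)
    for (fam in config$families) {
      reports[[blk]][[fam]] <- t_stage(
        paste0("loo_evaluate/", blk, "/", fam),
        loo_evaluate(feats, tally$final_features, blk, fam, cost = rfe_cfg$cost))
    }
  }

  merged <- NULL
  if ("combined" %in% config$blocks) {
    merged <- t_stage("merge_top_fraction",
      merge_top_fraction(models$brain, models$metabolite, config$merge_fraction))
    combined_features <- dplyr::left_join(
      block_features$brain,
      select(block_features$metabolite, -all_of(setdiff(reserved_cols, "subject_id"))),
      by = "subject_id")
    models$combined <- {
      des <- assemble_design(combined_features, merged$selected, "combined")
      train_linear(des$x, des$y, family = "svm", cost = config$rfe$cost)
    }
    for (fam in config$families) {
      reports$combined[[fam]] <- t_stage(
        paste0("loo_evaluate/combined/", fam),
        loo_evaluate(combined_features, merged$selected, "combined", fam,
                     cost = config$rfe$cost))
    }
    block_features$combined <- combined_features
  }

  if (config$permutation_R > 0) {
    for (blk in config$blocks) {
      sel <- if (blk == "combined") merged$selected else selection[[blk]]$tally$final_features
      perms[[blk]] <- t_stage(paste0("permutation_test/", blk),
        permutation_test(block_features[[blk]], sel, blk,
                         family = config$permutation_family,
                         R = config$permutation_R,
                         seed = config$seed + 100 + match(blk, config$blocks)))
    }
  }

  structure(
    list(
      table1 = tab1,
      selection = selection,
      models = models,
      reports = reports,
      merged = merged,
      permutation = perms,
      truth = truth,
      features = block_features,
      manifest = list(seed = config$seed, config = config,
                      generated = !is.null(cohort),
                      timestamp_free = TRUE)
    ),
    class = "pipeline_run"
  )
}

# route a pre-assembled feature table into blocks by column naming:
# <MetricTag>__<region> columns are brain, the rest metabolite
split_feature_blocks <- function(features, data_blocks) {
  fn <- feature_names(features)
  brain_cols <- grep("^(NodeBWCent|AvPathLength|Strength|EigCent)__", fn, value = TRUE)
  met_cols <- setdiff(fn, brain_cols)
  keep <- intersect(reserved_cols, names(features))
  out <- list()
  if ("brain" %in% data_blocks) out$brain <- features[c(keep, brain_cols)]
  if ("metabolite" %in% data_blocks) out$metabolite <- features[c(keep, met_cols)]
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  for (blk in names(x$reports)) {
    for (fam in names(x$reports[[blk]])) {
      r <- x$reports[[blk]][[fam]]
      cat(sprintf("  %-10s %-8s accuracy %.4f  AUC %.4f\n",
                  blk, fam, r$accuracy, r$auc))
    }
  }
  for (blk in names(x$permutation)) {
    p <- x$permutation[[blk]]
    cat(sprintf("  permutation %-10s mean permuted %.4f, p = %.4g\n",
                blk, mean(p$permuted_accuracies), p$empirical_p))
  }
  invisible(x)
}

#' Summarize a pipeline run
#'
#' @param x A `pipeline_run`.
#' @param ... Unused.
#' @return Tibble with one row per block x family: accuracy, AUC, confusion
#'   counts, selected feature count.
#' @export
glance.pipeline_run <- function(x, ...) {
  rows <- list()
  for (blk in names(x$reports)) {
    n_sel <- if (blk == "combined") length(x$merged$selected)
             else x$selection[[blk]]$tally$target_n
    for (fam in names(x$reports[[blk]])) {
      rows[[paste(blk, fam)]] <- glance(x$reports[[blk]][[fam]]) %>%
        mutate(n_selected = n_sel)
    }
  }
  bind_rows(rows)
}
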