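#' Write a synthetic cohort to delimited text files
#'
#' Emits, under `dir`: one tab-separated square count matrix per subject
#' (`connectome_<id>.tsv`, region names as header row and first column), a
#' long region-volume table (`volumes.tsv`: subject_id, region, volume), the
#' metabolite table (`metabolites.tsv`, subjects x features), the
#' covariate/label table (`covariates.tsv`) and a truth manifest
#' (`truth.tsv`) naming the planted informative features.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(cohort$covariates, file.path(dir, "covariates.tsv"))
  if (!is.null(cohort$metabolites)) {
    readr::write_tsv(cohort$metabolites, file.path(dir, "metabolites.tsv"))
  }
  if (!is.null(cohort$fibers)) {
    vols <- purrr::imap(cohort$fibers, function(fc, sid) {
      tibble(subject_id = sid, region = fc$region_names, volume = fc$volumes)
    })
    readr::write_tsv(bind_rows(vols), file.path(dir, "volumes.tsv"))
    for (sid in names(cohort$fibers)) {
      write_fiber_matrix(cohort$fibers[[sid]],
                         file.path(dir, paste0("connectome_", sid, ".tsv")))
    }
  }
  truth <- bind_rows(
    tibble(block = "brain", feature = cohort$truth$regions),
    tibble(block = "metabolite", feature = cohort$truth$metabolites)
  )
  readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

write_fiber_matrix <- function(fc, path) {
  df <- as.data.frame(fc$counts)
  df <- cbind(region = fc$region_names, df)
  readr::write_tsv(df, path)
}

#' Read one square connectivity matrix written by [write_cohort()]
#'
#' @param path Path to a tab-separated square matrix with region names as
#'   header row and first column.
#' @param volumes Numeric vector of region volumes (or a tibble with
#'   `region`, `volume` columns, matched by name).
#' @return A [fiber_connectivity()] object.
#' @export
read_fiber_matrix <- function(path, volumes) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  regions <- df[[1]]
  cm <- as.matrix(df[-1])
  rownames(cm) <- regions
  if (is.data.frame(volumes)) {
    volumes <- volumes$volume[match(regions, volumes$region)]
  }
  fiber_connectivity(cm, volumes, regions)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory produced by [write_cohort()].
#' @return A `synthetic_cohort`-shaped list (without a spec).
#' @export
read_cohort <- function(dir) {
  covariates <- readr::read_tsv(file.path(dir, "covariates.tsv"),
                                show_col_types = FALSE)
  metabolites <- NULL
  if (file.exists(file.path(dir, "metabolites.tsv"))) {
    metabolites <- readr::read_tsv(file.path(dir, "metabolites.tsv"),
                                   show_col_types = FALSE)
  }
  fibers <- NULL
  vol_path <- file.path(dir, "volumes.tsv")
  if (file.exists(vol_path)) {
    vols <- readr::read_tsv(vol_path, show_col_types = FALSE)
    if (!"subject_id" %in% names(vols)) vols$subject_id <- NA_character_
    fibers <- lapply(covariates$subject_id, function(sid) {
      v <- vols %>% filter(is.na(.data$subject_id) | .data$subject_id == sid)
      read_fiber_matrix(file.path(dir, paste0("connectome_", sid, ".tsv")),
                        v[c("region", "volume")])
    })
    names(fibers) <- covariates$subject_id
  }
  truth <- NULL
  if (file.exists(file.path(dir, "truth.tsv"))) {
    tr <- readr::read_tsv(file.path(dir, "truth.tsv"), show_col_types = FALSE)
    truth <- list(regions = tr$feature[tr$block == "brain"],
                  metabolites = tr$feature[tr$block == "metabolite"])
  }
  structure(list(fibers = fibers, metabolites = metabolites,
                 covariates = covariates, truth = truth, spec = NULL),
            class = "synthetic_cohort")
}

#' Write the artifacts of a pipeline run
#'
#' Writes, under `dir`: `summary.json` (per-block/family accuracies, AUCs,
#' confusion counts, selected features, permutation results, manifest),
#' per-block selection tables (`tally_<block>.tsv`, `curve_<block>.tsv`),
#' ROC points per block/family (`roc_<block>_<family>.tsv`), the cohort
#' descriptive table (`table1.tsv`) and the merged feature list
#' (`merged_features.tsv`). JSON output is byte-stable for a fixed seed.
#'
#' @param run A `pipeline_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "pipeline_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$table1, file.path(dir, "table1.tsv"))
  for (blk in names(run$selection)) {
    readr::write_tsv(run$selection[[blk]]$tally$tally,
                     file.path(dir, paste0("tally_", blk, ".tsv")))
    readr::write_tsv(run$selection[[blk]]$curve$curve,
                     file.path(dir, paste0("curve_", blk, ".tsv")))
  }
  for (blk in names(run$reports)) {
    for (fam in names(run$reports[[blk]])) {
      readr::write_tsv(run$reports[[blk]][[fam]]$roc$points,
                       file.path(dir, paste0("roc_", blk, "_", fam, ".tsv")))
    }
  }
  if (!is.null(run$merged)) {
    readr::write_tsv(run$merged$features, file.path(dir, "merged_features.tsv"))
  }

  summary <- list(
    seed = run$manifest$seed,
    models = lapply(run$reports, function(fams) lapply(fams, function(r) {
      list(accuracy = r$accuracy, auc = r$auc,
           confusion = as.list(r$confusion),
           precision_recall = r$precision_recall,
           protocol = r$protocol)
    })),
    selection = lapply(run$selection, function(s) {
      list(optimal_k = s$curve$optimal_k,
           final_features = s$tally$final_features)
    }),
    merged = if (!is.null(run$merged)) {
      list(n_selected = length(run$merged$selected),
           n_brain = run$merged$n_brain, n_metabolite = run$merged$n_metabolite,
           note = run$merged$note)
    },
    permutation = lapply(run$permutation, function(p) {
      list(observed_accuracy = p$observed_accuracy,
           mean_permuted_accuracy = mean(p$permuted_accuracies),
           empirical_p = p$empirical_p, R = p$R, seed = p$seed)
    })
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
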