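#' Generate a synthetic brain-gut cohort
#'
#' Draws a cohort from a [cohort_spec()]: per-subject streamline-count
#' connectomes with region volumes, a subjects x metabolites abundance table,
#' covariates (age, sex, diet) and group labels, plus a manifest of the
#' planted informative features.
#'
#' The generative model is intentionally the simplest one matching the
#' assumptions the downstream analysis makes (linear separability in a small
#' set of features):
#'
#' * A shared random connectivity template assigns each region pair an
#'   expected fiber count (a fraction of pairs are unconnected); each
#'   subject's counts are independent Poisson draws around the template.
#'   In the obese group, every count incident to an informative region is
#'   scaled by `brain_effect` (rounded back to an integer).
#' * Metabolite log-abundances are Gaussian with feature-specific mean and
#'   sd; informative features have their obese-group mean shifted by
#'   `metabolite_effect` standard deviations. Abundances are the
#'   exponential, hence strictly positive.
#' * Covariates are drawn from the group-wise `covariate_model`.
#'
#' Identical seeds give bit-identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @param blocks Which data blocks to generate: any of `"brain"`,
#'   `"metabolite"`. Restricting blocks speeds up simulation studies that
#'   only need one block.
#' @return A `synthetic_cohort` object: list with `fibers` (list of
#'   [fiber_connectivity()], one per subject, when the brain block is
#'   generated), `metabolites` (tibble), `covariates` (tibble with
#'   `subject_id`, `label`, `age`, `sex`, `diet`), `truth` (planted feature
#'   names per block) and `spec`.
#' @export
generate_cohort <- function(spec, blocks = c("brain", "metabolite")) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  blocks <- match.arg(blocks, several.ok = TRUE)

  n <- spec$n_overweight + spec$n_obese
  # overweight (label 0) first, then obese (label 1)
  label <- c(rep(0L, spec$n_overweight), rep(1L, spec$n_obese))
  subject_id <- sprintf("S%03d", seq_len(n))
  region_names <- sprintf("roi_%03d", seq_len(spec$n_regions))
  met_names <- sprintf("met_%04d", seq_len(spec$n_metabolites))

  withr::with_seed(spec$seed, {
    covariates <- draw_covariates(spec, subject_id, label)
    metabolites <- NULL
    fibers <- NULL
    if ("metabolite" %in% blocks) {
      metabolites <- draw_metabolites(spec, subject_id, label, met_names)
    }
    if ("brain" %in% blocks) {
      fibers <- draw_connectomes(spec, label, region_names)
      names(fibers) <- subject_id
    }
  })

  structure(
    list(
      fibers = fibers,
      metabolites = metabolites,
      covariates = covariates,
      truth = list(
        regions = region_names[spec$informative_regions],
        metabolites = met_names[spec$informative_metabolites]
      ),
      spec = spec
    ),
    class = "synthetic_cohort"
  )
}

draw_covariates <- function(spec, subject_id, label) {
  cm <- spec$covariate_model
  grp <- ifelse(label == 1L, "obese", "overweight")
  age <- sex <- diet <- numeric(length(label))
  for (g in c("overweight", "obese")) {
    idx <- which(grp == g)
    age[idx] <- rnorm(length(idx), cm[[g]]$age_mean, cm[[g]]$age_sd)
    sex[idx] <- rbinom(length(idx), 1, cm[[g]]$p_male)
    diet[idx] <- rbinom(length(idx), 1, cm[[g]]$p_american)
  }
  tibble(
    subject_id = subject_id, label = label,
    age = round(pmax(age, 18), 1), sex = as.integer(sex), diet = as.integer(diet)
  )
}

draw_metabolites <- function(spec, subject_id, label, met_names) {
  p <- spec$n_metabolites
  mu <- rnorm(p, mean = 5, sd = 1)         # feature-specific log-abundance level
  sigma <- runif(p, min = 0.5, max = 1.5)  # feature-specific spread
  z <- matrix(rnorm(length(label) * p), length(label), p)
  z <- sweep(sweep(z, 2, sigma, `*`), 2, mu, `+`)
  shift <- spec$metabolite_effect * sigma[spec$informative_metabolites]
  z[label == 1L, spec$informative_metabolites] <-
    sweep(z[label == 1L, spec$informative_metabolites, drop = FALSE], 2, shift, `+`)
  ab <- exp(z)
  colnames(ab) <- met_names
  dplyr::bind_cols(tibble(subject_id = subject_id), as_tibble(ab))
}

draw_connectomes <- function(spec, label, region_names) {
  r <- spec$n_regions
  # shared template: ~45% of region pairs connected, gamma-distributed intensity
  lambda <- matrix(0, r, r)
  ut <- upper.tri(lambda)
  connected <- runif(sum(ut)) < 0.45
  intensity <- stats::rgamma(sum(ut), shape = 2, scale = 30) * connected
  lambda[ut] <- intensity
  lambda <- lambda + t(lambda)
  base_vol <- stats::rlnorm(r, meanlog = log(3000), sdlog = 0.4)

  scale_mat <- matrix(1, r, r)
  if (spec$brain_effect != 1 && length(spec$informative_regions) > 0) {
    scale_mat[spec$informative_regions, ] <- spec$brain_effect
    scale_mat[, spec$informative_regions] <- spec$brain_effect
  }

  lapply(seq_along(label), function(i) {
    cnt <- matrix(0, r, r)
    cnt[ut] <- rpois(sum(ut), lambda[ut])
    cnt <- cnt + t(cnt)
    if (label[i] == 1L) cnt <- round(cnt * scale_mat)
    vols <- base_vol * stats::rlnorm(r, meanlog = 0, sdlog = 0.05)
    fiber_connectivity(cnt, vols, region_names)
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n <- nrow(x$covariates)
  cat(sprintf("<synthetic_cohort> %d subjects (%d obese / %d overweight)\n",
              n, sum(x$covariates$label == 1), sum(x$covariates$label == 0)))
  if (!is.null(x$fibers)) {
    cat(sprintf("  connectomes: %d regions\n",
                length(x$fibers[[1]]$region_names)))
  }
  if (!is.null(x$metabolites)) {
    cat(sprintf("  metabolites: %d features\n", ncol(x$metabolites) - 1L))
  }
  invisible(x)
}

#' Assemble a feature table from a synthetic cohort
#'
#' Joins the requested data blocks into one analysis-ready feature table:
#' covariates plus metabolite abundances and/or flattened connectome nodal
#' metrics (see [connectome_features()]).
#'
#' @param cohort A `synthetic_cohort`.
#' @param blocks Any of `"brain"`, `"metabolite"`.
#' @param metrics Nodal metrics for the brain block, passed to
#'   [connectome_features()].
#' @return A feature table (tibble): `subject_id`, `label`, `age`, `sex`,
#'   `diet`, then feature columns.
#' @export
cohort_features <- function(cohort, blocks = c("brain", "metabolite"),
                            metrics = c("NodeBWCent", "AvPathLength")) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  blocks <- match.arg(blocks, several.ok = TRUE)
  out <- cohort$covariates
  if ("brain" %in% blocks) {
    if (is.null(cohort$fibers)) abort("Cohort was generated without the brain block.")
    out <- left_join(out, connectome_features(cohort$fibers, metrics = metrics),
                     by = "subject_id")
  }
  if ("metabolite" %in% blocks) {
    if (is.null(cohort$metabolites)) abort("Cohort was generated without the metabolite block.")
    out <- left_join(out, cohort$metabolites, by = "subject_id")
  }
  out
}
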