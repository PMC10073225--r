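#' Specify a synthetic brain-gut cohort
#'
#' Defines the study design the generator emulates: a two-group
#' (overweight vs obese) cohort with per-subject structural connectomes
#' (streamline-count matrices plus region volumes) and a fecal-metabolite
#' abundance table, with group-discriminative signal planted in a chosen
#' set of brain regions and metabolites.
#'
#' Defaults mirror the study design this package models: 64 obese and 53
#' overweight subjects, 165 brain regions from a whole-brain parcellation,
#' 987 stool metabolites, and covariate distributions (age, sex, habitual
#' diet) matching the cohort's clinical table. Effect sizes are planted as:
#'
#' * `brain_effect`: a multiplicative factor applied, in the obese group, to
#'   every fiber count incident to an informative region (1 = no signal).
#'   Signal is injected in fiber-count space, upstream of network metrics,
#'   so the whole connectome-feature path is exercised on signal-bearing
#'   inputs.
#' * `metabolite_effect`: a standardized mean difference (Cohen's d) on
#'   log-abundance between groups for each informative metabolite
#'   (0 = no signal).
#'
#' @param n_obese,n_overweight Group sizes (label 1 = obese, 0 = overweight).
#' @param n_regions Number of brain regions per connectome.
#' @param n_metabolites Number of metabolite features.
#' @param informative_regions Integer indices of regions carrying planted
#'   connectome signal.
#' @param informative_metabolites Integer indices of metabolites carrying
#'   planted abundance signal.
#' @param brain_effect Multiplicative edge-scaling factor (>= 0) applied to
#'   the obese group's informative-region edges.
#' @param metabolite_effect Cohen's d (>= 0) on log-abundance.
#' @param covariate_model List with per-group covariate distributions; see
#'   [default_covariate_model()].
#' @param seed Integer seed; identical seeds reproduce the cohort exactly.
#' @return A `cohort_spec` object.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_obese = 64,
                        n_overweight = 53,
                        n_regions = 165,
                        n_metabolites = 987,
                        informative_regions = seq_len(min(10, n_regions)),
                        informative_metabolites = seq_len(min(10, n_metabolites)),
                        brain_effect = 1.05,
                        metabolite_effect = 1.5,
                        covariate_model = default_covariate_model(),
                        seed = 1L) {
  spec <- structure(
    list(
      n_obese = as.integer(n_obese),
      n_overweight = as.integer(n_overweight),
      n_regions = as.integer(n_regions),
      n_metabolites = as.integer(n_metabolites),
      informative_regions = as.integer(informative_regions),
      informative_metabolites = as.integer(informative_metabolites),
      brain_effect = as.numeric(brain_effect),
      metabolite_effect = as.numeric(metabolite_effect),
      covariate_model = covariate_model,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
}

#' Default covariate distributions for the synthetic cohort
#'
#' Group-wise probabilities of male sex and American-style diet and group-wise
#' age mean/sd, taken from the modeled cohort's clinical table (sex 19 male /
#' 34 female overweight vs 17/47 obese; diet 12 American / 41 other vs 29/35;
#' ages 31.45 (10.96) vs 33.20 (10.25) years).
#'
#' @return A list with elements `overweight` and `obese`, each holding
#'   `p_male`, `p_american`, `age_mean`, `age_sd`.
#' @export
default_covariate_model <- function() {
  list(
    overweight = list(p_male = 19 / 53, p_american = 12 / 53,
                      age_mean = 31.4528, age_sd = 10.964),
    obese = list(p_male = 17 / 64, p_american = 29 / 64,
                 age_mean = 33.203125, age_sd = 10.2457)
  )
}

validate_cohort_spec <- function(spec) {
  counts <- c(spec$n_obese, spec$n_overweight, spec$n_regions, spec$n_metabolites)
  if (any(counts < 1)) abort("All cohort counts must be >= 1.")
  if (spec$brain_effect < 0 || spec$metabolite_effect < 0) {
    abort("Effect parameters must be >= 0.")
  }
  if (length(spec$informative_regions) > 0 &&
      (min(spec$informative_regions) < 1 ||
       max(spec$informative_regions) > spec$n_regions)) {
    abort("informative_regions indices out of range [1, n_regions].")
  }
  if (length(spec$informative_metabolites) > 0 &&
      (min(spec$informative_metabolites) < 1 ||
       max(spec$informative_metabolites) > spec$n_metabolites)) {
    abort("informative_metabolites indices out of range [1, n_metabolites].")
  }
  for (grp in c("overweight", "obese")) {
    cm <- spec$covariate_model[[grp]]
    if (is.null(cm)) abort(paste0("covariate_model lacks group '", grp, "'."))
    probs <- c(cm$p_male, cm$p_american)
    if (any(probs < 0 | probs > 1)) abort("Covariate probabilities must lie in [0, 1].")
    if (cm$age_sd <= 0) abort("Age sd must be positive.")
  }
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  subjects: %d obese + %d overweight = %d\n",
              x$n_obese, x$n_overweight, x$n_obese + x$n_overweight))
  cat(sprintf("  regions: %d (%d informative, brain_effect = %.3g)\n",
              x$n_regions, length(x$informative_regions), x$brain_effect))
  cat(sprintf("  metabolites: %d (%d informative, d = %.3g)\n",
              x$n_metabolites, length(x$informative_metabolites),
              x$metabolite_effect))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
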