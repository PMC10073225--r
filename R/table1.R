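#' Two-group comparison of one clinical variable
#'
#' Student's pooled-variance two-sample t-test comparing overweight (label 0)
#' against obese (label 1) subjects, with the difference taken as overweight
#' minus obese. Binary variables are coded 0/1 on a stated reference level
#' (male = 1 for sex, American = 1 for diet) and compared on the coded means,
#' which also reproduces the chi-square-free t-on-proportions convention.
#' Degrees of freedom are n0 + n1 - 2. Welch's unequal-variance variant is
#' available behind a flag.
#'
#' @param values Numeric vector (binary variables already coded 0/1), one per
#'   subject.
#' @param labels Group labels (0 = overweight, 1 = obese).
#' @param variable Name carried into the output row.
#' @param welch Use Welch's t instead of the pooled-variance Student's t.
#' @return A one-row tibble: `variable`, group means and sds, `t`, `df`,
#'   `p_value`.
#' @export
group_comparison <- function(values, labels, variable = "variable", welch = FALSE) {
  labels <- check_labels(labels)
  if (length(values) != length(labels)) abort("values and labels lengths differ.")
  x0 <- values[labels == 0]   # overweight
  x1 <- values[labels == 1]   # obese
  if (length(x0) < 2 || length(x1) < 2) abort("Each group needs at least 2 subjects.")
  if (sd(x0) == 0 && sd(x1) == 0) abort("Zero pooled variance: variable is constant in both groups.")
  tt <- stats::t.test(x0, x1, var.equal = !welch)
  tibble(
    variable = variable,
    mean_overweight = mean(x0), sd_overweight = sd(x0),
    mean_obese = mean(x1), sd_obese = sd(x1),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = unname(tt$p.value)
  )
}

#' Cohort descriptive table
#'
#' Group-wise summaries and two-sample t statistics for the standard clinical
#' variables of a cohort covariate table: age (years), sex (male = 1) and
#' diet (American = 1), plus BMI when a `bmi` column is present. Binary
#' variables are summarized both as level counts and as coded means.
#'
#' @param covariates Tibble with `label` plus `age`, `sex`, `diet` (and
#'   optionally `bmi`) columns; sex/diet may be 0/1 or factors whose first
#'   level after coding is the reference.
#' @param welch Use Welch's t throughout.
#' @return A `cohort_table`: tibble with one row per variable (the
#'   [group_comparison()] columns plus level counts for binary variables).
#' @export
cohort_table <- function(covariates, welch = FALSE) {
  labels <- check_labels(covariates$label)
  code_binary <- function(v, one_level) {
    if (is.numeric(v)) return(v)
    as.integer(as.character(v) == one_level)
  }
  rows <- list()
  if ("diet" %in% names(covariates)) {
    d <- code_binary(covariates$diet, "American")
    rows$diet <- group_comparison(d, labels, "diet (American = 1)", welch) %>%
      mutate(counts_overweight = binary_counts(d[labels == 0], c("American", "Other")),
             counts_obese = binary_counts(d[labels == 1], c("American", "Other")))
  }
  if ("sex" %in% names(covariates)) {
    s <- code_binary(covariates$sex, "Male")
    rows$sex <- group_comparison(s, labels, "sex (male = 1)", welch) %>%
      mutate(counts_overweight = binary_counts(s[labels == 0], c("Male", "Female")),
             counts_obese = binary_counts(s[labels == 1], c("Male", "Female")))
  }
  if ("age" %in% names(covariates)) {
    rows$age <- group_comparison(covariates$age, labels, "age (years)", welch)
  }
  if ("bmi" %in% names(covariates)) {
    rows$bmi <- group_comparison(covariates$bmi, labels, "BMI (kg/m2)", welch)
  }
  out <- bind_rows(rows)
  class(out) <- c("cohort_table", class(out))
  out
}

binary_counts <- function(coded, level_names) {
  paste0(level_names[1], ": ", sum(coded == 1), ", ",
         level_names[2], ": ", sum(coded == 0))
}

#' Two-group t statistic from printed binary compositions
#'
#' Reconstructs the 0/1-coded samples from level counts (e.g. a published
#' table's "Male: 19, Female: 34" per group) and runs [group_comparison()].
#' Useful for checking a printed table's t statistics from its own counts.
#'
#' @param n1_overweight,n0_overweight Counts of the reference (coded 1) and
#'   other (coded 0) level in the overweight group.
#' @param n1_obese,n0_obese Same for the obese group.
#' @param variable Name carried into the output.
#' @param welch Use Welch's t.
#' @return A one-row tibble as in [group_comparison()].
#' @export
group_comparison_from_counts <- function(n1_overweight, n0_overweight,
                                         n1_obese, n0_obese,
                                         variable = "variable", welch = FALSE) {
  values <- c(rep(1, n1_overweight), rep(0, n0_overweight),
              rep(1, n1_obese), rep(0, n0_obese))
  labels <- c(rep(0, n1_overweight + n0_overweight),
              rep(1, n1_obese + n0_obese))
  group_comparison(values, labels, variable, welch)
}
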