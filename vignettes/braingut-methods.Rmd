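---
title: "Methods: brain-gut classification of obesity vs overweight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-gut classification of obesity vs overweight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(braingut)
```

## The problem

Obese (BMI > 30) and overweight (25 &le; BMI < 30) individuals are usually
treated as points on one continuum, yet the two phenotypes may differ
qualitatively in both brain microstructure and gut chemistry. `braingut`
implements a discriminative analysis of that distinction for a two-group
cohort of 117 adults (64 obese, 53 overweight): per-subject structural brain
networks derived from diffusion tractography are reduced to nodal graph
metrics, combined with a stool metabolite abundance table, pushed through
SVM-based recursive feature elimination with cross-validated subset-size
selection and fold voting, and the final linear classifiers are evaluated by
leave-one-out cross-validation, merged into a combined brain + metabolite
model, and stress-tested with a label-permutation null.

Because no subject-level data are distributed with this package, a
synthetic-cohort generator with planted, configurable group effects stands in
for the study data. It is first-class, tested code: every downstream stage is
exercised on cohorts whose ground truth is known.

## Connectome weighting and nodal metrics

Each subject contributes a symmetric matrix of streamline counts
$c_{ij}$ between $R$ parcellated regions and a vector of region volumes
$v_i$ (mm^3^). Connection weights normalize fiber counts by the volumes of
the two interconnected regions:

$$w_{ij} = \frac{c_{ij}}{v_i + v_j}.$$

Dividing by the *sum* of the two volumes is the prevailing volume-correction
convention for streamline counts; the statement "divided by the individual
volumes of the two interconnected regions" is also compatible with a product
or mean convention, so both remain selectable
(`build_weighted_network(volume_convention =)`), but the sum is the default
and is what every shipped analysis uses.

Four weighted nodal metrics are available, named by the
`<MetricTag>__<region>` scheme used throughout the outputs:

* **Strength** (`Strength__*`): $s_i = \sum_j w_{ij}$.
* **Betweenness centrality** (`NodeBWCent__*`): the fraction of shortest
  paths between other region pairs passing through region $i$, with
  fractional splitting over tied paths, normalized by $(R-1)(R-2)/2$.
* **Eigenvector centrality** (`EigCent__*`): the dominant eigenvector of
  $W$, nonnegative, Euclidean norm 1.
* **Average path length** (`AvPathLength__*`): the mean shortest-path
  distance from region $i$ to every other *reachable* region.

Shortest paths use the edge distance $d_{ij} = 1/w_{ij}$ — a stronger
connection is a shorter distance; a zero weight is no edge. The distance
transform, the betweenness normalization, and the per-node definition of
average path length are all package choices (none is forced by a published
formula); each is recorded here and enforced by tests against an exhaustive
path-enumeration oracle on small random networks. Numerical policy for
degenerate inputs: average path length excludes unreachable pairs from the
mean and reports an isolated region as `NA` rather than zero; eigenvector
centrality refuses disconnected networks outright (naming the component
sizes) instead of guessing a per-component convention, and is computed by
power iteration to tolerance $10^{-10}$ with a bounded iteration budget.

The default feature block uses betweenness and average path length only —
the two metric families that the final brain models draw on — giving
$2 \times 165 = 330$ columns at the default parcellation. All four metrics
can be selected, but note that no combination of $\{2,3,4\}$ metrics over
165 regions reproduces a brain feature space of exactly 2156 variables; the
package makes no attempt to match that count.

## Feature selection

Selection is classical SVM-RFE: train a linear SVM (cost $C = 1$ by
default) on the surviving features, drop those with the smallest $|w|$,
refit, repeat. Three choices deserve comment:

* **Elimination criterion** is smallest *absolute* weight. Eliminating by
  signed weight would discard the strongest negatively-associated
  predictors, which contradicts the role negative-weight features play in
  the final models.
* **Elimination step** defaults to one feature per round (classical RFE);
  `rfe_config(step =)` accepts a count or a fraction of the remaining
  features per round. The shipped analyses use `step = 0.1` at the
  200–500-feature scale and `step = 1` on small problems.
* **Standardization**: features are z-scored on the training portion inside
  every fit. Linear-SVM weights are scale-sensitive; without this the
  elimination order just mirrors the units of each column.

**Optimal subset size.** For each candidate $k$ in a grid, every subject is
held out in turn; elimination runs on the remaining $n-1$ subjects only, an
SVM is trained on that split's top-$k$ features, and the held-out subject is
predicted. The curve value at $k$ is the mean held-out accuracy, and the
optimal $k$ attains its maximum (ties toward smaller $k$). Within a split, a
single elimination path serves every $k$ at once — stepwise elimination is
nested, so the top-$k$ of a full path equals RFE run to $k$ directly. The
default grid is geometric with extra density at small $k$ (~15 candidates);
`k_grid = "full"` gives the exact 1..p grid where affordable. An alternative
mode (`refit = "once"`) ranks features once on all subjects and only refits
the per-$k$ classifiers inside splits; it is not the default because it lets
the ranking see every subject.

**Vote aggregation.** With the optimal $k$ fixed, subjects are split into
ten label-stratified folds; elimination to $k$ runs on each fold's training
portion and every surviving feature earns a vote. The final subset is the
top $k$ by votes. Vote ties at the boundary are broken by the larger mean
$|w|$ across the folds that selected the feature, then lexicographically —
the tally invariant (total votes $= 10k$) and this tie policy are tested.

## Final models and evaluation

The selected features plus covariates — age and sex always, habitual diet
whenever metabolite features are present — form the design. Three linear
families are fit: a linear SVM, a ridge classifier (penalized least squares
on $\pm 1$-coded labels, decision by the sign of the linear score,
$\lambda = 1$), and logistic regression (falling back to a lightly
ridge-penalized fit, with a warning, under separation or $p > n$). Using
three families guards against a result that is an artifact of one
estimator; a test asserts they agree within 0.05 accuracy on strongly
separable cohorts.

Evaluation is leave-one-out: the model (including standardization
statistics) is refit on $n-1$ subjects and the held-out subject predicted;
the $n$ predictions aggregate into a confusion matrix (class 1 = obese
positive), accuracy, per-class precision $TP/(TP+FP)$ and recall
$TP/(TP+FN)$ (a $0/0$ is flagged undefined, never reported as zero), and an
ROC over the held-out decision scores (SVM margin, ridge linear score,
logistic probability; threshold sweep with ties grouped, trapezoidal AUC).

**A deliberate caveat, annotated in every report:** the default protocol
selects features once on *all* subjects and then LOO-evaluates the final
model, inheriting the selection step's view of every subject. That mirrors
the study protocol this package reimplements, but it is optimistically
biased. `loo_evaluate(nested = TRUE, selector = )` refits the selection
inside every training fold and is the honest generalization estimate; the
package's own null-calibration tests use the nested mode, because an
optimism-free pipeline is the only instrument that should score at chance
on effect-free cohorts.

## Combined model and permutation null

The combined model merges, from the final brain and metabolite models, the
features whose $|w|$ (standardized scale; covariates excluded) ranks in the
top 90% of their block, with $\lceil 0.9 \, p_{block} \rceil$ kept and ties
at the cut kept together and flagged. No single rounding rule reproduces a
83 &rarr; 76 and 57 &rarr; 50 reduction simultaneously
($\lceil 0.9 \times 83 \rceil = 75$, $\lceil 0.9 \times 57 \rceil = 52$), so
`merge_top_fraction(count_override = )` accepts exact per-block counts and
the merged object records which rule produced it. The merged set is used
directly — selection is not rerun on it.

The permutation test shuffles labels uniformly, retrains the final model on
its selected features and re-scores it by stratified ten-fold CV
(folds re-drawn per replicate), and repeats $R = 199$ times by default
(reduced in the shipped analyses where stated). This generalizes a
single-shuffle check into an empirical null with
$p = (1 + \#\{A_{perm} \ge A_{obs}\})/(R+1)$.

## The synthetic cohort: what it emulates, what it does not

The generator draws, under one seed (bit-identical reproduction is tested):

* **Connectomes** — a shared random template (45% of region pairs connected,
  gamma-distributed intensities, log-normal region volumes) with independent
  Poisson draws per subject; in the obese group, all counts incident to the
  informative regions are scaled by `brain_effect` and re-rounded. Signal is
  injected in fiber-count space — upstream of weighting and graph metrics —
  so the entire connectome path is exercised on signal-bearing inputs.
* **Metabolites** — Gaussian log-abundances with feature-specific mean and
  sd; informative features shift the obese mean by `metabolite_effect`
  standard deviations (Cohen's d). Reported abundances are exponentials,
  hence positive and right-skewed like real intensity data.
* **Covariates** — sex, diet and age from group-wise distributions matching
  the modeled cohort's clinical table (sex 19M/34F vs 17M/47F; diet 12/41 vs
  29/35 American/other; ages 31.45 (10.96) vs 33.20 (10.25)). The printed
  table's own age row (28.0 / 31.0) is inconsistent with these means and
  with its own t statistic, so the text's values are used. Note the
  covariates carry genuine weak group signal (the diet difference alone has
  $|t| \approx 2.6$), so a cohort with all *planted* effects nulled is not a
  complete null; calibration tests that require a complete null equalize
  the covariate model explicitly.

Defaults are the modeled study's dimensions: 64/53 subjects, 165 regions,
987 metabolites (reduced to 200 in the shipped demo analyses), 10
informative regions and 10 informative metabolites. Where no effect sizes
are documented anywhere, the package fixes `metabolite_effect = 1.5` — a
per-feature shift large enough that a linear model on $n = 117$ can find it
among hundreds of noise features, small enough that single features do not
separate the groups — and `brain_effect = 1.05`, i.e. a 5% fiber-count
scaling, reflecting that microstructural group differences are subtle while
propagating through every nodal metric of the affected regions.

What the generator does *not* model: tractography error structure, spatial
correlation between neighboring regions, metabolite-metabolite correlation
(pathway structure), batch effects, or any BMI value (groups exist only as
labels). Passing tests therefore demonstrate that the pipeline recovers
planted linear signal at realistic dimensions and is honest under the null
— not that the specific published feature lists or accuracies would
replicate on resampled human data.

## Problem sizes used by the shipped analyses

The package's own test suite and the acceptance script run, as the
package's chosen desk-scale configurations: the full 165-region connectome
with 200 metabolites and a ~15-point subset-size grid for the end-to-end
demo (10% elimination steps, permutation $R = 49$); 500 metabolites for the
planted-recovery study (25 cohorts); 25–40 nested-LOO cohorts at 30
metabolites for null calibration and effect-size monotonicity; and 100
cohorts at reduced $R = 19$ for permutation-p uniformity. The full
987-metabolite space and the exact 1..p grid are supported but not exercised
by default.

## Known limitations

* The default evaluation inherits the non-nested selection protocol
  described above; treat its accuracies as in-protocol scores, not
  generalization estimates, and use `nested = TRUE` for the latter.
* Eigenvector centrality requires a connected network by design; brain
  networks at this density are connected in practice, but fragmented inputs
  must be handled by the caller.
* The ridge and logistic families are sensitive to the heavy right skew of
  raw abundance scales; the SVM is the reference family, and comparisons
  across families are cleanest on log-abundances.
* Betweenness ties are split fractionally; with continuous weights exact
  ties are measure-zero, but integer-ratio weights (as in the tests) do
  produce them and the tie handling is oracle-checked.
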