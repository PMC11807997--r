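---
title: "Methods: staged-cohort urine metabolomics with metaboStage"
author: "metaboStage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged-cohort urine metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboStage)
```

# Scope and data model

metaboStage analyses untargeted LC–MS urine metabolomics of a cohort
staged into three diagnostic groups — cognitively normal (CN), mild
cognitive impairment (MCI) and Alzheimer's disease (AD) — compared
pairwise in disease order (CN–MCI, CN–AD, MCI–AD; the later stage is
always the *case* group). The pipeline starts from identified
feature-by-sample intensity tables, one per electrospray ion mode;
peak alignment, spectral identification and wet-lab processing are out
of scope. Each table is held in a `MetaboSet`, a thin
`SummarizedExperiment` with a single raw-intensity assay in which `NA`
marks a missing measurement, pooled-QC replicate columns flagged in
`colData`, and the ion mode in `metadata()`. The two modes are treated
as fully independent until the differential screen merges their calls.

# Preprocessing

**QC CV filter.** A feature's technical reliability is measured by the
coefficient of variation of its pooled-QC replicate intensities,
CV = s/x̄ with the sample (n−1) standard deviation, computed on raw
(untransformed) intensities — CV is conventionally a raw-scale
quantity. Features are removed when CV is *strictly* greater than 0.30
("over 30 %"), so a feature at exactly the threshold is retained.
Features whose CV is undefined (QC mean zero, or fewer than two
observed QC values) are excluded conservatively with `cv = NA`.
Filtering precedes imputation because the CV must be computed on
observed QC values only; imputing first would let the imputer
manufacture the QC variability it is judged by.

**Group-wise KNN imputation.** Missing cells are imputed within each
diagnostic group independently; the neighbour count is tied to the
group, k = max(1, round(0.10 · group size)) with half-up rounding (k
must be a positive integer). Restricting the neighbour pool to the
group prevents imputed values from leaking between-group differences
into the screen. Distance between two samples is the Euclidean distance
over features observed in both, scaled by the number of shared observed
features (so sparsity does not shrink distances); ties are broken by
sample-id lexicographic order for determinism. The imputed value is the
unweighted mean of the k nearest neighbours' observed values for that
feature; neighbours lacking the feature are skipped in favour of the
next nearest. Observed cells are never altered, and a feature missing
in an entire group is an error rather than a guess.

# Latent-variable models

Feature matrices are log10-transformed (offset 1e-9) and autoscaled
(mean 0, unit sample sd per feature) by default — the standard choice
for untargeted LC–MS, where intensities span decades; scaling is
configurable and constant features are flagged and given scale 1.

**PLS-DA** uses NIPALS with deflation of both blocks against the
centered one-hot class-membership matrix, giving unit-norm weights and
cumulative R²X/R²Y. It serves as the all-sample overview ordination.

**OPLS-DA** handles one pairwise comparison at a time with the response
encoded as the centered 0/1 indicator. The predictive weight is
w = X′y/(y′y), normalised; for each orthogonal component the X-loading
of the current predictive score is stripped of its projection on w,
normalised to w_o, and the component t_o p_o′ is deflated from X; the
predictive component is then extracted from the filtered matrix. With
zero orthogonal components this reduces exactly to the first PLS
component (a tested identity). The predictive score sign is chosen so
the case group has positive mean — plots are reproducible and "up in
AD" reads naturally. One orthogonal component is the default: at these
sample sizes it is the parsimonious choice, and the component count is
a configuration knob rather than an automatic search.

**VIP** is computed on the single predictive component,
VIP_j = √p · |w_j| / ‖w‖, honouring the screen's "first component"
reading; it satisfies mean(VIP²) = 1 exactly, which the test-suite
asserts on every fit.

**Q²** comes from stratified 7-fold cross-validation in which both the
scaling parameters and the model are refit inside each training fold —
refitting the scaling inside the fold is what keeps Q² honest.
Q² = 1 − PRESS/SS of the centered response over held-out predictions;
values at or below zero mean no predictive value.

**Permutation validation** refits the full model — including Q², with
the same number of orthogonal components, a like-for-like null — under
200 uniformly random label permutations and reports
p = (1 + #{null ≥ observed})/(n_perm + 1), so p is bounded below by
1/201 and attains that bound exactly when no permutation matches the
observed fit.

# Differential screen

A feature is called up-regulated iff VIP > 1 **and** two-sided Wilcoxon
rank-sum p < 0.05 **and** FC > 1.25; down-regulated with FC < 0.8. All
thresholds are strict inequalities (a literal reading of "VIP > 1",
"p < 0.05", "FC < 0.8 or FC > 1.25"), and the three criteria are
conjunctive — relaxing any one can only add calls, a tested
monotonicity. Fold change is the ratio of arithmetic means of raw
intensities, case over reference, using imputed values where the
original cell was missing; an undefined ratio (reference mean zero)
flags the record and forces `ns`. The Wilcoxon p uses exact enumeration
when both groups have at most eight values and no ties, otherwise the
normal approximation with tie and continuity corrections. No
multiple-testing correction enters the call — the screen mirrors its
stated raw-p criterion — but a BH-adjusted column is emitted for
information. Volcano coordinates (log2 FC, −log10 p) and top-15
up/down lists by |log2 FC| accompany each comparison.

# Pathway enrichment

Over-representation uses the hypergeometric upper tail with the
background universe defined as the annotated, QC-passing features —
the standard ORA choice; using all features would dilute N with
untestable ids. Differential sets from both ion modes are merged first,
since pathway identity is mode-agnostic. Pathways with zero overlap
report p = 1; BH adjustment is reported alongside raw p without
changing the headline sort.

# Key panel and staging model

A CART classification tree (Gini impurity, depth ≤ 5, `cp = 0`,
`minsplit = 10`) is fitted on the autoscaled differential features —
restricted to those annotated to significantly enriched pathways when
an enrichment result is supplied, falling back to all differential
features if the restriction leaves fewer than ten candidates. Features
are ranked by total impurity decrease (including surrogate credit),
with ties broken by smaller univariate p then feature id; if the tree
uses fewer than ten features the panel is padded from the VIP ranking.
Shallow trees give stable importance rankings at n ≈ 100; the depth
bound and split parameters are pipeline choices, configurable.

The staging model is logistic regression on the autoscaled panel with a
weak L2 penalty (λ = 1e-4), fitted by Newton iterations with step
halving. The penalty exists solely so that separable panels — common
with strong biomarkers at these sample sizes — still yield finite,
deterministic coefficients while leaving predicted probabilities
essentially saturated (≥ 0.99 on separated groups, a tested property).

"Combined AUC" is the AUC of the multivariable logistic score over the
full panel, computed by the rank (Mann–Whitney) formula with half
credit for ties; the trapezoidal area under the constructed ROC curve
is checked against the rank formula on every call. The headline ROC is
computed on the modeling data (no held-out set enters it); the honest
generalisation estimate is the 200× stratified resampling validation,
which redraws a 70/30 train/test split per group, refits the model —
scaling included — on the training split, and reports the held-out AUC
and accuracy distributions.

# Cohort statistics

Categorical cohort variables get a Pearson chi-square test of
independence without continuity correction — the convention that
reproduces the published staged-cohort demographic p-values from their
printed counts, which the acceptance suite checks to three decimals. A
low-expected-count flag (< 5) is attached without suppressing the test.
Continuous variables pass a Shapiro–Wilk normality gate (α = 0.05 per
group; all groups must pass); non-normal variables get a Kruskal–Wallis
omnibus test — an extension, since a three-group table needs an omnibus
p even though only the two-sample tests are canonical here — with all
three pairwise Mann–Whitney p-values flagged at the Bonferroni level
0.05/3. Normally distributed multivariate summaries can be compared
with Hotelling's T², intended for low-dimensional inputs (model scores,
selected covariates); the implementation refuses ill-posed dimensions
and singular pooled covariances rather than regularising silently.

# The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions
under which every downstream claim is verified.

* **Design.** Defaults mirror the staged study: 62 CN / 43 MCI / 57 AD
  biological samples, two independent ion-mode tables of 100 features
  with disjoint `neg_`/`pos_` ids, and 20 pooled-QC replicates.
* **Intensities** are log-normal: feature log-means from
  N(log 1e5, 1.5²), within-group biological noise N(0, 0.4²) on the
  natural-log scale. Log-normality is the standard model for
  untargeted LC–MS feature intensities.
* **Planted effects** add log FC to the case group of their comparison
  (defaults: 20 features per comparison at FC 2.0 up / 0.5 down), so
  the ratio of group means equals FC exactly in expectation — verified
  at n = 500 per group within 5 %. The third group stays at baseline,
  which means a planting for one comparison can legitimately shift a
  second comparison sharing its case group (an MCI–AD planting also
  separates CN from AD); recovery tests therefore score false calls on
  pure-noise features only.
* **Technical CV.** Reliable features draw CV ~ U(0.05, 0.20); about
  10 % draw from U(0.40, 0.70) and are recorded as the features the QC
  filter must remove. The unreliable range starts well above the 0.30
  threshold so that a 20-replicate QC estimate identifies them with
  high probability. Planted features always draw from the reliable
  range: otherwise a planting could be removed by the filter and the
  recovery tests would measure the filter, not the screen.
* **QC replicates** are drawn log-normally around each feature's pooled
  biological mean with sdlog chosen so the mean and CV are exact —
  standard pooled-QC practice; zero CV collapses to the mean exactly.
* **Missingness** is MCAR at 2 % plus left-censoring (probability 0.5
  below the 5th global intensity percentile), injected after intensity
  generation; QC columns stay complete, and no feature is left entirely
  missing within a group (the largest value is restored), matching the
  imputer's contract.
* **Pathway map.** One planted-enriched pathway per comparison seeded
  with 8 of that comparison's planted features (pathway size 15), plus
  background pathways drawn uniformly from all features — so background
  pathways carry the honest base rate of planted features and the
  excess in planted pathways is what enrichment must detect.

What the generator does **not** emulate: retention-time structure,
adducts and in-source fragments, batch and injection-order drift,
correlated metabolite modules, covariate-driven confounding, or
longitudinal sampling. Passing the recovery tests therefore shows the
pipeline recovers clean multiplicative group effects under realistic
noise and missingness — not that it is robust to batch effects or
identification errors in real data.

# Numerical choices and degenerate inputs

* Half-up rounding for k (base `round()` is round-half-even).
* Neighbour-distance and importance ties break lexicographically.
* log10 offset 1e-9; constant features flagged, scale forced to 1.
* OPLS orthogonal extraction stops with an error if no orthogonal
  variation remains; requesting components at or beyond rank(X) errors.
* Wilcoxon switches between exact and corrected-normal paths as above;
  identical groups give p = 1.
* All randomised operations (generation, folds, permutations,
  resampling, tree seed) take an explicit seed and restore the caller's
  RNG state; identical seeds give byte-identical outputs end to end.

# Problem sizes in the test-suite

The suite verifies oracle identities at enumerable sizes (Wilcoxon
n ≤ 10, hypergeometric N ≤ 12, AUC n ≤ 12), planted-truth recovery at
the default 62/43/57 design with 200 features, enrichment ranking over
20 generated cohorts, key-panel recovery (10 strong among ~50
differential plantings) over 20 seeds, permutation calibration at 60
null datasets with 50 permutations each, and resampling at 100–200
draws — sizes chosen to make the stochastic assertions stable across
seeds while keeping a full run in the low minutes.

# Known limitations

* The screen's raw-p criterion is anti-conservative by construction;
  the BH column is informational only, mirroring the screened workflow
  it re-implements.
* VIP uses the predictive component only; multi-component VIP variants
  would rank features differently.
* The headline ROC/AUC is resubstitution; rely on the resampling
  distribution for generalisation claims.
* Hotelling's T² requires n₁ + n₂ − 2 > dim and a well-conditioned
  pooled covariance; it is not applicable to the full feature matrix.
* The imputer's scaled-Euclidean distance operates on raw intensities,
  so high-abundance features dominate neighbour choice; with the
  default log-normal spread this is acceptable because neighbours are
  also chosen within groups, but strongly heteroscedastic real data may
  warrant log-scale distances.
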