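---
title: "Methods: discriminant analysis of untargeted metabolomics feature tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminant analysis of untargeted metabolomics feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`hypoxmet` implements the statistical workflow of a two-class untargeted
UPLC-QTOFMS metabolomics comparison at small sample size — the setting of
a discovery study with two groups of five biological samples, each
injected in triplicate, accompanied by solvent blanks. The raw input is
an aligned marker table: one row per detected feature, identified by its
retention time (minutes) and m/z, one column per injection, with zero
meaning "not detected" (aligned tables from peak-alignment software are
zero-filled; a separate missing mask is derivable, never stored). Files
are feature-per-row; in memory, sample-per-row matrices are used, with
one documented transpose at the boundary.

# Preprocessing

Three reductions are applied in a fixed order:

1. **Replicate collapsing** (`collapse_replicates`): the per-sample value
   of a feature is the median of its replicate injections, zeros
   included. Including zeros is the faithful treatment of zero-filled
   tables: a feature detected in only one of three replicates collapses
   to zero. An alternative "median of detected" is deliberately not the
   default.
2. **Blank-feature removal** (`remove_blank_features`): a feature
   detected (intensity > 0, configurable floor) in at least
   `min_blank_detections` (default 1) blank injections is background —
   solvent contaminants, carry-over — and is removed wholesale.
3. **Frequency filtering** (`frequency_filter`): features detected in
   fewer than `min_samples` (default 3) collapsed samples are unreliable
   markers and are removed.

With the default synthetic design this traces 365 → 229 → 112 features
and reduces the missing-value fraction from about a third to about a
seventh. Counts always reconcile
(`n_in − n_blank − n_lowfreq = n_out`).

**Autoscaling** (`autoscale`) mean-centers each column and divides by its
sample (n−1) standard deviation — the n−1 convention matters at n = 10
and matches common chemometrics practice. Zero-variance columns are an
error naming the feature when autoscaling directly; inside
cross-validation folds a constant training column simply contributes
zeros (scaled by 1), since dropping columns per fold would change the
feature space across folds.

# Unsupervised exploration

PCA is computed by singular value decomposition of the autoscaled
matrix — deterministic, rank-safe, and identical to NIPALS-PCA at
convergence. The number of components can be chosen by leave-one-out
cross-validation: scaling is refit without the held-out row, and PRESS is
accumulated element-wise — each coordinate of the held-out row is
predicted from its *other* coordinates through the fold's loadings.
Plain projection PRESS decreases monotonically with the component count
and cannot select a model, which is why the element-wise form is used.
`ncomp_max` defaults to `min(n − 2, 6)`.

Outlier screening uses two statistics per sample: the **Q residual**
(squared Euclidean distance between the autoscaled sample and its
projection onto the model plane) and **Hotelling's T²** (sum of squared
scores, each normalized by its component's score variance). The 95%
control limits are the F-distribution form
`A(n−1)(n+1)/(n(n−A)) · F₀.₉₅(A, n−A)` for T² and the Jackson–Mudholkar
approximation from the residual eigenvalues for Q, with a Box
χ²-moment fallback (logged) when the Jackson–Mudholkar form is unusable.
These limit formulas are standard chemometrics choices; they are
documented as such, not claimed to be the only possibility.

Hierarchical clustering (`ward_hca`) runs Ward's minimum-variance
linkage on Euclidean distances between samples in the PCA score space
(not on raw features), via `stats::hclust(method = "ward.D2")`; merge
heights are non-decreasing and are checked in the test suite against a
brute-force Lance–Williams implementation.

# PLS-DA, dQ² and NMC

Class labels are coded 0 (hypoxia) and 1 (normoxia) and mean-centered;
the feature matrix is autoscaled. PLS1 is fitted by NIPALS with
deflation (`fit_plsda`); for a single response the weight update has an
exact one-pass fixed point, and a convergence guard (tolerance 1e-12,
500 iterations) is kept for form. The model dimensionality is capped at
`lv_max = 3` latent variables to guard against overfitting at n = 10.
The regression vector `b` reproduces the latent-variable predictions
(`ŷ = X b` on the scaled/centered scale) and is the statistic later used
for variable selection.

Two figures of merit summarize cross-validated predictions:

- **dQ²** (discriminant Q²): `1 − Σe²/Σ(y−ȳ)²` where the residual of a
  prediction that overshoots its own class code in the correct
  direction is set to zero. Since classification, not regression, is
  the goal, predicting a class-1 sample at 1.3 is not an error.
  dQ² can never fall below the standard Q² on the same predictions.
- **NMC**: the number of predictions on the wrong side of the midpoint
  between the class codes; a prediction exactly at the midpoint counts
  as misclassified (the conservative tie rule).

Cross-validation folds refit both autoscaling and the response centering
on the training portion only, so no information from the held-out sample
leaks into the transform. Fold predictions are mapped back to the 0/1
label scale by adding the fold's training response mean; the dQ² clipping
codes and the NMC midpoint are then the 0 and 1 labels themselves. This
is equivalent to working with fold-specific centered codes (with a 5/4
split the centered codes are −4/9 and 5/9) and keeps out-of-fold
predictions from unevenly centered folds on one common scale.

# Double cross-validation and the permutation test

Figures of merit quoted for the model come from **leave-one-out double
cross-validation** (`double_cv`): the outer loop holds each sample out in
turn; the inner loop — a second leave-one-out on the remaining nine —
picks the number of latent variables by dQ² (smallest dimensionality at
the maximum, the parsimonious tie rule); the refit model predicts the
held-out sample. The ten out-of-fold predictions give dQ² and NMC, and
the mean of the ten outer-fold regression vectors, `b_mean`, is the
selection statistic.

Statistical significance comes from an **exhaustive non-complementary
permutation test** (`permutation_test`). For balanced 5 vs 5 labels
there are `choose(10,5) = 252` same-size relabelings; a relabeling and
its complement produce mirror-image models with identical figures of
merit, so each complement pair is counted once, and the true labeling is
excluded: 125 permutations. Exhaustive enumeration makes the p-values
deterministic given the data — there is no sampling error in the null.
The whole double-CV procedure is recomputed under every relabeling
(exchangeability: the same functional is applied to real and permuted
labels), giving null distributions of dQ², NMC, and the regression
vector. Empirical p-values are plain fractions of permuted statistics at
least as extreme as the real one (equality included); an add-one
convention is available via `plus_one = TRUE` but is not the default,
since with exhaustive enumeration the plain fraction is itself a valid
and conventional estimate.

**Variable selection**: each feature's p-value is the smaller of its two
one-tailed fractions — how often the null regression coefficient is at
least as large, and at least as small, as the real one — and features
with p below `alpha = 0.025` (2.5% per tail) are selected as
differentiating. Signed per-tail comparison is the default; comparing
absolute values is available (`extremeness = "absolute"`). With 125
permutations the attainable p-values are multiples of 1/125, so the
0.025 threshold means at most three null draws beyond the real
coefficient.

Failed permutations (a fold losing a class — impossible for balanced
5 vs 5, possible in pathological configurations) are dropped with a
warning, never silently imputed.

# Annotation and targeted quantitation

`annotate_features` matches observed feature m/z against candidate
compounds under `[M+H]⁺` (+1.00728 Da), `[M+Na]⁺` (+22.98922 Da) and
configured neutral losses (seeded with the formic-acid loss CH₂O₂,
46.00548 Da, the classic in-source fragment), within a ±5 mDa tolerance.
Shrinking the tolerance can only remove matches.

Targeted MRM quantitation uses unweighted ordinary least squares of peak
area on standard concentration (`fit_calibration`) — whether a weighted
fit would be preferable depends on the standard series' heteroscedasticity
and is out of scope — inverted by `quantify` with an in-range flag
against the standard series' span. Identity confirmation
(`confirm_identity`) applies three criteria jointly: transition
co-occurrence in time (default tolerance ±0.05 min, comfortably above
the ≤0.02 min retention-time spreads of well-behaved MRM assays),
confirmation/quantification abundance ratio within ±25% of a comparable
standard, and signal-to-noise strictly above 9 for both transitions.
SNR is an input, not computed from raw traces. `tissue_concentration`
converts extract concentrations to nmol per mg tissue for homogenates
prepared at a fixed tissue density (default 33.3 mg/mL).

# The synthetic-data generator

`generate_dataset` emulates the full study design so that every stage of
the pipeline can be exercised with known ground truth:

- **Layout**: 5 + 5 biological samples × 3 replicate injections + 7
  blanks = 37 injections; 365 features partitioned into 136 blank-borne,
  117 low-frequency, and 112 reliable features, of which 8 carry the
  planted class effect. The partition is enforced structurally, so
  preprocessing always reproduces 365 → 229 → 112 exactly
  (`study_shape_fixture` is the default configuration under a fixed
  seed).
- **Abundances and noise**: feature base abundances are log-normal;
  between-sample biological variation is multiplicative log-normal with
  20% CV (a physiologically homogeneous cohort); between-replicate
  variation is 14% CV, matching the internal-standard stability the
  design assumes.
- **Class effect**: the 8 planted markers change by ±2 log₂ units
  (4-fold), two elevated under hypoxia (the CDP-choline ions at m/z
  489.1157 and 511.0977) and six under normoxia. The remaining reliable
  features receive a weak random-signed effect (SD 0.3 log₂ units),
  emulating the pervasive, sub-threshold metabolome-wide response that
  accompanies a profound physiological insult — real metabolomic data
  are highly collinear, and a design with 104 strictly null independent
  features would understate the multivariate class separation real
  studies of extreme exposures show. The pervasive effect is applied
  only when `n_discriminant > 0`: a no-discriminant configuration is an
  exactly label-exchangeable null, which the calibration tests rely on.
- **Missingness**: detection is a logistic function of log base
  abundance — a limit-of-detection mechanism — with low-frequency
  features placed at the low-abundance end; dropout therefore decreases
  monotonically with abundance. Blank-borne background contamination is
  present in nearly all injections, which is what makes the overall
  missing fraction fall from roughly 33% before filtering to roughly
  14% after.
- **Instrument channel**: an internal-standard channel with 14% area RSD
  and per-injection measured m/z within ±10 ppm of 609.2812; feature
  m/z values are jittered within ±10 ppm of their true mass (the 8
  planted markers keep their canonical observed m/z so that annotation
  examples are addressable).

What the generator does **not** emulate: retention-time drift and
alignment errors, correlated blank contamination patterns, heteroscedastic
detector saturation, class-dependent missingness, and genuine biological
covariance between named metabolites beyond the planted/pervasive effect
structure. Passing parameter-recovery tests on this generator shows the
pipeline's statistics behave as designed under the assumed data model;
it does not certify performance on real data that violate these
assumptions.

Under the default configuration, across 20 seeds, double cross-validation
yields dQ² around 0.6–0.85 with zero misclassifications, the permutation
p-value of dQ² is below 0.01, and the median number of planted markers
recovered by the selection rule is 8 of 8 — the test suite and the
acceptance script recompute all of these.

# Numerical choices and problem sizes

- NIPALS: weight-change tolerance 1e-12, max 500 iterations; deflation
  stops early when `‖Xᵀy‖ < 1e-14` (rank exhausted), and regression
  vectors for higher dimensionalities then repeat the last extractable
  one.
- Ties: LV selection takes the smallest dimensionality within 1e-12 of
  the maximal dQ²; Ward merges are delegated to `stats::hclust`, whose
  tie-breaking is deterministic given input order.
- Degenerate inputs: single-class responses, zero-variance columns,
  missing blank injections, and rank-deficient calibrations raise
  errors naming the offender; they are never silently repaired.
- Test-suite problem sizes: oracle comparisons use random 10×20 to
  12×30 matrices; the null-calibration property runs 200 generated null
  datasets at a reduced 60-feature configuration (the procedure under
  test is identical; only the matrix is smaller); the full-design
  checks run the complete 125-permutation double-CV analysis on 10×112
  matrices over 20 seeds.

# Known limitations

- The permutation count is driven by the class sizes; below 4 + 4 the
  null is too coarse for a 0.025 per-tail threshold to be meaningful.
- Empirical p-values without the add-one correction can be exactly zero;
  they should be read as "smaller than 1/125", not as literal zeros.
- The PCA component-selection criterion and the Q/T² limit formulas are
  reasonable standard choices among several in use; other chemometrics
  software may select differently near ties.
- Double cross-validation at n = 10 has high variance; the figures of
  merit are honest for the sample at hand but generalization claims
  require external validation, which no resampling scheme replaces.
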