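---
title: "Methods: cross-correlation features and irritancy classification for EEM fingerprints"
author: "eemscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-correlation features and irritancy classification for EEM fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eemscreen)
```

# The problem and the data model

A cell-based fluorescence irritancy assay records, per chemical compound,
two excitation–emission matrices (EEMs): intensity as a function of emission
wavelength (rows) and excitation wavelength (columns). One image is measured
with growing human keratinocytes, one without cells (control). The
biological premise is that cells respond to an irritant and a mixture of
five environment-sensitive dyes transduces that response into a changed
fluorescence landscape; the control image carries the compound's own
photophysics but no cellular response. The statistical task is binary
classification — irritant (IRR, the positive class) versus non-irritant
(Non-IRR) — in three input configurations: control image only (task 1),
with-cells image only (task 2), both concatenated (task 3).

`eemscreen` stores a dataset as an `EEMSet`, a `SummarizedExperiment` with
assays `control` and `cells` whose rows are pixels, flattened row-major with
rows = emission (the single orientation used in vectorization, masks and the
on-disk text format). At instrument resolution the grids are 511 points per
axis over excitation 74–691 nm and emission 227–724 nm (the printed lower
excitation bound is kept as-is; all dye signal lies far inside the grid, so
it only affects empty background), giving input dimensions
511 × 511 = 261,121 (tasks 1–2) and 522,242 (task 3).

# Feature extraction

With at most a few dozen samples against >10^5 pixels, classification works
in a learned feature space built in three steps.

**Cross-correlation embedding.** Each task vector is standardized:
centered and scaled to unit Euclidean norm. The dot product of two
standardized vectors is their Pearson correlation, and
`‖x̃ − ỹ‖² = 2 − 2r`, so representing each image by its correlations with
the n training images is affinely equivalent to representing it by squared
Euclidean distances — `correlationDistanceCheck()` verifies the identity
numerically, and the test suite checks that PCA scores computed from either
embedding coincide up to component sign. Correlation is invariant to
per-image gain and offset, which absorbs lamp intensity and exposure
differences by construction. For task 3 the concatenated vector is
standardized as a whole, preserving the printed input dimension and the
relative scaling of the two images.

**PCA in correlation space.** The n × n training correlation matrix is
column-standardized (zero mean, unit variance per column, variance
denominator n − 1) and eigen-decomposed. Standardizing makes the eigenvalue
sum equal n, so the Kaiser threshold of 1 is exactly the average eigenvalue
of a correlation matrix. Whether the original analysis standardized these
columns is implied by that reading of the Kaiser rule but not stated; both
interpretations were open, and the standardized form is the package's
default and only mode because it is the one under which the rule's stated
rationale is exact.

**Component retention.** Three rules are implemented. `kaiser`: count of
eigenvalues strictly greater than 1. `broken_stick`: eigenvalue proportions
`p_k` are compared with the expected sorted piece lengths of a randomly
broken unit stick, `b_k = (1/n) Σ_{i=k..n} 1/i`, and the retained count is
the maximal *leading* run with `p_k > b_k` — the standard reading of
"exceed", stopping at the first failure. Both comparisons use strict
inequality, so ties reject a component (the conservative choice; the source
does not specify). The raw rules may return 0; `fitExtractor()` floors
retention at one component so the feature space is never empty. `fixed(m)`
(default m = 5) mirrors the published choice of five components and is the
default for all evaluation protocols. Loading signs are fixed by making each
loading's largest-magnitude entry positive, so scores are reproducible
across platforms.

**Masks.** After fitting, the map from a standardized test vector to each
retained feature is linear: `feature_j(x) = ⟨x̃, mask_j⟩ + offset_j`, where
the mask folds the reference vectors, column statistics and loading into one
image (two stacked images for task 3). `computeMasks()`/`applyMasks()`
implement this route and the tests require agreement with `extractFeatures()`
to below 1e-8; masks are exportable as ordinary EEM matrix files for visual
inspection.

Degenerate inputs are errors, not silent fixes: constant images (correlation
undefined), fewer than 3 training samples, a single-class training set, and
constant correlation-matrix columns all stop with a message.

# Classifiers

All families share one contract: `fitClassifier(method, X, y)` and
`predictLabels(model, X)` returning a label and a score with "larger = more
irritant-like". Vote and posterior ties resolve to IRR — fail-safe toward
flagging toxicity. Registry names follow the report tables: DT, GM, 3NN,
KNN, LDA, LR, NB, PDFE.

- **Fisher / LDA.** `w ∝ S_pooled⁻¹(μ_IRR − μ_NonIRR)`, unit-normalized.
  No normality assumption is made for the threshold; it is chosen by
  exhaustive scan over midpoints of consecutive sorted training projections
  (plus one candidate beyond each extreme), maximizing training
  Sensitivity + Specificity. Among maximizers the widest-margin midpoint
  wins, then the smallest. A singular pooled covariance gets a ridge
  `1e-8 · trace(S)/d · I` (or an explicit error with `ridge = FALSE`).
- **kNN.** Three distances: Euclidean; "Fisher-transformed" — Euclidean
  after whitening by the pooled within-class covariance (pooled
  Mahalanobis), the natural Fisher-consistent metric; and "adaptive" —
  query-local normalization `d_i / d_(k+1)`, the scheme that makes kernel
  voting well-posed by putting the kernel argument on [0, 1]. The
  literature the original study cites for these two names is not restated
  there, so both are package interpretations, documented as such. The
  kernel argument is always the normalized distance, so a neighbour exactly
  at the normalization distance contributes zero weight under the
  triangular kernel. Class weights multiply votes; the published optimum
  0.45 for the Non-IRR class (IRR = 0.55) is the default for the advanced
  3NN configuration (whether the original applied the weight to votes or to
  priors is unstated; votes is the default here). Distance ties break by
  training order.
- **LR.** Class-weighted logistic regression through `stats::glm`
  (quasi-binomial IRLS, per-sample class weights, default weight 0.5);
  constant columns are dropped; non-convergence raises an error carrying the
  last coefficient iterate.
- **NB.** Gaussian naive Bayes, empirical priors; zero class variances are
  floored at 1e-9 times the mean feature variance, with a message.
- **GM.** Per-class Gaussian mixtures via `mclust::densityMclust`
  (default one component per class; mclust's hierarchical-clustering EM
  initialization makes fits deterministic), with empirical or equal priors
  as the prior-correction modes.
- **PDFE.** Per-class kernel density with per-point bandwidth equal to the
  distance to the point's `kRadius`-th same-class neighbour
  (`kRadius` ∈ [5, 30], default 10, clipped to class size − 1). Gaussian
  kernel by default; the triangular radial kernel uses the exact
  d-dimensional normalizer so densities integrate to one. Zero bandwidths
  (duplicate points) are floored at 1e-6 times the smallest positive
  bandwidth; if both class densities vanish at a query (possible with the
  compact kernel) the posterior falls back to the priors.
- **DT.** Greedy binary single-feature splits via `rpart` (gini or
  information criterion), `minbucket = minLeaf`, no complexity pruning.

# Validation protocols

`loocv()` implements leave-one-out with two leakage modes. `paper_faithful`
reproduces the published 61+1 protocol: the feature extractor is fitted once
on all samples and only the classifier is refitted per fold — the held-out
image (not its label) influences the feature space. `strict`, the default
for new analyses, refits the extractor inside every fold. The difference is
recorded in the report metadata, and a test verifies that flipping a
held-out sample's label never changes its own prediction in either mode.

`stratifiedSplit()` draws the hold-out test set by seeded sampling without
replacement: exactly 9 IRR + 10 Non-IRR for the study's 34/28 design
(19 test / 43 training), generalizing to `ceiling(0.26 · n_class)` per class
for other sizes — the two rules disagree for the Non-IRR class of the
original design (10 vs 8), and the published counts win there. Hold-out
feature extraction uses the 43 training compounds only. `runBenchmark()`
assembles the method × task × protocol grid with rows in the table order
DT, GM, 3NN, LDA, LR, PDFE; metrics are kept at full precision internally
and rounded to whole percent only by `formatReport()`.

# The synthetic data generator

The study's 62-compound image set is not deposited, so `generateEEMSet()`
emulates its statistical structure. Each image is a sum of five bivariate
Gaussian dye peaks at the published excitation/emission maxima — (470, 527),
(504, 528), (541, 576), (541, 628), (463, 637) nm — plus zero-truncated
Gaussian noise. Two of the listed emission maxima are 1 nm apart despite the
assay's stated 20 nm band separation; the generator reproduces the printed
values and relies on the 34 nm excitation gap to keep those dyes resolvable
(peak widths σ_ex = 20 nm, σ_em = 25 nm were chosen to make that so).

Per compound, a nuisance log-amplitude vector (sd `nuisanceScale`, applied
to both images) models compound-specific but class-uninformative variation;
the with-cells image is additionally modulated by
`exp(cellEffectScale · v_class)` where the unit-norm directions `v_IRR` and
`v_NonIRR` boost and quench alternating dyes in opposite patterns. The
mechanism is deliberately the simplest one consistent with the assay's
premise — toxicity is "reported by dyes" as amplitude changes — and with the
observed ordering of class separability across tasks: control images carry
no class signal, so task 1 performs at chance, and tasks 2–3 separate.
Defaults (`cellEffectScale = 0.4`, `nuisanceScale = 0.15`, `noiseSd = 20`
intensity units against dye base amplitude 1000, i.e. 2% peak noise) were
fixed once to represent a clear cellular effect over moderate
compound-to-compound variation; `cellEffectScale = 0` makes the two images
of a compound identically distributed, the null used for the chance-level
checks. Each compound draws from a counter-derived RNG substream, so
appending compounds never re-randomizes earlier ones.

What the generator does **not** model: Rayleigh/Raman scatter ridges,
inner-filter effects, dye–dye energy transfer, detector saturation, or any
real HaCaT dose–response. Passing tests therefore demonstrate that the
pipeline recovers multiplicative amplitude signatures confined to the
with-cells image under realistic nuisance variation — not that the published
accuracy on the real chemicals is reproduced. The published per-table
numbers are not reproducible without the original data, and the package
makes no claim to them.

# Problem sizes and numerical tolerances

The test and acceptance runs use the full 62-compound design on a 64 × 64
grid — the package's chosen working resolution, which preserves the five-peak
geometry at ~1/8 the instrument sampling — with 511 × 511 reserved for the
dimension checks; the broken-stick Monte-Carlo oracle uses 100,000 simulated
stick breakings (3 standard-error band), brute-force oracle comparisons use
200 random kNN instances and 50 Fisher threshold datasets (10,001-point
grids), and chance-level checks average 50 replicate null datasets under the
published 61+1 protocol. Algebraic identities (mask route, correlation =
1 − d²/2, loading orthonormality) are asserted at 1e-8 to 1e-12; text
serialization carries 8 significant digits in the interchange format and
full `%.17g` precision for extractor internals.

# Known limitations

- The adaptive and Fisher-transformed distances are interpretations of
  names whose defining references are not restated in the source; they are
  documented as package choices.
- `paper_faithful` LOOCV intentionally reproduces a leaky protocol for
  comparability; use `strict` for honest error estimates on new data.
- The generator's class effect is a global amplitude pattern; it cannot
  probe robustness to spectral shape changes, scatter artefacts, or
  wavelength calibration drift.
- Broken-stick and Kaiser retention operate on the correlation-space PCA
  only; no other selection heuristics (sparse/kernel PCA) are provided.
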