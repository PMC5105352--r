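---
title: "Methods: edge-wise sex/age regression and brain-graph comparison"
author: "fcnets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: edge-wise sex/age regression and brain-graph comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Resting-state fMRI functional connectivity (FC) — here the Pearson
correlation between the mean time courses of two anatomically defined brain
regions — varies systematically with sex and age even within early
adulthood. Characterizing that variation requires (i) a mass-univariate
model over every region pair ("edge") that lets each edge carry its own
subset of covariates, and (ii) a topological comparison of the binary graphs
obtained by thresholding each subject's FC matrix. This vignette documents
the models, the defaults, the numerical choices, and the limits of what the
synthetic-data tests establish.

# Data model

ROI time series are T × R matrices (no missing values, no constant
channels). `computeFC()` correlates all column pairs over the full scan —
static FC, no windowing — and applies the Fisher transform z = atanh(r),
whose sampling s.e. is approximately 1/sqrt(T−3). Correlations at |r| = 1
are clipped to 1 − 1e-12 rather than mapped to infinity, with a warning
counting the clips; this keeps every downstream table finite while leaving
ordinary values untouched to machine precision.

Edges are enumerated over the upper triangle (i < j) in row-major order
under the display ordering of the parcellation scheme, with 0-based
`edge_id`; all result tables key on (edge_id, i, j) so the enumeration is
auditable. The subjects × edges table travels as an `FCExperiment`
(a `SummarizedExperiment`: assay `"z"` with edges as rows, cohort as
`colData`, edge map as `rowData`).

# Per-edge regression

The full model for edge $i$ is

$$F_i = \beta^0_i + \beta^s_i\,\mathrm{sex} + \beta^a_i\,\mathrm{age}
        + \beta^{int}_i\,\mathrm{sex}\times\mathrm{age} + \varepsilon_i$$

with sex coded female = 0 / male = 1 (so $\beta^s > 0$ means male > female)
and age in raw years by default. `centerAge` mean-centers age; note that
with the interaction present, centering changes what the main-effect tests
mean, which is why raw years is the default.

**Backward elimination.** At each step the removable term with the largest
single-term partial-F removal p-value is dropped if that p-value is
≥ `alphaRemove` (default 0.05, the conventional stay threshold; the
procedure's description does not pin it). For single-term removal the
partial F equals the squared t of that coefficient in the larger model, so
"model-comparison F" and "coefficient t" readings of the rule coincide.
The marginality rule makes the interaction removable at any time but the
main effects only once the interaction is gone; the reachable models are
exactly M1 (intercept), M2 (sex), M3 (age), M4 (sex + age), M5 (all).
Exact ties in removal p-values (they occur with noise-free synthetic data)
are broken deterministically: the higher-order term first, then the
later-listed term — with terms listed (sex, age, sex:age), a tied pair of
main effects drops age first.

**Degenerate responses.** With a noise-free response the residual sum of
squares is exactly zero and F ratios are 0/0. The implementation treats a
removal that keeps the fit exact (ΔRSS below a relative tolerance of
1e-12 · max(‖y‖², 1)) as maximally insignificant (p = 1) and one that breaks
it as maximally significant (p = 0); a constant response therefore selects
M1 with a model p-value of 1, and planted noise-free M2/M4/M5 responses are
recovered exactly.

**Significance extraction.** The model-level gate is the selected model's
overall F-test against the intercept-only model at the corrected threshold;
term-level significance is read from the selected model's coefficient
p-values at the same threshold. The default correction is Bonferroni at
alpha / n_edges — 0.05/6670 ≈ 7.49E-6 for 116 regions, reported truncated to
two decimals in 1e-6 units — with the denominator equal to the full edge
count (not the count of significant models; the alternative is available via
`nTests`). Benjamini–Hochberg FDR is provided for the interaction analysis.

**Post-selection caveat.** Testing the F-statistic of the *selected* model
is anti-conservative under a global null: the selected model is the
best-looking of several candidates, and simulation at Bonferroni-scale
thresholds shows the per-edge rate running ≈ 2.5–3× nominal (spread over
M2/M3/M4/M5). Consequently the family-wise error of the select-then-test
chain is roughly 2.5× the nominal alpha rather than bounded by it. This is a
property of the published procedure itself, inherent to running selection
and inference on the same data; the package implements the procedure
faithfully and documents the inflation rather than silently replacing it
(a split-sample or closed-testing scheme would control it, at the cost of
no longer being the procedure under study). The acceptance suite carries a
deliberately failing check recording the nominal target.

**Satellite analyses.** `augmentWithCovariates()` appends named cohort
covariates to each edge's already-selected model without re-selection, as a
robustness check of the sex/age conclusions; collinear or zero-variance
covariates are errors, not silent drops. `stratifiedAgeSlopes()` fits z ~
age within each sex and counts edges where both slopes are negative with the
female slope steeper. `edgeCognitionCorrelation()` correlates edges with a
cognitive score directly, Bonferroni-controlled at alpha / n_tests.

# Graph construction and metrics

**Proportional thresholding.** At density d the k = round(d · R(R−1)/2)
edges with the largest Fisher-z values are kept (halves round away from
zero; R's banker's rounding would make edge counts depend on parity). Ties
at the cutoff break by ascending (i, j) order, so the edge count is exact
and runs are bit-reproducible. Ranking is by signed z — "largest FC" — with
`absolute = TRUE` available for |z| ranking. Fixing the density fixes the
wiring cost, making metrics comparable across subjects; the default grid is
0.05 to 0.95 in steps of 0.05 (19 levels).

**Metrics.** Nodal clustering is 2tᵢ/(kᵢ(kᵢ−1)) with zero assigned below
degree 2; the network coefficient C averages over *all* R nodes
(zero-degree nodes contribute 0 and are excluded from no average). Local
efficiency is the mean inverse geodesic distance over ordered neighbour
pairs within the subgraph induced by a node's neighbours. The
characteristic path length is the harmonic mean of geodesic distances over
ordered pairs, with 1/∞ = 0 for disconnected pairs — the reciprocal of
global efficiency — so L is finite for any graph with an edge and no
infinities are ever emitted. Distances come from breadth-first reachability
expansion; an exhaustive-oracle test battery (triple enumeration, per-node
BFS, label propagation, and igraph as an independent library) pins every
metric on 200 random graphs.

**Null model.** Degree-preserving randomization uses double-edge swaps
(a,b),(c,d) → (a,d),(c,b), rejecting self-loops and duplicate edges. Each
null performs `swapsPerEdge × |E|` *successful* swaps (the "~10 rewires per
edge" convention is ambiguous between attempts and successes; successes are
the stricter reading and the default), with attempts capped at 100× the
target and a warning on shortfall — near-complete graphs accept almost no
swaps, which is also why dense grid levels dominate runtime. A graph with no
legal swap returns unchanged with a warning. Small-worldness is
sigma = (C/C_rand)/(L/L_rand) with ensemble means over 30 nulls by default;
a triangle-free ensemble (C_rand = 0) yields NA rather than infinity.
sigma > 1 is read as small-world organization; calibration tests show
sigma ≈ 1 (within [0.8, 1.25]) when the input is itself an Erdős–Rényi draw
and sigma > 1 on Watts–Strogatz lattices.

**Determinism.** One master seed fans out to named substreams — a
counter-based hash of (seed, subject, density, null index) below 2³¹ — so
results cannot depend on evaluation order and full runs reproduce
bit-for-bit, manifest hashes included.

# Group comparison

Male/female differences use Student's pooled-variance two-sample t by
default (the conventional reading of "two-sample t-test"; Welch is a flag).
Nodal metrics gate at p < alpha/R per node and density — no across-density
correction, matching per-density presentation — and the flagged signed
significances sign(t)·(−log10 p) are summed across densities into the
per-node stack (positive = male > female). Global metrics (component size,
normalized C, normalized L, sigma) are compared per density.
`metricRegression()` refits each comparison with sex + age covariates, and
`motionChecks()` reports the frame-displacement sex t-test and FD–age
correlation as confound checks.

# The synthetic world

The generator exists so that every downstream stage has a testable ground
truth; its defaults state the cohort the analysis targets rather than tuning
toward any particular outcome:

* 203 males / 291 females, ages uniform on [22, 36] continuous (only the
  range and moments of the real cohort are public, so uniform is the
  minimal-assumption choice), 116 regions, 1200 timepoints.
* Direct-z mode (the default test path) draws each edge as
  z = mu + b_sex·sex + b_age·age + b_int·sex·age + N(0, sigma²), with the
  same sex coding and age units the regression stage fits, so planted
  coefficients are recovered exactly as sigma → 0.
* Effect directions follow the cohort the package models: sex effects
  positive (male > female), age effects negative (higher FC in younger
  subjects). Effect *sizes* are not public — only p-values are — so the
  default sex effect (0.5 z-units at residual SD 1) was fixed a priori by a
  noncentral-t power analysis: noncentrality 0.5/sqrt(1/203 + 1/291) ≈ 5.5
  gives ≈ 80% detection power at the 0.05/6670 Bonferroni threshold. The
  acceptance suite then checks observed detection against that same oracle.
* Baseline means are Normal(0.3, 0.15) on the z scale — typical resting FC
  magnitude; cognition scores are Normal(100, 15) with optional per-score
  sex shifts; male ICV is drawn ~12% above female; frame displacement is
  drawn identically for both sexes so motion is a true non-confound.
* Time-series mode embeds a lobe-block target correlation (within-lobe
  `blockR`, between-lobe `baseR`, optional per-edge male shift) and draws
  T × R multivariate-normal series; non-positive-definite targets shrink
  linearly toward the identity (factor 0.95, max 200 iterations, minimum
  eigenvalue 1e-8). Effects here live on the correlation scale and only
  approximately on the z scale, which is why direct-z is the default test
  path.

What the generator does **not** emulate: BOLD autocorrelation, scanner
drift, motion artifacts, spatially varying noise, or any real anatomy in
the parcellation (lobes are contiguous blocks of roughly equal size). A
green test therefore establishes that the *statistics* behave as designed on
data satisfying the model's assumptions — not that the pipeline is robust to
fMRI physics the model does not represent.

# Known limitations

* Pearson full-duration FC only; no partial correlation, tangent-space or
  shrinkage variants, and no dynamic (windowed) FC.
* OLS only; no robust, mixed-effects or permutation inference.
* The select-then-test family-wise inflation described above.
* The parcellation front end consumes in-memory arrays; no NIfTI file I/O
  (no NIfTI reader is available in this build environment), no resampling,
  and the homogeneity QC includes each voxel's own contribution to the
  region mean (the conventional, as-written reading).
* Rewiring nulls at densities near 1 are expensive and barely move the
  graph; normalized metrics converge to 1 there by construction.
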