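---
title: "Methods: modular architecture analysis of functional connectivity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modular architecture analysis of functional connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fcmod` packages the analysis chain used to characterise modular
reorganisation of resting-state functional brain networks in cerebral
small vessel disease (SVD) cohorts. This vignette documents the model
behind each stage, the conventions and tunable parameters, what the
synthetic cohort generator does and does not emulate, and the numerical
choices a user auditing results will want to know.

## 1. From time series to binary networks

The pipeline begins where spatial preprocessing ends: a
timepoints × regions matrix of regional mean signals per subject
(the emulated acquisition keeps 220 volumes at TR = 2 s after discarding
the first 10 of 230).

`clean_timeseries()` applies, per region, in this order:

1. **Linear detrending** — least-squares removal of intercept + slope.
2. **Band-pass filtering** — a zero-phase ideal (frequency-domain) filter
   keeping Fourier components with 0.01 Hz ≤ f ≤ 0.08 Hz inclusive.
   An ideal FFT filter was chosen over IIR designs because it is exactly
   reproducible across platforms and has no phase distortion; its
   ringing is immaterial for correlation estimates on stationary series.
   The band must lie strictly below Nyquist (1/(2·TR)).
3. **Nuisance regression** — ordinary least squares on caller-supplied
   confound columns (motion expansions, tissue signals; global-signal
   regression is simply one more column). Rank-deficient confound sets are
   reduced to an independent subset with a warning rather than an error,
   since duplicated motion regressors are common and harmless.

Filtering precedes nuisance regression, matching the conventional
preprocessing sequence; the order matters only when confounds carry
stop-band power.

`connectivity_from_timeseries()` computes all pairwise Pearson
correlations and Fisher-transforms them, z = atanh(r), for approximate
variance stabilisation. Correlations are clipped to ±(1 − 1e−7) first so
that degenerate duplicated signals yield a large finite z (≈ 8.4) rather
than infinity; this affects nothing else. Negative correlations are
**retained** in the matrix — they are excluded only later, as edge
candidates — so the same matrix can serve analyses with other conventions.

`threshold_sparsity()` binarises at a target sparsity S: the
K = round(S·N(N−1)/2) largest-z pairs **among strictly positive z only**
become edges. Ties at the cutoff break by ascending (row, column) index,
making the edge set a pure function of the matrix. If fewer than K
positive candidates exist, all are kept and an `insufficient` flag is set;
whether unranked negative pairs are "zeroed" or "excluded" is then the
only observable difference between conventions, and exclusion is what is
implemented. Edge sets nest monotonically in S given this tie rule.

## 2. Modularity and module detection

Partition quality is Newman modularity
Q = Σᵢ [lᵢ/L − (dᵢ/2L)²]. `detect_modules()` optimises Q by spectral
bipartitioning of the modularity matrix B = A − kkᵀ/(2L), recursively and
on the generalised form B⁽ᵍ⁾ for subgraphs, stopping when the leading
eigenvalue is ≤ 1e−10 or no refined split increases Q. Disconnected
components are partitioned independently. Implementation choices, each
made for determinism or partition quality and validated against exhaustive
search on small graphs:

- **Candidate splits.** For subproblems of ≤ 12 nodes every bipartition is
  scored directly (at most 2047 sign vectors, one vectorised quadratic
  form each) — exhaustive is cheaper than spectral at this size. For 13–24
  nodes, candidates are all contiguous cuts of the nodes ordered by each
  of the top (≤ 3) positive-eigenvalue eigenvectors, each cut refined by
  Kernighan–Lin passes; above 24 nodes only the leading eigenvector is
  swept. Eigenvector sign ambiguity is fixed by making the first
  non-negligible component positive.
- **Kernighan–Lin refinement.** A pass tentatively relocates every node
  exactly once in best-gain order, tracks the cumulative change in Q, and
  keeps the best intermediate state; passes repeat while they strictly
  improve Q. Tentative moves may pass through worse partitions, which is
  what lets the pass escape single-flip local optima.
- **Beam over candidates.** On subproblems of ≤ 24 nodes the best eight
  distinct candidate splits are each completed recursively and the best
  final Q wins; larger subproblems keep the single best candidate (plus
  exact ties). Ties in split gain are measure-zero on weighted-derived
  networks, so study-scale runs pay nothing for this.
- **Global refinement.** After recursion, a final Kernighan–Lin phase over
  the complete partition moves single nodes between modules (or into a
  fresh singleton), accepting a pass only if Q strictly increases. This
  catches multi-way structure a first bipartition cut through.

The test suite validates this scheme against exhaustive search over all
set partitions on a battery of structured and random graphs of up to 10
nodes, where it is expected to reach (and in the shipped battery does
reach) the exhaustive-maximum Q, and checks exact recovery of
bridged-clique and clique-ring constructions.

Labels are canonical — 1..N_m by decreasing module size, ties by smallest
member node — so equal partitions always serialise identically.
`merge_small_modules()` (default floor: 5 nodes, merged into the module
with the most connecting edges, ties to the smaller label) is a
*reporting* aid applied after detection, reflecting the convention of
describing a few large functional systems; detection itself has no size
constraint.

Modules are detected on **group-averaged** networks only; per-subject
partitions are never computed. For cross-group comparability every
analysis uses one fixed reference partition — by convention the low-risk
control group's — and `match_to_reference()` relabels other groups'
partitions by maximum-overlap one-to-one assignment on the confusion
matrix (exhaustive over permutations for ≤ 8 modules, which is exact;
greedy above). Surplus modules get fresh labels above the reference
maximum, largest first. Relabeling never changes the grouping itself.

## 3. Module and nodal metrics

All metrics are computed on each subject's binary network under the fixed
reference partition:

- **Intramodule density** D_s = 2e_s/(N_s(N_s−1)); singleton modules
  return 0 rather than NaN.
- **Intermodule density** D_st = e_st/(N_s N_t); the matrix diagonal is
  filled with the intramodule densities for convenient reporting.
- **Within-module degree** WD_i = (e_i − ē_s)/σ_s with the **population**
  (divide-by-N_s) standard deviation — the convention of the metric's
  original definition; the source formulation does not specify, so this
  choice is documented here. Modules with σ_s = 0 return 0 for all nodes.
- **Participation coefficient** PC_i = 1 − Σ_s (k_is/k_i)², summed over
  **all** modules including the node's own (as the formula is
  conventionally printed); isolated nodes return 0.

The σ_s = 0 and k_i = 0 conventions mean cohort tables never contain
structurally missing cells. All four metrics are tested for exact
agreement with brute-force pair-enumeration oracles.

## 4. Group inference

- **Composite cognitive scores** (`composite_domain_score()`): each raw
  test is z-scored against the whole analysed sample (no healthy-reference
  subgroup is singled out, since none is specified by the emulated
  protocol), timed lower-is-better tests are sign-flipped *after*
  standardisation, and domains average their member z-scores. Flipping
  makes "higher = better" hold in every domain, which the expected group
  ordering (impaired group lowest) requires.
- **Covariate adjustment** is by joint linear modelling (ANCOVA: outcome ~
  covariates + group indicators, F-test on the group block), not by
  pre-residualisation — joint modelling keeps the residual degrees of
  freedom honest. With no covariates this reduces exactly to one-way
  ANOVA. Kruskal–Wallis serves the skewed lesion volumes and chi-squared
  (without continuity correction, so 2×2 tables match the plain formula)
  the categorical variables.
- **FDR** (`fdr_correct()`): Benjamini–Hochberg step-up; the significance
  mask is `adjusted p ≤ q`, which is algebraically the step-up rule. The
  default level is 0.05, with 0.01 the convention for nodal metrics; both
  are arguments. Nodal correction is applied per metric family (WD and PC
  separately) by the workflow, a documented choice where the emulated
  protocol is ambiguous.
- **Post-hoc pairwise contrasts** come from the same linear model
  (cell-means coding), tested as t-statistics on the residual df and
  reported **without** additional family-wise correction — raw pairwise
  p-values, flagged as such in the method string.
- **Metric–cognition regressions** standardise outcome and metric and
  report the standardised β with its t-test.

## 5. Mediation

`fit_mediation()` standardises x, m, y and fits three OLS regressions
sharing one covariate set: m ~ x + C (a), y ~ x + m + C (c′, b), and
y ~ x + C (c). Sharing the covariate set makes the decomposition
c = c′ + a·b an algebraic identity, which the tests assert to 1e−10 on
every fitted dataset. The indirect effect a·b gets a nonparametric
percentile bootstrap CI (subjects resampled with replacement; default
5000 resamples, seeded, so CI endpoints are exactly reproducible); the
Sobel normal-theory z is reported as a secondary check only, since the
product distribution is skewed at realistic n. All paths are reported
standardised, the scale on which such coefficients are conventionally
printed.

## 6. The synthetic cohort generator

The generator exists so that every downstream stage can be exercised
against known truth. It emulates, per group (HC-low, HC-high, SVD-NCI,
SVD-MCI; default sizes 17/19/25/24):

- **Planted connectivity**: a group target correlation matrix with four
  equal 32-node modules; within-module pairs drawn uniformly from
  0.15–0.45 and between-module pairs from 0.05–0.30. The ranges
  *overlap* deliberately: block-constant weights would leave no
  between-module edges at realistic sparsities and drive Q to its 0.75
  ceiling for four equal modules, whereas the heterogeneous draw lands Q
  in the empirically expected 0.3–0.7 band (≈ 0.43 at 20% sparsity).
  Because of the same overlap, the expected Q declines along the sparsity
  grid and drops slightly below 0.3 at the top of the 0.10–0.30 range —
  the test suite asserts the closed-form expected curve rather than a
  flat bound.
- **Group effects** (additive shifts of the weight means): module 2 — the
  executive-control analogue — gains +0.10 internally in HC-high and
  loses 0.10 in SVD-MCI; module 1 (default-mode analogue) gains +0.10 in
  SVD-MCI; the module 1–2 coupling gains +0.06 in HC-high. These encode
  the expected reorganisation pattern (early compensation, late
  disconnection) at effect sizes a 20-subject group detects with high
  power.
- **Subject time series**: multivariate normal draws whose correlation is
  the positive-semidefinite repair of the group target (eigenvalues
  clipped at 1e−6, reconstructed, rescaled to unit diagonal). Eigenvalue
  clipping was chosen over an exact nearest-correlation projection
  because the repair is tiny at these magnitudes and the clipped form is
  simple and exactly reproducible.
- **Covariates** loosely matched to the emulated cohort's published
  means (age, sex ratio, education, grey-matter volume, log-normal WMH
  with a Beta-distributed periventricular share, lacune counts); the
  published dispersion entries behave like standard errors, so plausible
  SDs are used instead. Covariates carry no connectivity effect unless
  configured. Vascular-risk group membership is assigned directly rather
  than via a risk-score calculation, whose point tables are not part of
  the emulated material.
- **Cognitive status**: MoCA scores drawn per group and kept consistent
  with each SVD subject's NCI/MCI label under the education-adjusted
  cutoffs (13/14 for no formal education, 19/20 for 1–6 years, 24/25 for
  7+ years).
- **Mediation pathway**: standardised log-PWMH (X) drives a mediator
  variable (standing for a nodal PC readout; M) which drives the
  visuospatial score (Y), with configurable paths. Defaults a = −0.5,
  b = 0.4, c′ = −0.5 reproduce the expected pathway signs (burden lowers
  the network metric; the metric supports cognition) without asserting
  any particular empirical magnitudes. How SVD connectivity should scale
  with WMH volume is left as a free parameter rather than a hard-coded
  functional form, since no established form exists.

The same configuration and seed regenerate a cohort bit-for-bit.

**What the generator does *not* emulate** — and hence what passing tests
do and do not show about real data: no temporal autocorrelation or
hemodynamic spectrum (series are white within the passband), no head
motion, scanner drift or physiological artifacts, no spatial geometry or
atlas structure (any partitionable node set is accepted), no
heavy-tailed or non-Gaussian connectivity noise, and no
lesion-location effects. Passing the pipeline on synthetic cohorts
demonstrates correctness of the computations and calibration of the
inference under the assumed model, not robustness to fMRI artifacts.

## 7. Validation problem sizes

The test suite validates at sizes chosen to make the checks exact or
well-powered while keeping a full run in minutes: metric oracles on 200
random graphs of ≤ 12 nodes; detection against exhaustive search on
graphs of ≤ 10 nodes (Bell(10) ≈ 1.2e5 partitions); the planted
study-scale network at 128 nodes; ANCOVA calibration on 1000 null
cohorts; mediation CI coverage on 500 replicates of n = 200 with 1000
bootstrap resamples (generated at unit population variances for M and Y,
so the standardised estimand equals the planted a·b); and the
full-pipeline power check at 64 nodes, 20 subjects/group, 200
simulations. The acceptance script reruns the study-scale
planted-structure analysis from scratch at the caller's seed.

## 8. Known limitations

- Binary undirected networks only; no weighted-network variants.
- Negative correlations never form edges (the analysed convention); an
  edge-insufficiency flag is the only trace when positive candidates run
  out.
- Recursive spectral optimisation is a heuristic: beyond the sizes where
  the beam and exhaustive-small-split machinery apply, near-optimality is
  expected but not guaranteed.
- `match_to_reference()` is exactly optimal only up to 8 modules
  (exhaustive assignment); more modules fall back to a greedy matching.
- The mediation model is a single-mediator linear SEM with OLS paths; no
  moderated or multi-mediator designs, and no causal identification
  beyond the model's own assumptions.
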