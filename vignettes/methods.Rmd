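---
title: "Spatial colocalization of cortical thickness development: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial colocalization of cortical thickness development: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Cortical thickness (CT) changes throughout life in a regionally patterned
way: some parcels thin quickly during adolescence, others change most in
aging. `ctcoloc` asks how much of that regional patterning is explained by
the underlying molecular and cellular architecture of the cortex —
neurotransmitter receptor densities, metabolic markers, cell-type
distributions, microstructure — each available as a parcellated brain map.

All analysis happens on parcel vectors: a map assigns one value to each of a
set of labeled cortical parcels (e.g. the 148 Destrieux parcels). The
package links two kinds of inputs:

* **normative CT trajectories**: a grid of modeled CT values over
  parcel × age (5–90 years in 0.5-year steps, 171 timepoints) ×
  percentile (1, 5, 25, 50, 75, 95, 99) × sex, consumed from a file or the
  synthetic generator — never fitted here;
* **neurobiological marker maps**: parcel × marker matrices,
  Z-standardized across parcels within each marker.

The relative CT change between ages $i < j$ is
$\Delta CT(i,j) = (CT_j - CT_i)/CT_i$ per parcel, computed from the
sex-averaged median curve. Lifespan change is swept with sliding windows of
5-year length and 1-year steps (81 windows from (5, 10) to (85, 90)), plus
the main developmental period (5, 30) — 82 models in total.

## Inference against spatially structured nulls

Brain maps are spatially autocorrelated, so parametric p-values for
map-to-map associations are meaningless. Every test statistic here — a
regression $R^2$, a dominance share, a factor solution's explained
variance — is compared against the same statistic recomputed with
**variogram-matched surrogate maps** in place of the predictors:

1. permute the source map's values across parcels;
2. smooth the permutation with a distance-decaying kernel truncated at the
   k nearest neighbors, over a grid of candidate k (including k = 0, no
   smoothing — the best choice for spatially unstructured sources);
3. rescale so the surrogate's variogram (semivariance vs. distance) matches
   the source's, adding white noise to reproduce the short-range nugget;
4. select the candidate scale with the best variogram match and remap the
   surrogate's ranks onto the source's exact value multiset.

Variograms used for fitting and scoring are kernel-smoothed over distance
(Gaussian kernel, bandwidth three times the evaluation-point spacing) over
pairs up to the 50th percentile of pairwise distances; the raw binned
estimator remains available as `empirical_variogram()` (default cutoff
25%). The wider fitting range is deliberate: at ~150 parcels, matching only
the shortest quarter of distances leaves surrogate long-range structure
unconstrained, which measurably inflates the empirical rejection rate under
the spatial null; matching to the median distance restores calibration with
unchanged fit quality. With rank
resampling on, the value multiset is fixed, which makes the smoothing
amplitude irrelevant; candidate scales are therefore scored on the
*realized* post-resampling variogram rather than the affine prediction.
Each surrogate records a fit score — the mean relative absolute deviation
from the source variogram — as a per-map quality diagnostic.

Ensembles are generated once per map and reused across every window and
analysis (the "constant null set" contract; the cache in
`surrogate_cache()` enforces it). Defaults are 10,000 maps for map-level
inference and 1,000 for subject-level analyses; the examples and tests use
smaller ensembles.

Empirical one-sided p-values use $(1 + \#\{null \ge obs\})/(1 + N)$, so ties
count against the observation and $p > 0$ always. Benjamini–Hochberg FDR is
applied within analysis-specific families: univariate scans within each
source modality across windows; multivariate scans across all models; the
dominance scan as one family spanning the full-model and predictor-wise
p-values (82 + 82·p entries); gene period tests across all tests of a run.

## Dominance decomposition

For the joint predictor set, explained variance is decomposed by dominance
analysis: the total dominance of predictor $x$ is the average, over subset
sizes, of the mean incremental $R^2$ from adding $x$ to each subset of the
other predictors. The shares sum exactly to the full-model $R^2$, which is
why the decomposition runs on raw $R^2$ (the identity does not hold for
adjusted $R^2$; the adjusted value is reported for the full model only).
The implementation enumerates all $2^p$ subsets from centered cross-moment
matrices in compiled code and is limited to $p \le 15$; a literal
`lm()`-based enumeration guards it in the tests. Spearman correlations
between the target and each marker are emitted alongside to sign the
associations, and regional influence maps
($\Delta PE_x = |PE_{X\setminus\{x\}}| - |PE_X|$, the gain in absolute
prediction error when $x$ is removed) localize which parcels drive each
marker's contribution.

## Factor reduction of marker sets

Marker sets are reduced with minimum-residual (minres) factor analysis on
the marker correlation matrix, implemented via eigen-truncation inside an
optimization over uniquenesses. Retention is decided on the *unrotated*
variance fractions (every factor explaining ≥ 1% of the set's variance by
default); retained factors are promax-rotated (κ = 4, oblique — correlated
biological processes are expected), factor scores use the regression
(Thurstone) method, and each loading column is sign-flipped so its
largest-magnitude loading is positive, which removes sign nondeterminism.
Factors are named by assigning every marker to the factor it loads on most
(ties break to the lower factor index). Communalities are computed from the
unrotated loadings — they are rotation-invariant, and this keeps the
explained-variance statistic stable when a degenerate (e.g. null-map)
solution makes the oblique rotation matrix near-singular. Both unrotated
and rotated variance fractions are emitted, since either may be the
quantity of interest. The initial extraction uses the largest factor count
with non-negative model degrees of freedom. Solutions are validated by
refitting on surrogate-map marker sets and comparing total explained
variance (`validate_factors_null()`); a plain label-shuffle null is the
natural alternative and is obtained by generating surrogates with an
unsmoothed permutation only.

## Synthetic data with planted truth

The generator produces every input the pipeline consumes, with known ground
truth, so that recovery is testable end to end:

* **Geometry**: parcels quasi-uniform on a unit sphere as two hemispheric
  caps (Fibonacci spiral + small jitter), Euclidean chord distances. No
  cross-hemisphere mirroring and no realistic folding.
* **Markers**: latent factors drawn as Gaussian random fields with
  covariance $\exp(-d/\rho)$, mixed by a loading matrix plus iid noise and
  standardized. The default range ρ = 0.3 gives neighboring parcels
  (chord distance ≈ 0.19 on the unit sphere) a correlation near 0.5,
  matching what parcel-level molecular maps typically show; ρ = 1 would be
  implausibly smooth and shrinks the effective sample size drastically.
* **CT trajectories**: change maps are *planted* and CT integrated
  multiplicatively — for each schedule window, $\Delta = s + \varepsilon$
  with $s \propto M w$ and the spatially autocorrelated noise field
  residualized on $s$ and scaled so $cor(Mw, \Delta)^2$ equals the
  requested $R^2$ exactly; then $CT_j = CT_i (1 + \Delta)$ at the window
  knots and monotone (Fritsch–Carlson) interpolation fills the 0.5-year
  grid. Planting change and integrating CT (rather than the reverse) makes
  the true window-level $R^2$ exactly controllable. Window means/SDs
  default to −1%/2% relative change, mild lifetime thinning. Percentile
  curves are fixed multiplicative offsets of the median and the sex curves
  are symmetric around it, so the sex-averaged median recovers the planted
  maps bit-exactly at window endpoints.
* **Subjects**: population median curve × (1 + subject-level spatially
  correlated offset) × (1 + site effect) + iid session noise (default
  0.01 mm), with a skewed (log-normal) surface-defect count per session for
  QC testing. These noise defaults make individual-subject windowed change
  noise-dominated — subject-level $R^2$ spanning roughly 0–0.4 with a
  cohort mean far below the cohort-average-map $R^2$ — which is the
  attenuation regime single-subject MRI change data actually live in.
* **Expression**: donor ages log-uniform over 0.33–82.05 years (n = 33 by
  default), signal genes carry a Gaussian age bump, null genes are flat and
  flagged `non_brain`.

Passing recovery tests on these data shows the estimators are correct under
spatially autocorrelated, noisy, but stationary and Gaussian conditions; it
does not certify behavior under the nonstationarities, registration errors
and site artifacts of real imaging data.

## Subject-level validation

Subjects pass a Q3 + 1.5·IQR filter on surface-defect counts (quantiles by
linear interpolation, type 7; pooled over all sessions; by default a
subject is excluded if *any* session exceeds the threshold, matching
longitudinal use — per-session exclusion is a flag). Per-subject relative
change maps feed per-subject dominance decompositions. Because a single
subject's p-value would be nearly powerless, inference is at the group
level: the across-subject mean full-model $R^2$ (and each predictor's mean
dominance) is compared against the same mean recomputed in null analyses
with all markers jointly replaced by their k-th surrogates — one constant
ensemble (default 1,000 maps) serving all subjects and iterations.
`include_markers = FALSE` provides a fast full-model-only path used for
large calibration studies. Scalar covariates such as intracranial volume
are recorded for group models; map-valued covariates are residualized from
each subject's change map.

## Gene-expression period tests

A marker's developmental relevance is validated against postmortem
developmental expression: the marker's gene set is averaged per donor,
LOESS-smoothed over age (span 0.75, degree 2 by default; statistics are
computed on the smooth curve over a uniform age grid, making them
independent of the donor age sampling density), and its mean expression
during vs. outside a candidate period is compared with 10,000 same-sized
gene sets drawn from non-brain genes (2,154 in the emulated pool). The mean
statistic asks "is expression elevated in the period"; the ratio statistic
asks "does expression peak there". The period boundaries are supplied
explicitly (in the full pipeline they come from the FDR-significant window
spans), keeping the module testable standalone. The ratio statistic is
invariant to rescaling all genes jointly but not to additive offsets —
offsets can reorder ratios — so inputs should be on a common normalized
scale.

## Numerical choices and degenerate inputs

* Z-standardization uses the sample SD (n − 1); re-standardization of
  cell-type averages before factor analysis is off by default
  (`zscore_parcels()` makes it a one-call opt-in).
* Parcel identity is the label string; alignment is by label intersection
  in the first input's order, listwise-complete for multivariate models and
  pairwise for rank correlations.
* Grid ages must match exactly (no silent interpolation); constant maps,
  empty label intersections, rank-deficient designs, off-grid ages and
  invalid thresholds are hard errors.
* Fisher z is plain `atanh`; a perfect correlation yields an infinite z
  that is excluded from LOESS smoothing rather than clipped.
* The spatial covariance Cholesky adds escalating diagonal jitter
  (0 to 1e-6) before failing.
* All generators are pure functions of their seed; the pipeline derives
  every stage seed from the single config seed, and reruns are
  byte-identical.

## Problem sizes used in the tests

The statistical acceptance tests run the full designs at sizes chosen to
make their Monte Carlo error small relative to the asserted margins while
keeping a routine test run short: surrogate quality on 500–1,000 maps at
148 parcels; scan calibration on 1,000 repeats with 500-map ensembles (each
ensemble serving 50 repeats — targets are fresh in every repeat); planted
recovery on 100 replicates with 100-map ensembles; gene period power on 100
simulations with 1,000 null sets; subject-level power on 100 cohorts of 200
subjects against one constant 1,000-map ensemble, with the null-cohort
calibration drawing fresh markers and ensembles per cluster of repeats so
no single marker draw biases the rejection rate. Null cohorts carry a flat
population change (no aging signal) with all subject-level variability
present: when every subject additionally shares one strongly smooth
population-change map, the group-mean test becomes mildly anti-conservative
because that single map's chance alignment with the marker set offsets all
of a cohort's p-values jointly — the same conditional-leverage limitation
noted below, amplified by averaging over subjects. The `pipeline_cli`
orchestration surface is the exported `run_pipeline()`/`write_report()`
pair plus `scripts/acceptance.R`; this package is a library, not a shell
tool, so no separate executable is shipped.

## Known limitations

* Surrogates match the variogram up to the 25th-percentile distance cutoff;
  long-range structure beyond it is unconstrained, so a specific marker
  draw can sit above or below its own surrogates in leverage against very
  smooth targets. Group-level calibration is exact marginally over marker
  draws (verified in the tests) but conditionally on one fixed marker set
  the test can be mildly conservative or liberal.
* Dominance analysis is exponential in the predictor count (capped at 15);
  reduce markers by factor analysis first.
* The LOESS-based peak localization of expression bumps has a typical error
  of ~2–3 years at realistic noise; period tests, not peak positions, carry
  the inference.
* The generator's stationary exponential kernel cannot emulate
  distance-dependent anisotropies or the hemispheric mirroring of real
  transcriptomic data.
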