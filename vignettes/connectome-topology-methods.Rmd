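---
title: "Graph-theoretical connectome analysis with connectopath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretical connectome analysis with connectopath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectopath)
```

## The analysis in one paragraph

connectopath implements the standard graph-theoretical pipeline for
case-control brain-connectome studies.  Per subject, a functional
connectome (FC) is built from parcellated resting-state fMRI node time
series as the matrix of pairwise Pearson correlations — optionally within
the slow-4 (0.027–0.073 Hz) or slow-5 (0.01–0.027 Hz) frequency band — and
a structural connectome (SC) is read from a matrix of region-pair mean
fractional anisotropy (FA) values.  Each weighted N×N matrix is
thresholded into binary graphs over a sparsity grid (default 0.10–0.34 in
steps of 0.01), global and nodal topology is computed at every threshold,
and each metric is summarized by its trapezoidal area under the curve
(AUC) across the grid so that no single arbitrary threshold drives the
results.  Group differences in AUC values are tested with a
covariate-adjusted label-permutation test; associations with clinical
scores use partial correlations; and structure–function–symptom pathways
are probed with Baron–Kenny mediation and a percentile bootstrap of the
indirect effect.

## Network construction

**Functional edges.** The edge between nodes *i* and *j* is the Pearson
correlation of their time series.  The diagonal is forced to zero and the
matrix is exactly symmetrized.  Constant (zero-variance) node series mark
a degenerate region; their correlations are set to 0 with a warning
rather than propagating `NA`s.  Whether to Fisher-transform correlations
before thresholding is immaterial here: thresholding is rank-based, and
the z-transform is monotone, so the binarized graphs are identical.  Raw
*r* is therefore used.

**Band-limited analysis.** `bandpass_filter()` is an ideal
(rectangular) discrete-Fourier filter: coefficients with frequency `f`
satisfying `low < f <= high` are retained, everything else is zeroed.
The closed upper edge makes the abutting slow-5 and slow-4 bands exactly
disjoint and exhaustive — a coefficient exactly at 0.027 Hz belongs to
slow-5.  An ideal filter (rather than, say, a Butterworth design) matches
common resting-state toolbox practice for these bands and is exactly
idempotent, which the test suite asserts to 1e-10.  The filter itself
only demeans; the pipeline's FC stage additionally removes a linear trend
per node before filtering, which is where detrending belongs as a
preprocessing step.

**Structural edges.** `load_sc_matrix()` validates dimension, symmetry
(tolerance 1e-6, after which the matrix is exactly symmetrized) and the
FA range [0, 1].  FA weights are treated exactly like FC weights
downstream: they rank edges for sparsity thresholding and are then
discarded, giving unweighted graphs in both modalities.

## Binary graph topology

`binarize_at_sparsity()` keeps exactly `k = round(s·n(n−1)/2)` strongest
upper-triangle weights (rounding half away from zero, stated explicitly
because IEC-60559 half-even rounding would make edge counts
platform-dependent).  Ties at the cut are broken by ascending (i, j)
index, so binarization is fully deterministic.  Negative FC correlations
are zeroed before ranking by default (`negative_weights = "zero"`), the
common toolbox convention that also keeps FC and SC treatment symmetric;
`"absolute"` is available for sensitivity analyses.

Metrics follow the unweighted conventions of the connectome literature:

* **Cp** — mean over nodes of the fraction of neighbor pairs that are
  connected, 0 for degree < 2.
* **Lp** — mean shortest-path length over ordered pairs at finite
  distance.  At sparse thresholds graphs can disconnect; infinite
  distances are excluded from the mean and their count is reported, while
  global efficiency separately captures disconnection through the
  `1/∞ = 0` convention.
* **Eg / Ne** — (nodal) efficiency as mean inverse distance; **Eloc** —
  mean over nodes of the efficiency of the neighbor-induced subgraph.
* **Nd / Nb** — degree, and Brandes betweenness with fractional counting,
  normalized by `(n−1)(n−2)/2`.  The normalization cancels in group
  comparisons but is fixed for reproducibility.
* **γ, λ, σ** — Cp and Lp divided by their means over degree-preserving
  Maslov–Sneppen rewired null networks, and their ratio.  "Random
  network" is read as degree-preserving (the field-standard null), not
  merely density-matched.  Defaults: 100 nulls per graph and a budget of
  10·|E| accepted double-edge swaps, both configurable; swaps that would
  create self-loops or multi-edges are rejected, and a graph admitting no
  swap (a star) is returned unchanged with a warning.  A network is
  called small-world when γ > 1 with λ ≈ 1.

The AUC over the sparsity grid uses the trapezoid rule; it is linear in
the metric, so group-difference directions are preserved under the
alternative rectangle rule.

All metric implementations are verified against an independent
brute-force oracle (vectorized Floyd–Warshall distances, exhaustive
triangle counting, shortest-path counting cross-validated against DFS
path enumeration) on every labeled connected graph with up to 6 nodes
and on random 8-node graphs, to 1e-10.

## Group inference

The group comparison is a two-sided permutation test on the difference
of group means of covariate-adjusted residuals.  Covariates (age and a
0/1 sex indicator by default) are handled Freedman–Lane style: responses
are residualized on the covariates once, then group labels are permuted.
With fixed covariates the residuals are exchangeable under the null,
which keeps the test exact up to Monte-Carlo error; the test suite
verifies nominal type-I error at the study's group sizes.  The p-value
uses the `+1` correction, `(1 + #{|T_perm| ≥ |T_obs|})/(n_perm + 1)`, so
the smallest achievable p is `1/(n_perm + 1)` and p = 0 never occurs.

Both Bonferroni and Benjamini–Hochberg FDR correction are provided and
selected per stage, because case-control connectome studies commonly use
the stricter correction for the many group tests and FDR for the
clinical correlations.  The correction family defaults to modality ×
band × scope (each nodal map corrects across its nodes) and is
configurable, since family definitions are a genuine analytic choice.

Partial correlations residualize both variables on the covariates and
refer `r` to a t distribution with `n − k − 2` degrees of freedom.
Clinical correlation and mediation run within the patient group, where
the clinical scales actually vary; pooling groups would let the group
contrast masquerade as a clinical association.

## Mediation

`mediate()` fits the three Baron–Kenny regressions (`Y ~ X`, `M ~ X`,
`Y ~ X + M`, all with the same covariates) and bootstraps the indirect
effect a·b by resampling subjects with replacement and refitting a and b
per resample.  Using one covariate set across the three fits makes the
decomposition `c = c′ + a·b` an exact algebraic identity of OLS, which
the tests assert to 1e-8.  The default interval is the plain 95%
percentile bootstrap (n_boot = 5000 by default); bias-corrected BCa is
available behind a flag.  Rank-deficient resamples are redrawn rather
than dropped so the replicate count stays fixed.  The mediation is
declared significant exactly when the interval excludes zero.  Variables
are not standardized before fitting — raw-scale coefficients keep the
output interpretable against the instruments' units.  Model triplets
(X, M, Y) are user-specified; a helper suggests triplets that pair an
altered FC metric with an altered SC metric sharing a significantly
correlated clinical scale, mirroring how such models are typically
chosen, but the heuristic is never hard-wired.

## The synthetic cohort generator

Because per-subject MRI derivatives are rarely shareable, the package
ships a generator whose ground truth is fully known, so the entire
pipeline is testable end-to-end.

* **Structural template.** Communities (8 near-equal blocks of the 116
  nodes by default) are internally dense — within-community weights
  uniform on [0.5, 0.9] — and a fraction (default 0.1) of those edges is
  rewired to random cross-community pairs, Watts–Strogatz style.  After
  thresholding this yields γ > 1 with λ near 1, the small-world regime.
* **Planted group effect.** The patient template additionally receives
  high-weight cross-community shortcuts (default 5% of the
  within-community edge count).  Shortcuts shorten paths and raise
  global efficiency — patients' Eg up, Lp down — with the effect size a
  configuration knob, not a claim about effect sizes in patients.
* **Subject data.** FA matrices are the template plus symmetric Gaussian
  noise (sd 0.05), clipped to [0, 1].  Time series are draws from a
  zero-mean multivariate normal whose covariance is the template with
  its diagonal loaded until positive-definite; strongly coupled node
  pairs then show strong sample correlations.  T defaults to 230 volumes
  at TR = 2 s — a typical ~8-minute run; the volume count is a
  placeholder in the sense that any realistic T works, and it is
  configurable.
* **Clinical scores.** Patients follow the means and spreads of a
  chronic low back-related leg pain case series (VAS ≈ 5.8, Barthel ≈ 88,
  JOA ≈ 14, two-point discrimination ≈ 25–30 mm); controls sit at the
  healthy end of each instrument.  All scores are clipped to instrument
  bounds.  Ages are truncated-normal N(52, 7) on [35, 65]; sex
  alternates for balance.  Only the (X, M, Y) mediation triplet carries
  planted structure (M = aX + ε, Y = c′X + bM + ε; a = b = 0 by
  default), every other score is independent noise — which is what
  isolates the mediation-recovery tests.

What the generator does **not** emulate: temporal autocorrelation and
hemodynamics, head motion, physiological noise, tractography biases,
spatially heterogeneous edge reliability, and any coupling between
clinical scores and network topology beyond the planted terms.  Passing
tests therefore demonstrate that the statistical machinery recovers
known truth under the model's assumptions — not that those assumptions
hold in scanner data.

## Numerical and design choices

* Edge-count rounding is half-away-from-zero; binarization tie-breaks are
  lexicographic; both stated so results are bit-reproducible across
  platforms.
* All randomness flows from explicit seeds; the pipeline derives
  per-stage sub-seeds from one master seed, so changing `n_perm` does not
  perturb the bootstrap draws, and a rerun with the same configuration is
  bit-identical.
* Diagonal loading of the template covariance iterates until the smallest
  eigenvalue exceeds 1e-8.
* The rewiring null returns a partially rewired graph (with a warning)
  when the proposal budget is exhausted, rather than looping forever on
  graphs like stars where no swap is acceptable.
* p-values entering the correction routines must lie in (0, 1]; zero or
  out-of-range values raise errors rather than silently adjusting.

## Problem sizes used in the shipped checks

The test suite exercises the statistical calibration at reduced but
informative sizes, chosen to make each property measurable: type-I error
of the permutation test from 1000 null simulations with 999 permutations
at the 32/31 group sizes; bootstrap coverage from 500 simulated datasets
(n = 200, 1000 resamples); small-worldness and the planted-effect
recovery on cohorts of 12 and 63 subjects at 116 nodes with 20 nulls per
graph and 1000 permutations.  The defaults users see
(`n_perm = 10000`, `n_boot = 5000`, `n_null = 100`) are the
analysis-grade settings.

## Known limitations

* Only binary (unweighted) graph metrics are implemented; weighted
  variants, modularity, rich-club and hub classification are out of
  scope.
* Lp on disconnected graphs is a conditional mean over reachable pairs;
  comparisons across graphs with very different disconnection counts
  should lean on the efficiency metrics instead.
* The mediation model is linear with a single mediator; no sensitivity
  analysis for unmeasured confounding is provided.
* The permutation test assumes exchangeable residuals after linear
  covariate adjustment; strongly non-linear covariate effects would
  violate this.
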