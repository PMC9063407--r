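---
title: "Dynamic connectivity states: models and methods in dfncstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic connectivity states: models and methods in dfncstates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfncstates)
```

## What the package computes

Resting-state fMRI connectivity is not static: over a scan of several
minutes the correlation structure among brain networks reorganises on a
time scale of tens of seconds. `dfncstates` implements the standard
sliding-window approach to *dynamic functional network connectivity*
(DFNC) for ICA-derived component time courses, and the downstream
machinery used to characterise it:

1. **Post-processing** of per-subject component time courses
   (T time points × C components): initial-volume discard, cubic
   polynomial detrending, robust (median/MAD) despiking, fifth-order
   Butterworth low-pass filtering, and nuisance regression against motion
   parameters, plus motion-based subject QC.
2. **Windowed connectivity**: tapered sliding windows (rectangle
   convolved with a Gaussian), a weighted window covariance, an
   L1-penalised precision matrix (graphical lasso) inverted and
   normalised to correlations, and the Fisher z-transform, giving a
   W × P matrix per subject (P = C(C−1)/2 component pairs).
3. **State clustering**: k-means under the city-block (L1) metric on
   "exemplar" windows (local maxima of connectivity variance), with the
   number of states chosen by the gap statistic and the mean silhouette
   over k = 2..10, then a full-data pass that assigns every window of
   every subject to a state.
4. **Temporal properties** per subject: fractional windows (occupancy),
   mean dwell time, and total plus directional transition counts.
5. **Group statistics**: pooled two-sample t-tests, three-level one-way
   ANOVA with post hoc t-tests gated on a significant omnibus, Pearson
   chi-square without continuity correction for categorical tables, and
   Benjamini–Hochberg FDR across the P connectivity pairs within each
   state.

Because real cohort recordings of this kind are rarely shareable, the
package also ships a **synthetic cohort generator** with known ground
truth, which is what all quantitative validation runs on.

## The generative model behind the simulator

Each simulated subject carries a hidden first-order Markov chain over k
connectivity states, advanced per time point (window-level persistence
then arises from the windowing itself). Conditional on the active state
s(t), the C-vector signal is drawn i.i.d. from N(0, Σ_s); white noise of
standard deviation `noise_sd` is added on top. The state covariances are
correlation-scale block matrices defined by the component→network map:

- the *inter-network dominant* state places positive correlation between
  components of different networks within a designated set (SMN, VN,
  DAN, VAN by default) — an analogue of a globally integrated state;
- the *within-network dominant* state places positive correlation inside
  every network block — a segregated state.

A raw cross-block pattern need not be positive semi-definite; it is
repaired by eigenvalue clipping (floor 1e−6) followed by rescaling to a
unit diagonal, which preserves the dominant block structure. The repair
is validated by requiring the smallest eigenvalue to be non-negative.

Default study conditions: three groups (HC n = 51, SF n = 39, NSF
n = 16), C = 33 components mapped to nine networks (CB 1, DAN 1, DMN 5,
FPN 3, LIM 6, SC 6, SMN 3, VAN 2, VN 6), T = 770 time points at
TR = 0.720 s (788 acquired volumes minus 18 equilibration scans), and
noise_sd = 0.2 relative to unit signal variance.

**Choice of state persistence.** The literature gives no generative
magnitudes for state dynamics, so the defaults are chosen for
recoverability under the method's own assumptions. A windowed state
analysis presumes states persist on at least the window scale
(60 TR ≈ 43 s); defaults therefore use stay probabilities HC
(0.97, 0.98), SF (0.96, 0.985), NSF (0.95, 0.99), i.e. mean dwell times
of 33–100 TRs (24–72 s). Groups differ only in persistence, with NSF the
most dominated by the segregated state; the implied stationary occupancy
of the integrated state falls from ≈ 0.40 (HC) to ≈ 0.17 (NSF), and the
cohort-wide occupancy of that state is ≈ 30%. Had persistence been set
far below the window length, most windows would be state mixtures and no
method of this family could label them — an early development draft with
12–36 s dwells showed exactly that, which is why the defaults are pinned
at window scale.

**What the generator does not emulate.** No hemodynamic convolution, no
1/f spectral shape (the state signal is white within state), no spatial
maps or ICA unmixing, no scanner drift or physiological noise unless the
artifact options (spikes, polynomial drift, motion coupling — all off by
default) are enabled, and no clinical covariates. Passing tests
therefore demonstrate internal correctness and recoverability under the
model's own assumptions, not performance on scanner data.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `TR` | 0.720 | s | acquisition repetition time |
| `n_discard` | 18 | volumes | magnetisation equilibrium |
| `window_length` | 60 | TR (≈ 43 s) | balance between covariance precision and temporal resolution |
| `window_step` | 1 | TR | maximal temporal sampling of states |
| `taper_sigma` | 3 | TR | Gaussian convolved with the rectangle; standard DFNC practice |
| `lambda_grid` | 10^seq(−3, 0, 10 pts) | — | cross-validated per subject |
| `fixed_lambda` | NULL | — | bypasses CV (used in validation runs for speed and comparability) |
| `k_min..k_max` | 2..10 | states | candidate range for validity criteria |
| `replicates` | 100 | runs | k-means++ restarts for the exemplar model |
| `gap_B` | 10 | datasets | gap-statistic reference draws |
| `alpha` | 0.05 | — | two-sided significance level |
| motion QC | 0.3 / 3.0 | mm | maximum displacement / mean FD thresholds |

The motion thresholds are implemented verbatim as printed in the
protocol they follow (maximum displacement > 0.3 mm *or* mean FD > 3 mm
excludes). That pairing is unusual — common practice couples a laxer
maximum with a stricter mean — so both are plain config keys rather than
constants.

## Numerical and design choices

**Graphical lasso.** No installed R package provides the estimator, so
it is implemented natively (RcppArmadillo): blockwise coordinate descent
on the covariance estimate W with a cyclic-coordinate-descent lasso
inner loop; convergence when the largest entry change of W per sweep
falls below `tol` (1e−5 by default, on the data's covariance scale).
At λ = 0 the solution is the unpenalised MLE and is computed by direct
Cholesky inversion. Within a subject, adjacent windows warm-start each
other, which cuts the per-window cost several-fold. Unit tests verify
the KKT conditions of the penalised log-det problem
(`W − S = λ·sign(Θ)` on the support, `|W − S| ≤ λ` off it), equality
with the matrix inverse at λ = 0, and sparsity monotonicity in λ.

**Penalty selection.** The CV design treats a *window* as the estimation
unit, because that is what the pipeline penalises downstream: windows
are split into random folds, the lasso is fitted to individual
training-window covariances (capped at 20 per fold), and fits are scored
on the held-out pooled covariance by log det Θ − tr(S_hold Θ). Pooling
the training windows instead would make the unpenalised fit nearly
noise-free and the search would always collapse to the smallest penalty.
Ties go to the smaller λ. Validation and acceptance runs use
`fixed_lambda = 0.05` — a mild penalty on unit-variance data at window
length 60 — so that clustering results are not confounded by per-subject
penalty variation.

**City-block k-means.** Assignment ties go to the lowest centroid index;
the centroid update is the component-wise *lower* median (the exact L1
minimiser; the lower of the two central order statistics for even
cluster sizes), which makes runs bit-reproducible. Empty clusters are
re-seeded at the point farthest from its centroid. Restarts use
k-means++-style seeding under L1 through R's RNG. For small instances
(`exhaustive_init = TRUE`, k = 2) the algorithm restarts from every
distinct pair of points and finishes each run with a best-improvement
single-point reassignment descent on the median-centroid objective;
this matters because the optimal median-centroid partition need not be
assignment-stable, so plain Lloyd iteration cannot always reach it.

**Cluster-number validity.** The gap statistic uses the within-cluster
L1 dispersion (the k-means objective), reference sets drawn uniformly
over the feature-wise bounding box, the usual √(1 + 1/B) standard-error
factor, and chooses the smallest k with Gap(k) ≥ Gap(k+1) − se(k+1).
The silhouette uses L1 distances. When the two criteria disagree the
silhouette argmax wins with a warning (an explicit override is
available); on the synthetic cohorts the gap curve is nearly flat while
the silhouette is decisive, so the silhouette is the better referee
there. Validity curves are computed on the pooled exemplar windows,
subsampled to `validity_max_n` (default 1000) rows for tractable
reference clustering; the final exemplar model at the chosen k is then
fit on the *full* exemplar pool.

**Exemplar windows** are strict interior local maxima of the per-window
variance of z-connectivity across pairs; a subject without any (constant
or monotone variance series) contributes every 10th window instead.

**State ordering.** After the full-data pass, states are relabelled by
descending occurrence, so state 1 is always the dominant state. Under
the default generator the dominant state is the segregated
(within-network) one; the rarer, integrated state is the analogue of the
less frequent state reported in this literature. The ordering rule is a
config option, not an assertion about any particular dataset.

**Temporal properties.** Dwell time is reported in window units with an
exact `× step × TR` seconds conversion. A subject that never enters a
state has *undefined* (NA) dwell time there — it is excluded from that
state's dwell comparisons rather than imputed zero — while its
fractional occupancy of that state is 0. Entry percentages are rounded
half-away-from-zero to one decimal (5/16 → 31.3), matching how such
percentages are conventionally printed; banker's rounding would give
31.2.

**Group statistics.** Student (pooled-variance) t-tests by default,
Welch behind a flag; ANOVA via the standard between/within
decomposition; post hoc pairwise t-tests only when the omnibus p < α;
chi-square without continuity correction (required to reproduce printed
two-by-two p-values); BH-FDR applied within one state's family of P
pairs. Degenerate inputs (zero variance everywhere) return the t = 0 /
F = 0, p = 1 convention with a flag rather than NaN.

## Validation design and problem sizes

All quantitative validation is synthetic, with these problem sizes
chosen to keep the full suite inside a desktop-scale run while leaving
the statistical conclusions stable:

- *Exhaustive clustering oracle*: 1000 random instances with n ≤ 8
  points, k = 2, P ≤ 3, against full partition enumeration.
- *Model-selection recovery*: 20 cohort seeds, 30 subjects each
  (10 per group), T = 770, C = 12 (the reduced-component variant of the
  default conditions; windowed estimation, validity analysis and
  full-data assignment run end to end per seed). Expected: k = 2 chosen
  in ≥ 90% of seeds and matched state-median pattern correlation > 0.9.
- *Temporal identities*: 1000 fuzzed label sequences.
- *Statistical calibration*: 20 seeds of null cohorts (identical
  generators, n = 30/group, 528 pairs × 2 states) for the FDR
  false-positive fraction, and 20 seeds with a +0.3 z shift on the
  within-DMN block of the segregated state in one group for sensitivity.
  The calibration operates on per-subject per-state mean z-vectors
  generated directly at that level (`simulate_state_fc_cohort`), the
  exact quantity the comparison consumes.
- *Signal-processing analytics*: the −3 dB point of the Butterworth
  single pass at the cutoff, cubic annihilation by the detrender, λ = 0
  glasso against the matrix inverse, and the closed-form Fisher z.

`scripts/acceptance.R` re-runs a compact version of all of the above
from scratch and writes the resulting numbers as JSON.

## Known limitations

- The simulator's i.i.d.-within-state signal overstates the spectral
  flatness of real component time courses; filtering therefore removes
  genuine signal power in simulation that it would not remove from
  band-limited BOLD fluctuations.
- Sliding-window correlation smears state boundaries; windows straddling
  a transition are genuinely ambiguous and bound assignment accuracy
  from above (with window-scale dwell times, accuracy near 90% is the
  expected ceiling, not a defect of the clustering).
- The gap statistic under L1 dispersion with box-uniform references is
  nearly flat on these high-dimensional z-vectors; the silhouette
  carries most of the model-selection signal.
- The per-subject CV for λ is a documented design choice; other
  protocols (population-level λ, stability selection) are plausible and
  would give somewhat different sparsity.
- No covariate adjustment, mixed models, or longitudinal structure in
  the group comparisons.

## A minimal run

```{r example, eval = FALSE}
cfg <- list(C = 12, T_points = 770, n_per_group = 10, fixed_lambda = 0.05,
            replicates = 20, validity_replicates = 3, validity_max_n = 600,
            seed = 1, output_dir = "dfnc_run")
manifest <- run_pipeline(cfg)
print(manifest)
read.delim(file.path("dfnc_run", "state_occurrence.tsv"))
read.delim(file.path("dfnc_run", "temporal_comparisons.tsv"))
```
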