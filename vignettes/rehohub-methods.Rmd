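---
title: "Local functional-connectivity hubs: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local functional-connectivity hubs: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rehohub)
```

This vignette is the package's account of the science it implements:
the measurement model, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical decisions a user auditing the code will want
stated explicitly. It reports no empirical number that the test suite
or `scripts/acceptance.R` does not itself compute.

## 1. The measurement model

### Regional homogeneity

Local functional connectivity is measured voxel-wise as Kendall's
coefficient of concordance over the voxel's 3×3×3 neighbourhood. Each
of the K ≤ 27 series is ranked along its own time axis; with $R_i$ the
column sum of ranks at frame $i$ of $N$,

$$W = \frac{\sum_i R_i^2 - N \bar R^2}{\tfrac{1}{12} K^2 (N^3 - N)}.$$

Properties the tests rely on: $W$ is invariant to any per-series
strictly increasing transform (it sees only ranks), invariant to a
shared permutation of the time axis, equals 1 for identical tie-free
series, and averages just above $1/K$ on independent noise.

*Tie handling.* Ties receive average (mid) ranks and **no** tie
correction is applied to the denominator, because the plain form above
has none; heavily tied data therefore shrink $W$ below 1. Resting-state
BOLD values are effectively continuous, so this matters only for
degenerate inputs.

*Edge policy.* By default a voxel gets a value only if all 27
neighbourhood members are in the mask (`min_neighbors = 27`). Mixing
K = 27 interior estimates with K < 27 edge estimates biases edge values
(the null level of $W$ scales like $1/K$); interior-only estimation
avoids ranking that bias into the top-percentile sets. Toolboxes that
keep shrinking edge neighbourhoods are mirrored by lowering
`min_neighbors`. Undefined voxels are `NA`, never 0 — a 0 would be a
valid (minimal) concordance and would corrupt percentile thresholds.

### High-ReHo clusters

HRCs are maximal connected components of the top-fraction voxels.
Decisions a user should know:

- **Count rule.** `round(fraction * n_defined)` voxels (round half up)
  are selected; ties at the cutoff break by ascending linear voxel
  index, making selection deterministic.
- **Connectivity.** 26-connectivity by default, consistent with the
  3×3×3 ReHo kernel; 6 and 18 are selectable. Corner-touching blocks
  are one cluster at 26 and two at 6.
- **Grey-matter constraint.** A voxel-wise intersection applied after
  thresholding. It can only remove volume and only split components
  (never merge), so cluster counts per retained voxel cannot decrease.
  Results with and without it are both producible.
- **No minimum cluster size.** Single-voxel clusters are retained.
- **Grid.** Metrics are computed on the native grid; sizes are
  reported in voxels and mm³. A nearest-neighbour resampler is provided
  for visualization and cross-grid comparison; it preserves the
  component topology under integer upscaling.
- **Network labelling.** A cluster is credited to *every* network it
  overlaps by at least one voxel, and a network's mean size averages
  the overlap volumes, not the full cluster sizes. One cluster can
  therefore count in several networks, and per-network counts need not
  sum to the global count; output metadata flags this multiplicity
  rule.

### Scale-free statistics

Cluster sizes are binned into geometric bins $[b^k, b^{k+1})$ (base 2
by default) and normalized per unit size (`density = count /
(width × n)`), the standard variance stabilizer for heavy tails. The
tail exponent is the negative OLS slope of log density on log bin
centre over occupied bins with centre ≥ `s_min_fit` (default 100, the
observed turning point scale). Two deliberate choices:

- Bins that only partially cover the observed size range (the bin
  holding the minimum, and the top bin when the maximum falls inside
  it) are flagged by `log_bin()` and excluded from the fit: a partial
  bin understates its density and tilts the slope.
- The binned OLS route is the primary estimator because it is the
  method the cluster analysis is defined with; a continuous
  maximum-likelihood (Hill) estimator is included as an independent
  cross-check (`fit_powerlaw_mle()`), clearly labelled as such, and the
  tests require the two to agree on large samples.

Pooled (group-level) and per-participant fits are both possible — the
functions take plain size vectors, so pooling is the caller's `c()`.

### The statistical battery

Confounds (education, gender, mean FD) are removed by OLS
residualization with the grand mean added back; the operation is
idempotent and leaves residuals orthogonal to the confounds. Group
contrasts use the classical tests (pooled-variance two-sample t, paired
t on follow-up-minus-baseline differences, Wilcoxon and Kruskal-Wallis
fallbacks, one-way ANOVA); the Group × Threshold design is a mixed
(split-plot) ANOVA via `aov` with an `Error(participant/threshold)`
stratum on the difference scores. Normality routing uses the
one-sample KS test against a normal with estimated mean and SD — the
estimated-parameter variant, whose p-values are conservative; this is
documented rather than hidden, and Shapiro-Wilk is available in base R
for users who prefer it. FDR control is Benjamini-Hochberg within
declared families (within-group, between-group, ANOVA, education).
Zero-variance inputs yield results flagged `defined = FALSE`, never a
silent 0 or p = 1.

## 2. Preprocessing

Order: drop the first 4 frames (scanner equilibration), detrend
(intercept + linear term only), band-pass 0.01–0.08 Hz, regress out the
6 rigid-body motion parameters (trimmed identically). The narration
order of the upstream literature is followed; the stages are separate
functions, so a user can reorder them.

The band-pass is implemented as zero-phase frequency-domain filtering:
the DFT is multiplied by the squared magnitude response of an order-4
Butterworth band-pass — exactly the amplitude response of
forward-backward (filtfilt) time-domain filtering, without its edge
transients, and with a closed-form transfer function the tests evaluate
directly (gain ≈ 1 at 0.04 Hz; < 0.1 at 0.2 Hz for TR = 2 s). The DC
bin is zeroed, so output series are mean-zero. Framewise displacement
is the scalar convention: summed absolute frame-to-frame translation
differences plus rotation differences converted to arc length on a
50 mm sphere; `fd[1] = 0`. FD depends only on motion differences, so it
is invariant to constant offsets in any motion column.

**No spatial operation occurs anywhere in preprocessing** — smoothing
would manufacture local coherence, which is the very quantity under
study. A test asserts that a single-voxel delta keeps exactly
single-voxel spatial support through the whole preprocessing chain.

## 3. The synthetic cohort: what it emulates, and what it does not

The generator exists so that the full pipeline — images to group
statistics — can be validated against a known ground truth. Defaults
mirror the targeted acquisition regime: 32³ voxels at 3 mm, 155 frames
at TR = 2 s (151 after frame dropping), passband 0.01–0.08 Hz.

### Construction

- **Geometry.** An ellipsoidal brain mask; grey matter is the brain
  minus a deep core, cut by thin sulcus-like slit planes — enough
  geometry for the GM constraint to split clusters, with no pretence of
  cortical folding.
- **Patches.** `n_patches` (default 25) contiguous patches are grown by
  6-connected accretion inside grey matter (local-FC hubs are
  cortical; a deep planted core would be an artefact the anatomical
  constraint destroys). Sizes are drawn from a truncated power law
  $P(s) \propto s^{-\alpha}$ on `[27, 500]` voxels. The floor is one
  full ReHo kernel: a coherent patch smaller than the concordance
  neighbourhood cannot form a detectable hot-spot. A 1-voxel shell is
  reserved around each patch, so baseline component count equals the
  requested count. When the cohort generator varies the patch count
  across participants, sizes are rescaled to a fixed total patch
  volume (~10.5% of the brain), so count and mean size trade off at
  near-constant suprathreshold volume — the same identity that links
  the two metrics in the measured data.
- **Signals.** Each patch shares a band-limited Gaussian latent; voxel
  series are $\sqrt{c_v}\,\mathrm{latent} + \sqrt{1-c_v}\,\mathrm{noise}$.
  The coupling $c_v$ peaks at one interior voxel and decays linearly
  with within-patch geodesic distance (default 60% drop at the far
  edge). The gradient matters: a flat-coupling plateau produces a flat
  ReHo plateau whose top-percentile subset fragments into arbitrary
  noise-driven islands, which no real hub does — real hot-spots are
  peaked. Geodesic (not Euclidean) distance keeps every super-level
  set of the profile connected whatever the patch shape. Peak coupling
  grows mildly with patch size (`(size/27)^0.15`, capped at 0.95),
  reflecting that larger hubs carry higher peaks; without some size
  dependence all peaks tie and percentile selection among them is
  decided by noise.
- **Training effect.** `training_effect` is the fraction of a
  completer's patches that merge with their nearest neighbour at
  follow-up (default 0.7): the closest centroid pairs are joined by
  short, thick 6-connected bridges and share one latent afterwards.
  This raises integration — count down, mean size up — while total
  coherent volume stays nearly constant. Literal isotropic dilation
  was rejected during design: at realistic packing density it either
  merges nothing or almost everything, and it inflates coupled volume
  several-fold, both of which distort the threshold analysis in ways a
  training intervention would not. Bridges are thickened because a
  1-voxel neck depresses the concordance field (partial
  neighbourhoods) and would split the merged hub right back apart at
  high thresholds.
- **Confounds.** Education (years, ~N(10, 4²) clipped) shifts log
  patch count with slope `education_slope` (default −0.04/year), so
  more educated participants have fewer, larger hubs at baseline;
  gender adds a small shift; the per-participant motion scale is
  log-linearly tied to baseline patch count (`fd_slope`), giving FD the
  confound correlation the residualization step is meant to absorb.
  Motion traces are random walks calibrated to mean FD ≈ 0.1–0.2 mm.
- **Attendance.** Trainees draw 0–27 attended sessions with a
  configurable fraction below the >19-session completion cut-off;
  controls have `NA` attendance and never receive the training effect.

Bundles are regenerated deterministically from per-row seeds rather
than held in memory (an 80-scan cohort at this size is ~3 GB); the same
row always reproduces the same images, byte for byte.

### What passing tests do and do not show

The generator produces peaked, compact, anatomically embedded coherent
patches with known count, sizes, and confound structure. It does **not**
emulate haemodynamic response shapes, physiological (cardiac or
respiratory) noise, scanner drifts beyond a linear trend, spatial
autocorrelation of the background noise, registration error, or
realistic cortical folding. Consequently, a green suite demonstrates
that the *estimators and inference machinery* recover known structure
through the full pipeline — not that any particular empirical effect in
human data is true, nor that effect sizes here transfer to real
cohorts. The planted training effect is deliberately strong so that
directional failures signal implementation errors rather than power
limits; the age-contrast magnitude is parameterized, not calibrated,
because no quantitative target for it is available.

## 4. Numerical choices and degenerate inputs

- ReHo values are clamped to [0, 1] against last-ulp round-off; the
  map equals a brute-force per-voxel oracle to 1e−12.
- `mean_size × n_clusters = total_voxels` holds as an exact identity
  (mean is derived as total/n); empty cluster sets report
  `mean_size = NA`, flagged rather than 0.
- Threshold tie-breaks, cluster id ordering (descending size, then
  smallest linear index), and the shuffle permutation are all
  deterministic under a seed; pipeline outputs are byte-identical
  across runs with the same configuration.
- Rank-deficient nuisance or confound designs abort with the offending
  columns named; `n_drop ≥ t`, empty masks, out-of-range thresholds,
  short tails (< 3 occupied bins), and sub-minimal group sizes are all
  explicit errors, not warnings.
- The mixed ANOVA requires every participant to have all threshold
  cells and names the participants that do not.

## 5. Problem sizes used in validation

The test suite validates oracle equivalences on small grids (6³–8³
volumes, 20³ binary volumes for component labelling), calibration at
200 replicates per test, exponent recovery at 20 000 sampled sizes, and
the full longitudinal battery on a 20 + 20 cohort at the default
32³ × 155 scale — the same configuration `scripts/acceptance.R`
re-runs. These sizes were chosen so the planted effects are
unambiguous at the cohort size of the emulated study design.

## 6. Known limitations

- The KS normality gate uses estimated parameters and is conservative;
  it exists to mirror a common workflow, not as a recommendation.
- The binned-OLS exponent estimator carries the usual small positive
  bias at short tails; the MLE cross-check bounds it in the tests.
- Per-network counting with multiplicity means network counts are not
  a partition of the global count (flagged in output).
- The generator's background noise is spatially white; real BOLD noise
  is smooth, which would raise the null level of cluster sizes under
  shuffling. The shuffle control compares structured and shuffled
  versions of the *same* map, so this limitation does not affect that
  contrast's direction.
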