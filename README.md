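# rehohub

Local functional-connectivity hub analysis for resting-state fMRI:
regional homogeneity (ReHo) maps, high-ReHo clusters (HRCs), scale-free
cluster-size statistics, and longitudinal two-group comparisons.

## The scientific problem

Resting-state BOLD signal is locally coherent: a voxel's time course
tends to agree with its immediate neighbours, and the strength of that
agreement — *regional homogeneity* — marks local functional-connectivity
hubs. `rehohub` quantifies how those hubs are organized and whether an
intervention (e.g., cognitive training in older adults) changes their
*integration*: fewer, larger hubs versus many small ones.

The core quantities:

- **ReHo** at a voxel is Kendall's coefficient of concordance *W* over
  the K = 27 time series of its 3×3×3 neighbourhood, each ranked along
  time:

  $$W = \frac{\sum_{i=1}^{N} R_i^2 - N\,\bar R^2}{\tfrac{1}{12} K^2 (N^3 - N)}$$

  where $R_i$ is the sum of the K ranks at time point $i$, $\bar R$
  their mean, and $N$ the number of frames. $W = 1$ for perfectly
  concordant series, ~0 for independent noise.

- **HRCs** are the connected components (26-connectivity by default) of
  the top 5/10/15/20% ReHo voxels, optionally intersected with the
  individual grey-matter mask so that a cluster straddling a sulcus is
  split into its anatomically distinct parts.

- **Integration** of local FC is summarized per participant as the mean
  HRC size or, inversely, the HRC count; the HRC size distribution has a
  power-law tail whose exponent α is estimated by OLS on
  logarithmically binned densities in log-log coordinates,
  $p(s) \propto s^{-\alpha}$ above a turning point (~100 voxels).

- The group battery covers confound residualization (education, gender,
  framewise displacement), paired and two-sample t-tests with
  non-parametric fallbacks, a mixed Group × Threshold ANOVA on
  before–after differences, Spearman/Pearson correlations, and
  Benjamini–Hochberg FDR.

Because the kind of cohort this pipeline targets is rarely shareable,
the package ships a synthetic-cohort generator that plants contiguous,
power-law-sized patches of band-limited (0.01–0.08 Hz) coherent signal
in a 4D volume, with a two-group × two-timepoint design, a training
effect that merges neighbouring patches, and education/gender/motion
confounds — so every stage is testable end to end.

## Worked example

```r
library(rehohub)

# one synthetic participant: 32^3 voxels, 155 frames at TR = 2 s
p <- simulate_participant(simulation_config(seed = 1))

# preprocess: drop 4 frames, detrend, 0.01-0.08 Hz band-pass,
# regress out the 6 motion parameters
pre <- preprocess_bold(p$bold, p$motion, mask = p$brain_mask)

# voxel-wise ReHo and HRC extraction at the 10% threshold
map <- compute_reho(pre$bold, p$brain_mask)
hrcs <- extract_hrcs(map, 0.10, gm_mask = p$gm_mask)
glance(hrcs)
#> # A tibble: 1 × 4
#>   n_clusters mean_size total_voxels connectivity
#>        <int>     <dbl>        <int>        <int>
#> 1         25      35.7          892           26

# power-law tail of a size sample via logarithmic binning
set.seed(7)
sizes <- sample_patch_sizes(20000, alpha = 2.5, 100, 1e4, continuous = TRUE)
fit <- fit_powerlaw(log_bin(sizes), s_min_fit = 100)
fit
#> <powerlaw_fit> alpha = 2.502 (SE 0.016), tail s >= 100, 6 bins, R^2 = 1.000
```

The participant has 25 high-ReHo clusters covering 892 grey-matter
voxels (mean 35.7 voxels ≈ 963 mm³ at 3 mm resolution), and the binned
tail regression recovers the planted exponent 2.5 to within its
standard error.

A full longitudinal study — simulate a cohort, run every scan through
preprocessing/ReHo/HRC extraction, then the statistics preset — is one
call:

```r
run <- run_pipeline(
  cohort_design(n_per_group = 20, groups = c("multi-domain", "control"),
                fraction_incomplete = 0),
  simulation_config(seed = 101))
dplyr::filter(run$stats, family == "within_group", threshold == 0.10)
```

which prints, for training completers at the 10% threshold, a
significant drop in HRC count (t(19) = −11.2, p ≈ 9e−10) and rise in
mean HRC size (t(19) = 12.2, p ≈ 2e−10), and no change in controls —
the planted integration effect, recovered through the full image
pipeline.

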