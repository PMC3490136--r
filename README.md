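# fenica

Fully exploratory network ICA (FENICA) for multi-study resting-state fMRI,
as an R package.

Resting-state BOLD signal fluctuates coherently at 0.01–0.1 Hz across
distributed brain networks. Spatial ICA recovers such networks one subject
at a time, but leaves the group problem open: components arrive unordered,
unsigned, and in subject-specific numbers. FENICA builds group components
bottom-up from single-subject decompositions, in three stages:

1. **candidate pairs** — the spatial correlation r(m_i, m_j) is computed for
   every cross-subject pair of component z-maps, and the top K pairs seed
   candidates, with K calibrated to the total single-subject component
   count;
2. **candidate averages** — each seed pair's mean map is matched to every
   subject's best-correlating component (sign-aligned); the candidate's
   group map is the voxelwise mean of the matched maps and its rank key is
   the voxelwise sum of positive one-sample t-values,
   `t_sum = Σ_v max(t_v, 0)` with `t_v = mean_v / (sd_v/√n)`;
3. **final selection** — candidates are accepted greedily by descending
   `t_sum`, discarding any candidate whose correlation with an accepted one
   exceeds a similarity threshold chosen as the lowest grid value (0.50–0.95,
   step 0.01) that yields as many final components as the median
   single-subject model order.

Around that core the package provides the full analysis chain: preprocessing
(8 mm FWHM Gaussian smoothing, tissue-mean/motion nuisance regression,
0.01–0.1 Hz zero-phase bandpass), per-subject spatial ICA with automated
model-order estimation (the Laplace / Minka evidence of a probabilistic-PCA
model, "LAP"), subject-level consistency distributions, hierarchical
clustering of components by Kolmogorov–Smirnov distance, spectral metrics of
back-reconstructed timecourses (dynamic range; power ratio = power below
0.1 Hz over power above 0.15 Hz), per-study re-analysis with bidirectional
partner matching, robust OLS/MM meta-regression of model order on scan
duration, and a multi-study synthetic cohort generator that makes every
stage testable without real data. It is aimed at methods researchers who
want a transparent, fully scriptable implementation of component-averaging
group ICA at desk scale.

## Worked example

```r
library(fenica)

## the packaged multi-study metadata table: duration = TR x volumes
st <- fcon1000_studies()
summary(st)
#> 33 studies from 26 centers, 1285 subjects
#> scan duration 216.0-590.0 s, TR 1.00-3.00 s

## does scan duration drive the estimated model order?
duration_order_regression(st)
#> OLS fit (n = 33): slope 0.024068 (se 0.00519), intercept 7.3819, p = 6.11e-05
#> MM fit (n = 33): slope 0.024981 (se 0.0054), intercept 7.0435, p = 6.22e-05
```

Both estimators agree: every extra minute of scanning adds ~1.5 to the
median number of estimated components, and the association is significant
at p < 1e-4.

```r
## a synthetic 3-study cohort with 5 planted networks + 1 CSF artifact
co <- simulate_cohort(cohort_spec(seed = 1))
pl <- fenica_pipeline(co, seed = 1)
pl$fit
#> FENICA fit: 40 group components from 12 subjects (472 candidates)
#> similarity threshold 0.74 (target count 40, median order 40)

match_to_truth(group_maps(pl$fit), co$truth)[, 1:3]
#>   source is_artifact best_abs_r
#> 1   net1       FALSE  0.9297226
#> 2   net2       FALSE  0.9760333
#> 3   net3       FALSE  0.9637474
#> 4   net4       FALSE  0.9631630
#> 5   net5       FALSE  0.9615496
#> 6   art1        TRUE  0.7322928
```

All six planted sources are recovered (networks at r > 0.92; the CSF
artifact at r = 0.73 — it survives CSF-mean regression only through its
spatial structure). The artifact's spectral metrics separate it from the
networks exactly as expected for a high-frequency pulsation source: its
component scores dynamic range 5.6 and power ratio 0.96, against 11.0–13.8
and 3.8–5.4 for the five network components. Per-subject model orders
(38–40) reflect the in-band temporal dimension of the bandpassed series,
which grows with scan duration — the mechanism probed by the regression
above.

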