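---
title: "Methods: fully exploratory network ICA at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fully exploratory network ICA at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the method

Resting-state fMRI shows coherent low-frequency (0.01–0.1 Hz) BOLD
fluctuations organized into spatially reproducible networks. Spatial ICA
decomposes a single subject's 4D scan into statistically independent spatial
maps with associated timecourses, but offers no canonical way to combine
decompositions across subjects: components arrive unordered, unsigned and in
subject-specific numbers.

Fully exploratory network ICA (FENICA) solves the group problem bottom-up.
Every subject is decomposed separately; group components are then built by
matching and averaging single-subject z-maps:

1. **Candidate pairs.** Spatial (Pearson) correlations are computed between
   all cross-subject pairs of component maps; the top pairs seed candidates.
   This package calibrates the number of eligible pairs automatically to the
   total number of single-subject components, so no hand-set pair threshold
   enters.
2. **Candidate averages.** Each seed pair's mean map is matched against every
   subject (the component with maximal signed correlation, sign-flipped when
   negative); the candidate's group map is the voxelwise mean of the matched
   maps, its voxelwise one-sample t-statistic summarizes evidence across
   subjects, and the sum of positive t-values (`t_sum`) is its rank key.
3. **Final selection.** Candidates are accepted greedily in descending
   `t_sum` order, discarding any candidate correlating above a similarity
   threshold with an already-accepted one. The threshold is chosen as the
   lowest value on a 0.50–0.95 grid (step 0.01) whose final component count
   equals the median single-subject model order — again removing an
   observer-chosen parameter.

Downstream, the package quantifies **subject-level consistency** (the
distribution over subjects of the correlation between a component's seed
average and each subject's best-matching map), clusters components by the
**Kolmogorov–Smirnov distance** between their map value distributions,
computes **spectral metrics** of back-reconstructed component timecourses
(dynamic range; power ratio), re-runs the whole analysis per study and
**partner-matches** study components to group components (mutual best
match), and fits **meta-regressions** (OLS and a robust MM-estimator) of
per-study median model order on scan duration.

## Model order: the Laplace (PPCA evidence) criterion

`estimate_model_order()` implements the Laplace approximation to the model
evidence of a probabilistic-PCA model, evaluated on the eigenvalues of the
time-by-time covariance with voxels as observations (Minka's criterion —
the published meaning of the "LAP" option in MELODIC-style pipelines). Two
documented properties matter in practice:

* **Exact rank deficiency.** When the covariance is numerically rank
  deficient — noiseless low-rank data, or series whose hard bandpass
  annihilated all out-of-band temporal dimensions — the PPCA likelihood is
  unbounded at the numerical rank, which is returned (capped at `q_max`).
  A consequence worth stating plainly: on the synthetic cohorts generated
  here (white sensor noise, discrete-Fourier bandpass), the estimated order
  equals the number of in-band frequency dimensions, which grows linearly
  with scan duration. This is the mechanism behind the positive
  duration/model-order relationship the meta-regression detects. Real
  scanner noise is broadband and colored, so real-data orders sit well
  below the in-band rank; the qualitative duration dependence is the same.
* **Not a pure function of the covariance.** The voxel count enters the
  evidence beyond the eigenvalues (likelihood sharpness and curvature
  penalties), so transformations that preserve the covariance but change
  the nominal sample count — duplicating every voxel, say — can shift the
  estimate when the eigen-spectrum is marginal. Rescaling the data, by
  contrast, provably never changes the estimate.

## Spatial ICA

`run_spatial_ica()` whitens to the `q` leading principal components over
the spatial dimension and runs a symmetric fixed-point negentropy ICA
(tanh contrast, tolerance 1e-4, up to 200 iterations, up to 5 seeded
restarts). Conventions, fixed before any cross-subject matching:

* maps are z-scored over in-mask voxels (mean 0, sd 1). A probabilistic-ICA
  noise-model z-statistic is deliberately not used: plain standardization
  keeps every downstream correlation well defined without committing to a
  noise model;
* each component's sign is set so its voxelwise skewness is non-negative
  (networks are sparse positive activations). Matching then uses signed
  correlations throughout — absolute correlations would silently merge
  anticorrelated maps.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fwhm_mm` | 8 mm | Gaussian smoothing FWHM; `sigma = fwhm/(2*sqrt(2*ln 2))` |
| `band` | 0.01–0.1 Hz | temporal pass band (canonical resting-state band) |
| `q_max` | 40 | model-order cap, low-model-order regime |
| threshold grid | 0.50–0.95 by 0.01 | two-decimal resolution of the reported threshold |
| `t_cap` | 100 | finite stand-in for infinite t at zero-variance voxels |
| `strong_cutoff` | 0.75 | study-level "strong match" correlation cutoff |

Nuisance regression uses mean CSF, white-matter and gray-matter signals,
motion traces (dropped when constant), an intercept and a linear trend. The
pipeline order is fixed — smooth, regress, filter — and regressors are not
themselves filtered; whether filtering nuisance regressors first would be
preferable is a known open question in the preprocessing literature, and the
literal order is kept. Global (gray-matter) signal regression is retained
for fidelity to the emulated preprocessing despite the later controversy
around it.

## Numerical choices

* **Filter realization:** discrete-Fourier masking after linear detrending.
  Exactly zero-phase, platform-reproducible, idempotent up to leakage;
  pass-band retention of an in-band tone is within 5% and stop-band leakage
  below 5% at twice the band edge.
* **Tie-breaks:** candidate pairs order by correlation rounded to 1e-10,
  then lexicographically by (subject, component) identity; candidates order
  by `t_sum` rounded to 1e-8, then seed-pair identity. Rounding makes
  floating-point near-ties resolve deterministically.
* **Degenerate voxels:** a candidate voxel with zero across-subject variance
  gets `t = ±t_cap` (sign of the mean) rather than infinity.
* **Median model order** rounds half up (2.5 becomes 3) — the rounding
  direction is otherwise unspecified and must be deterministic.
* **Partner-match ties** void the match rather than picking arbitrarily: a
  mutual best match must be unique on both sides.
* **Exact-fit MM regression:** with zero residual scale the M-step is
  undefined; the least-squares solution is returned as the MM limit.
* **MM tuning:** bisquare psi at 95% Gaussian efficiency (c = 4.685), S-stage
  subsampling under a fixed internal seed so fits are reproducible.

## The synthetic cohort: what it emulates, and what not

`simulate_cohort()` generates a multi-study collection on a spherical
three-compartment phantom (CSF core, white-matter shell, gray-matter
shell; 20^3 voxels at 3 mm by default):

* **Networks** (default K = 5): unit-L2 Gaussian blobs centered in gray
  matter, pairwise |r| < 0.4 (an option plants one overlapping
  anterior/posterior-style pair at r in [0.4, 0.7]); timecourses are white
  noise band-limited to 0.01–0.1 Hz; amplitude ~ N(1, 0.25) relative to
  unit-sd sensor noise.
* **Artifacts** (default A = 1): blobs confined to the CSF core with width
  1.1 voxels — deliberately finer than the CSF compartment, because
  mean-CSF regression removes the spatially uniform part of any CSF signal
  by construction; only spatially structured CSF fluctuations can (and, in
  real data, do) survive it. Amplitude ~ N(3, 0.75): CSF pulsation is among
  the strongest fluctuation sources in fMRI. Timecourses place 65% of their
  variance above 0.15 Hz, mimicking aliased cardiorespiratory pulsation,
  with a low-frequency remainder.
* **Subject variability:** an integer-voxel random translation (sd 1.5 mm),
  a smooth multiplicative amplitude field (sd 0.15), and the amplitude
  draws above. These produce subject-level consistency correlations around
  0.5–0.8 on the default cohort — more consistent than real cohorts, whose
  anatomy, vasculature and registration error this phantom does not model.
* **Study heterogeneity:** three studies of four subjects with TR 1–2 s and
  durations spanning 216–590 s.

Passing end-to-end tests on this generator demonstrates that the algorithm
chain is correct and that its contracts (recovery, spectral ordering,
consistency ordering, duration dependence) hold under a controlled model of
the data. It does not demonstrate performance on real scans: no anatomy, no
motion, no colored or spatially structured noise, no registration error,
and sensor noise that is white by construction.

Spectral characterization back-reconstructs component timecourses (the
spatial-regression stage of dual regression, solved jointly over all group
maps so overlapping maps are separated correctly) from the smoothed,
nuisance-regressed but **unfiltered** data: measuring power above 0.15 Hz
after a 0.1 Hz low-pass would be meaningless, and the artifact/network
separation of the power ratio lives exactly in that band. Per-subject
spectra are unit-normalized before averaging across heterogeneous TRs so
that no study dominates by trace length.

## Design points that were genuinely open

* **`t_sum` over positive t only.** Summing signed t-values would let
  negative lobes cancel ranking mass; the positive-part sum behaves as the
  energy-like rank key the selection stage needs. Both interpretations are
  defensible; positive-part is the default.
* **Centroid vs complete linkage.** The clustering of components by KS
  distance supports both (`linkage =` flag); centroid is the default, and
  complete linkage — whose merge heights are provably monotone — is used
  where a monotone dendrogram is wanted. The package asserts neither as
  canonical.
* **Single matching pass.** The seed average is not iteratively re-matched
  after averaging; one pass keeps the estimator simple and deterministic.
* **Pipeline problem sizes.** Tests and the acceptance script run the
  default 12-subject cohort (about 3,000 in-mask voxels, 108–295 volumes),
  with smaller grids for property sweeps; these sizes were chosen so the
  full chain exercises every stage while a complete run stays interactive.

## Known limitations

* The phantom is geometric, not anatomical; tissue compartments are
  concentric shells.
* Sensor noise is white; consequently model orders on filtered synthetic
  data equal the in-band rank (see above) and sit higher than typical
  real-data orders at the same duration.
* FENICA's own core assumption is inherited: a group component must be
  present in (nearly) every subject to be found, since every subject's best
  match enters the average.
* The MM-estimator follows the classical S-then-M construction at 95%
  efficiency; the exact tuning of published alternatives (e.g. the
  SMDM variant) differs in small samples.
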