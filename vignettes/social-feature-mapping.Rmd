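---
title: "Mapping social features in naturalistic fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping social features in naturalistic fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`socmap` implements an annotation-driven analysis of naturalistic fMRI: the
moment-to-moment prominence of social and non-social stimulus features,
rated continuously by independent observers, predicts the BOLD signal in a
mass-univariate GLM; second-level maps, overlap counts, spherical-ROI
summaries, and a permutation-thresholded functional-connectivity graph with
map-equation communities follow. This vignette explains the models, the
tunable parameters, the synthetic-data generator used to validate the
chain, and the design decisions taken where the procedure was genuinely
underdetermined.

## From ratings to regressors

Two raters track each of 14 features per clip at `rating_rate_hz = 5` Hz on
a 1–5 prominence scale. The chain is:

1. **Average raters** element-wise per (clip, feature) track.
2. **Concatenate clips** in the presentation order; the stimulus has no
   gaps, so sample indices are continuous.
3. **Down-sample to the TR grid** (`tr_s = 2.112` s): output volume *k* is
   the mean of the raw samples whose centers `(i − 0.5)/rate` fall in
   `[(k−1)·TR, k·TR)`, and the partial final window is dropped
   (`floor(duration/TR)` volumes). Averaging within windows, rather than
   decimation, is the conservative anti-aliasing reading of "down-sampling"
   for a 5 Hz → 0.47 Hz conversion. Because window averaging is linear, it
   commutes with rater averaging and with affine rescaling of the values —
   properties the test suite asserts.

Diagnostics: per-feature inter-rater Pearson r (with the unweighted mean
across features as the headline reliability) and the 14×14 between-feature
correlation matrix of the regressors.

A note on scan length: at the nominal design scale the clip durations sum
to more than the acquisition (770 volumes × 2.112 s), so the synthetic
session truncates the concatenated rating track at the end of the scan.
The first two acquired volumes are equilibration scans and are discarded;
regressor volume *k* corresponds to retained volume *k*.

## The first-level model

Each voxel's series is regressed on the 14 feature regressors (optionally
HRF-convolved), an orthonormal discrete-cosine drift basis, and an
intercept:

* **HRF.** `hrf_mode = "canonical"` convolves with the double-gamma
  response (gamma shapes 6 and 16, undershoot ratio 1/6, unit peak; peak
  at ~4.2 s on the TR grid). Whether the original analysis convolved the
  rating regressors is not stated anywhere in its description, so
  `hrf_mode = "none"` is also provided; the default is `"canonical"`
  because BOLD responses lag their drivers, and regressor–response
  alignment otherwise relies on the ratings' own sluggishness.
* **Drift.** DCT-II columns with periods longer than
  `highpass_cutoff_s = 128` s; `K = floor(2·n·TR/cutoff)` columns (25 at
  n = 768). The floor convention only changes near-cutoff drift capture by
  one column either way.
* **AR(1) prewhitening.** One pooled ρ per subject (not voxelwise): the
  lag-1 autocorrelation of OLS residuals pooled over in-mask voxels.
  Two refinements matter numerically. First, the estimation model excludes
  the drift basis: DCT columns absorb exactly the low frequencies where
  AR(1) power lives, biasing ρ̂ down by ~0.07 at ρ = 0.4 (the fit itself
  keeps the drift columns; feature betas are unchanged by orthogonal
  drift). Second, ρ̂ is refined iteratively — whiten, re-estimate the
  residual lag-1 autocorrelation, step ρ̂ — until the whitened residuals
  are uncorrelated. Whitening is exact for a stationary AR(1): the first
  sample is scaled by `sqrt(1 − ρ²)`, later samples become
  `y_t − ρ·y_{t−1}`; with W the filter, `W'W ∝ Σ⁻¹`, so whitened OLS
  equals dense GLS in both betas and standard errors (asserted against a
  full-covariance oracle at small T).
* **Modes.** `glm_mode = "combined"` fits all 14 regressors at once;
  `"per_feature"` fits each feature with only drift + intercept as
  covariates (the mode in which single-feature beta summaries are usually
  displayed), implemented by Frisch–Waugh projection against the shared
  nuisance block — algebraically identical to the separate GLMs, asserted
  in the tests.

## Orthogonalization

To isolate each feature's unique contribution, every regressor can be
residualized against **all 13 other original regressors simultaneously**
(plus an intercept). A sequential Gram–Schmidt scheme would depend on
feature order and could not be summarized by one weight vector per feature;
the simultaneous fit can, and the ledger records those weights (positive =
subtracted) and the R² of each fit. Properties asserted: residuals are
orthogonal to every other original column at `1e-8` relative tolerance,
the ledger reconstructs each original regressor exactly, and
re-orthogonalizing a residual is a no-op.

By default residualization happens on the rating time courses before HRF
convolution (`ortho_stage = "pre_hrf"`), mirroring the order in which the
procedure is described; because convolution re-mixes time points,
post-convolution orthogonality is then only approximate, so
`"post_hrf"` is available when exact orthogonality in the fitted space is
wanted.

**Why the pipeline's "original" mode is the combined GLM.** All subjects
see the same stimulus, so regressors are identical across subjects and any
omitted-variable bias in a per-feature fit — `E[β̂_f] = β_f + Σ_g β_g r_fg`
for correlated features — is systematic, not noise. With 19 subjects and
768 volumes, group-level standard errors are small enough that even modest
leakage (mean |r| ≈ 0.18) becomes "significant" at planted null locations,
which is precisely the interpretive hazard orthogonalization is meant to
expose. The overlap pipeline therefore pairs the **combined** GLM (original
regressors; unbiased because every other feature is a covariate) with
**per-feature fits on orthogonalized regressors** (unbiased because the
residual regressor is orthogonal to all other originals). The
per-feature-on-raw mode remains available and is the right mode for
single-feature beta displays.

## Second level, FDR, and overlap maps

Random effects: a voxelwise one-sample t-test of subject betas against
zero (df = n − 1, two-sided), and a paired t-test implemented literally as
the one-sample test on differences. Voxels with zero between-subject
variance get t = 0, p = 1 — conservative, and it avoids infinities.

Significance is Benjamini–Hochberg over all in-mask voxels at
`fdr_q = 0.05` (the contemporaneous voxel-FDR convention; computed via
`p.adjust`, with the sorted-threshold construction `p* = max{p_(k) ≤
k·q/m}` asserted against a brute-force oracle). Overlap maps count, per
voxel, how many of the 8 social features are significant **with positive
effects** (t > 0): cumulative activation counts activation, not
deactivation. No correction across the 14 features is applied by default,
matching the reported analysis; a Bonferroni-by-14 switch would only
rescale q.

## ROIs

Spheres are defined in world (MNI mm) coordinates as closed balls over
voxel centers — no partial-volume weighting, since no such rule is stated;
on a 2 mm grid a 3 mm sphere holds exactly 19 voxels and a 6 mm sphere 123
(lattice-enumeration oracle in the tests). Beta summaries use 3 mm spheres
(`roi_radius_beta_mm`) and t-based 95% CIs of the across-subject mean —
t-based rather than normal-based, the correct small-sample interval at
n = 19. Connectivity time series use 6 mm spheres (`roi_radius_conn_mm`)
for signal-to-noise. Internally, R's 1-based array indices map to 0-based
voxel indices before the affine; all user-facing coordinates are mm.

## Connectivity, the permutation null, and communities

Subject-level ROI–ROI Pearson correlations are Fisher-z transformed,
averaged across subjects, and inverse transformed. The significance
threshold comes from circular-shift surrogates: per permutation, every
subject independently picks a seed ROI, rotates its series by a uniform
shift in `[min_shift_samples, T − min_shift_samples]` (min 10 samples;
rotation preserves the marginal distribution and, up to wrap effects, the
autocorrelation), and correlates it with all other ROIs. The null
statistic mirrors the statistic being thresholded, so the seed-to-target
correlations are Fisher-z averaged **across subjects** per permutation and
the threshold is the maximum pooled |r| (a per-subject-pooled variant is
available behind `pooling = "subject_pool"`). Edges use strict inequality
`|r| > threshold`, since the threshold is itself the maximum of a pure
null. The implementation evaluates all shifts via FFT cross-correlation
stacks and is asserted equal to the direct brute-force loop; draws are laid
out permutation-major so a longer run extends a shorter one under the same
seed.

Community structure minimizes the two-level **map equation**: with visit
rates `p_i` proportional to node strength and module exit rates `q_m`
given by boundary-crossing probabilities,
`L = q·H(q_m/q) + Σ_m (q_m + Σ_{i∈m} p_i)·H(·)` bits per step — for a
single module, exactly the entropy of the visit rates (closed-form star
example in the tests). No teleportation: these are undirected correlation
graphs. The search is greedy node moves (to neighboring modules or a fresh
singleton) to convergence, then best-pair agglomeration, repeated until
stable, restarted `n_community_restarts = 100` times from singleton
assignments with random sweep orders; the lowest-L partition wins, ties
(within 1e-10 bits) resolved to the lexicographically smallest canonical
labeling, and the fraction of restarts reproducing the winner is reported
as the modal fraction. `igraph::cluster_infomap` serves as an independent
cross-check in the tests, never as the implementation.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* **Ratings.** Per clip (137 clips, durations truncated-normal 16.6 ± 2.7 s
  in [10.3, 27.3] s), latent feature tracks are Gaussian processes
  (squared-exponential kernel, length scale 2 s — raters moved a cursor
  continuously, so tracks are smooth) correlated across features by a
  target matrix and mapped onto [1, 5] by `3 + 2·tanh(g/2)`. Each rater
  adds independent smooth noise on the latent scale
  (`rater_noise_sd = 0.52`; the Gaussian-scale reliability is
  `1/(1 + sd²)`, and the default was calibrated once, through the mild tanh
  attenuation, to a mean inter-rater r near 0.78). The default correlation
  target combines base levels (0.23 within the social and non-social sets,
  0.09 across) with conceptually coupled pairs near 0.5 (faces–social
  interaction, objects–rigid motion, bodies–biological motion, …), giving
  a realized mean between-feature |r| near 0.18. Both calibration targets
  are checked by the acceptance suite at the 137-clip scale with a ±0.05
  band.
* **BOLD.** Voxel series are `Σ_f β_f(v)·x_f(t)` plus stationary AR(1)
  Gaussian noise (ρ = 0.4, marginal SD `noise_sd = 2` — roughly twice the
  planted amplitude, so single-subject effects are clear but not
  noise-free); per-subject betas jitter around the planted values
  (`subject_sd = 0.25`) for a random-effects structure. The default
  geometry is a desk-scale 24³ grid at 4 mm with a spherical brain mask;
  planted spheres (8 mm) comprise one hub (all 8 social features, no
  non-social), four specialized regions with strict social subsets, and
  two non-social regions. Spatial smoothing is available
  (`smooth_fwhm_mm`) but defaults to 0: smoothing convolves the planted
  beta map and makes exact per-voxel recovery ill-defined, which would
  blur the very ground truth the tests recover. Subject *i* draws from
  child seed `f(seed, i)`, so studies can be generated subject-by-subject
  (streamed) with identical results.
* **What it does not emulate.** Motion, physiological noise, scanner
  drift beyond the drift basis, field inhomogeneity, or hemodynamic
  variability across regions. Passing recovery tests therefore shows the
  statistical chain is correct and calibrated under its stated noise
  model — not that the preprocessing of real data (realignment, bias-field
  removal, registration, smoothing), which is out of scope here, is
  handled.

## Numerical choices and degenerate inputs

Orthogonality assertions use `1e-8` relative to column norms; rank
deficiency raises a collinearity error naming the dependent set; zero
variance anywhere a correlation is needed raises an undefined-correlation
error rather than NaN; Fisher averaging refuses |r| = 1 (saturation);
`p.adjust`-based BH handles m = 1 through large m identically to the
sorted construction; stat maps carry NaN outside the mask and p ∈ [0, 1]
inside by construction. Community-detection ties and overlap-peak ties
break deterministically (lexicographic canonical labels; highest t then
lowest index).

## Problem sizes used in validation

The test suite exercises the full design scale where the property demands
it — 19 subjects × 768 volumes × 24³ voxels for beta-recovery calibration
and for 20 seeded hub-recovery runs, T = 768 with 14 ROIs × 19 subjects ×
10⁴ permutations × 100 replicate experiments for the permutation null —
and small instances (T ≤ 50, toy grids) for exact oracle equivalences.
The acceptance script (`scripts/acceptance.R`) reruns the full-scale study
once per invocation with all randomness derived from `--seed`.

## Known limitations

One pooled AR(1) per subject (voxelwise noise models out of scope);
two-level map equation only (no hierarchy, no directed flow); Pearson r as
the only reliability measure (no ICC); no cluster-extent or permutation
voxel inference; the BOLD-derived connectivity graph of the default
synthetic study is dominated by shared stimulus drive, so its community
structure is near-degenerate — planted-partition graphs are the sharper
test bed for the community machinery, and both are reported by the
acceptance script.
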