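---
title: "Estimating the decay of fMRI adaptation: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the decay of fMRI adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Repeating a stimulus suppresses the neural response to it (adaptation);
the response recovers as the interval between repetitions grows.  In a
block-design auditory fMRI experiment where each block fixes the trial
onset asynchrony (TOA) — here at 3, 6, 9 or 15 s — the block-wise BOLD
amplitude `beta` therefore grows with TOA, and the speed of that
recovery is summarized by a time constant.  This package implements the
full analysis chain for such experiments:

1. block-wise GLM amplitudes, one `beta` per TOA condition;
2. the exponential recovery model
   `beta(TOA) = a + b * exp(-TOA / tau)`,
   with `a` the asymptotic BOLD level (signal units), `b` the magnitude
   of adaptation (signal units), and `tau` the time constant (seconds);
3. nonparametric group comparison of `tau` (Mann-Whitney U, effect
   size `r = z / sqrt(N)`), voxelwise and per region of interest (ROI);
4. Monte-Carlo cluster-extent correction for whole-brain maps.

A seeded synthetic-cohort generator with known ground truth exercises
every stage without any external data.

## The forward model and the generator

A run is laid out as four sequential constant-TOA blocks of 16 trials
separated by a rest gap, three runs per subject.  Trials are modeled as
unit impulses at their onsets (a boxcar duration is available; the
impulse is the default because only block-level amplitudes are
analysed).  The impulse train of each block is convolved with a
two-gamma hemodynamic response function (HRF) and scaled per voxel by
the decay-model amplitude of that block's TOA.  On top of the noiseless
forward model the generator adds:

* i.i.d. Gaussian noise with SD `sigma` (optionally smoothed spatially
  and rescaled back to marginal SD `sigma`);
* a slow cosine drift per voxel, with random frequency of 1–3 cycles
  per run, random phase, and amplitude uniform on `[0, drift_amp]` —
  exactly the band the high-pass stage removes.

Subjects draw `(a, b, tau)` around group centers; `tau` is drawn on the
log scale (lognormal between-subject variability) so it stays positive
and right-skewed, which is how time constants behave empirically.

### Chosen study conditions

Group sizes 19 (control) and 20 (dyslexic), TOAs {3, 6, 9, 15} s, 16
trials/block, three runs of four blocks, TR = 1 s, 3 mm isotropic
voxels: these are the design constants of the experiment the generator
emulates.  Quantities the protocol does not pin down were fixed once,
as follows:

* **Inter-block gap 20 s** — long enough that a 32 s HRF tail decays to
  a negligible level before the next block's response builds; block
  order ascending by TOA (deterministic; the in-scanner order is not
  documented, so it is a parameter).
* **Group tau centers 10 s vs 5 s** — a twofold difference on the order
  of the measured TOAs, representing the "consistently faster decay"
  contrast under study.
* **Between-subject SD 0.2 on log-tau** (~20% coefficient of
  variation), and small between-subject spread on `a` (SD 0.05 around
  0.5) and `b` (SD 0.1 around 1.0).
* **Noise SD `sigma = 0.3`** — calibrated once by scanning `sigma` on
  single synthetic subjects through the standard pipeline until the
  dispersion of single-voxel `tau` estimates was ~30% of the generating
  value (36% at tau = 10 s, 17% at tau = 5 s), i.e. the "noisy
  single-voxel estimate" regime that motivates rank-based group tests.
* **Default grid 12x12x12 voxels** — a desk-scale stand-in for a brain
  volume; large enough for spatial statistics, small enough that a
  39-subject cohort simulates in seconds.

What the generator deliberately does **not** emulate: physiological
(cardiac/respiratory) noise, motion, scanner drift nonstationarity,
spatial heterogeneity of the HRF, and anatomical structure.  Passing
recovery and calibration tests on this generator therefore validates
the estimator and the inferential machinery, not robustness to every
artifact of real acquisitions.

## Preprocessing

`highpass_detrend()` projects out, per voxel, an intercept, a linear
trend, and sine/cosine pairs at 1–3 cycles per run.  Regression (rather
than FFT masking) is deterministic, exact at the stated frequencies,
and idempotent.  One consequence worth knowing: the *trend* regressor
is not orthogonal to mid-band sinusoids, so a sinusoid at 10 cycles/run
loses about 2% of its correlation with its original; far into the
pass-band the loss vanishes.

`zscore_voxelwise()` normalizes each voxel's time course to mean 0,
SD 1 (per run; whether the original normalization was per run or per
session is not documented, and per run is the conservative reading).
Constant voxels are zeroed and flagged in a QC table instead of
dividing by zero.  Because the decay fit is scale-equivariant, per-voxel
rescaling leaves `tau` untouched.

`smooth_gaussian()` applies a separable Gaussian of FWHM 4 mm
(`sigma = FWHM / (2 sqrt(2 ln 2))`, i.e. 0.566 voxels at 3 mm).  Kernel
rows are renormalized at volume borders, so constants are preserved
exactly and small synthetic grids are not darkened at their edges; the
price is that border voxels average slightly fewer neighbours.

## GLM and task-voxel selection

The design matrix has one column per TOA condition (same-TOA blocks
across runs share a column), an intercept, and — by default in the
pipeline — drift/trend confound columns matching the high-pass basis.
The confounds are *not* redundant: filtering the data but not the model
biases OLS amplitudes (the projection must be applied to both sides);
with the drift columns present the estimates are identical to fitting
in the filtered space.  The HRF kernel is max-normalized to 1 so that
`beta` carries signal units and is comparable across HRF parameter
choices; a scaling of the kernel by `c` scales `beta` by `1/c`, which
the tests pin down.

HRF defaults are the conventional two-gamma values: peak gamma shape 6,
undershoot shape 16, unit rates, undershoot ratio 1/6, 32 s support
(peak near 5 s).  Convolution uses the closed form of the gamma density
(and, for boxcar events, the gamma CDF), so regressors are exact at the
volume acquisition times — no fine-grid discretization error.

Task-responsive voxels are selected by the omnibus F test of the four
TOA predictors against the confound-only model, pooled across subjects
by fixed-effects combination (summing numerator and denominator sums of
squares and degrees of freedom), then thresholded by Benjamini-Hochberg
FDR at q = 0.001.  The omnibus statistic and the pooling rule are not
documented in the original protocol; the F test on the full TOA set is
the standard reading of "responds to the task", and fixed-effects
pooling matches the "all participants considered" phrasing.

## Fitting the decay model

For fixed `tau` the model is linear in `(a, b)`, so the fit is solved
by variable projection: profile the residual sum of squares over a
50-point log-spaced `tau` grid on (0.1, 60] s, then polish **every
local minimum** of the gridded profile by golden-section search in
`log(tau)` (70 iterations, bracketing between the neighbouring grid
points).  This is deterministic, needs no starting values, cannot be
trapped by a basin the grid can see, and vectorizes across voxels,
which is what makes per-subject whole-brain `tau` maps cheap.  The
tests verify that the polished optimum beats a 10x denser brute-force
grid on random instances.

Numerical flags (`reason` field):

* `nonidentifiable` — all betas numerically equal; `a` is their mean,
  `b = 0`, `tau = NA`.
* `boundary` — `tau` within 0.1% of a search bound, **or** the
  exponential regressor numerically flat across the design's TOAs
  (centered sum of squares `< 1e-4`, i.e. `tau` below ~0.8 s for TOAs
  of 3–15 s).  In that basin the linear system for `(a, b)` is
  ill-conditioned and `b` is amplified noise; the parameters are
  reported but flagged.
* `negative_b` — the best fit has `b < 0` (no adaptation); kept by
  default because the downstream rank test is robust to such values.

Flagged fits are included downstream (rank tests do not over-weight
extreme values) except where `tau` is undefined.  The bounds
(0.1, 60] s are a package choice — no bounds are documented — wide
enough to contain any `tau` measurable with TOAs of 3–15 s.

Two fitting paths exist deliberately: per-subject fits (voxelwise and
ROI) feed the group inference, while group-mean-beta fits are available
for descriptive maps; both are exposed because descriptive maps and
inference used different paths in the original analysis.

ROI analysis averages betas over the ROI and fits once per subject.
Averaging betas equals averaging time series and re-fitting under a
shared design (OLS is linear), which the tests verify rather than
assume.  Synthetic ROIs are geometric 99-voxel boxes, mirroring the
size of the primary auditory cortex masks; real masks are consumed as
NIfTI volumes on the analysis grid.

## Group inference

`mann_whitney_z()` computes U from midranks, z from the tie-corrected
normal approximation with a 0.5 continuity correction, and — for
combined samples of at most 12 — the exact two-sided p by exhaustive
enumeration of all group labelings.  At the study's 19 + 20 the normal
approximation is used; the tests bound its error against enumeration at
smaller sizes.  The effect size is `r = z / sqrt(N)`.

`monte_carlo_cluster_threshold()` simulates null maps on the mask's
grid, thresholds two-sidedly at the cluster-forming `voxel_alpha`
(default p < 0.05), labels clusters (26-connectivity by default;
"contiguous" is ambiguous, and both 6 and 26 are exposed), records the
maximum extent per iteration, and returns the smallest `k` with
empirical `P(max extent >= k) <= fwe_alpha`.  Two null-map models are
implemented, because the choice matters:

* `field = "gaussian"` — the classic construction: one white Gaussian
  field per iteration, smoothed to the preprocessing FWHM and
  standardized over the mask.
* `field = "rank"` — one smoothed Gaussian field *per subject* per
  iteration, converted into the same two-sample Mann-Whitney z map the
  pipeline actually thresholds.

The pipeline defaults to the rank model.  In end-to-end null
simulations the Gaussian model visibly under-corrects rank maps: a
thresholded rank field clumps more than a Gaussian field with matched
marginal rate and matched lag-1 autocorrelation (the dependence that
matters for extents is in the tails, which second-order matching does
not capture), so extent thresholds derived from Gaussian nulls let
through too many clusters.  Simulating the statistic map itself
removes the mismatch; the family-wise-error suite verifies the
resulting control.  The published 44-voxel threshold depends on the
real task mask and map smoothness and is not reproducible at desk
scale; it is not a target.

## Problem sizes used by the test suite

Replicate suites run on grids sized to the quantity they measure, and
the full 12^3 cohort is exercised once:

* parameter recovery: one 39-subject cohort on 12^3 (median ROI `tau`
  vs truth), plus 100 replicates on a grid equal to the 99-voxel ROI
  box (detection power) — with spatially independent noise, off-ROI
  voxels cannot change ROI-level results;
* null calibration: 200 replicates, 27-voxel ROI, one run per subject
  (the null distribution of a rank test does not depend on those
  sizes);
* family-wise error: 200 end-to-end null cohorts on 6^3 with one run
  per subject and zero between-subject spread (see Known limitations),
  against a threshold from 1000 Monte-Carlo iterations;
* oracle equivalence: 10,000-iteration Monte-Carlo reference on 6^3.

## Known limitations

* **The cluster-correction null models voxel-level dependence only.**
  Both null-map models simulate subject fields that are independent
  across distant voxels.  Under the group null, a subject's `tau` (and
  `a`, `b`) is a property of the subject, not the voxel, so
  between-subject parameter variance contributes a common,
  infinite-range component to the rank-test map that neither null
  model represents; the extent threshold is exactly calibrated only
  when that component is negligible.  The family-wise-error suite
  therefore runs on null cohorts with zero between-subject `tau`
  spread — the regime the null model describes — and regimes with
  substantial subject-level variance should expect some residual
  inflation.  Permutation-based cluster inference, which handles
  subject-level exchangeability exactly, is out of scope here.
* No prewhitening: GLM noise is treated as white, which is exact for
  the generator and approximate for real data.
* No random-effects group GLM; group inference is rank-based on
  per-subject `tau`, as in the analysis this package implements.
* Smoothness for the cluster threshold is taken from the applied
  smoothing kernel, not estimated from residuals.
* Atlas handling, surface analysis, motion and slice-time correction
  are upstream of this package: it consumes preprocessed voxel grids
  and masks.
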