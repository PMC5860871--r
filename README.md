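# adaptdecay

Estimating how fast fMRI adaptation decays — and comparing that speed
between groups.

## The problem

Repeating a stimulus suppresses the cortical response to it
(adaptation); the response recovers as the interval between
presentations grows.  In a block-design auditory experiment where each
block fixes the trial onset asynchrony (TOA) at 3, 6, 9 or 15 s, the
block-wise BOLD amplitude β therefore increases with TOA.  The speed of
that recovery is summarized by fitting

  β(TOA) = a + b·exp(−TOA/τ)

per voxel (or per region of interest) and per subject, where *a* is the
asymptotic BOLD level, *b* the magnitude of adaptation, and τ (seconds)
the time constant of adaptation.  A shorter τ means the trace of
previous trials fades faster — the quantity of interest when comparing
dyslexic readers (hypothesized to have faster-decaying implicit memory
of stimulus statistics) with good readers.

`adaptdecay` implements the complete analysis chain for such designs,
for researchers who want to run it on synthetic or preprocessed real
data:

* **synthetic cohorts** with known ground truth (two groups, 3 runs ×
  4 constant-TOA blocks × 16 trials, TR = 1 s, Gaussian noise, slow
  drift, optional spatial smoothness) — every stage is testable with no
  downloads;
* **preprocessing**: high-pass drift removal (up to 3 cycles/run),
  voxelwise z-scoring, 3D Gaussian smoothing (FWHM 4 mm);
* **block GLM**: two-gamma HRF convolution, one β per TOA condition,
  omnibus-F + Benjamini–Hochberg FDR selection of task-responsive
  voxels;
* **decay fitting**: global least squares by variable projection
  (profile τ on a log grid, polish every local minimum), returning a
  classed model object with the usual methods;
* **group inference**: voxelwise and ROI Mann–Whitney U tests on τ with
  effect size r = z/√N, and Monte-Carlo cluster-extent correction
  (including a null model that simulates the rank-statistic map
  itself).

## Worked example

Fit the decay model to four per-TOA amplitudes:

```r
library(adaptdecay)

toa  <- c(3, 6, 9, 15)
beta <- c(1.19, 0.91, 0.74, 0.62)
fit  <- fit_decay(beta, toa)
fit
#> Exponential adaptation decay fit: beta(TOA) = a + b * exp(-TOA/tau)
#>      a      b    tau
#> 0.5636 1.1603 4.8870
#> SSE 0.000108 on 1 residual df
```

The response asymptotes at a = 0.56, adapts by b = 1.16 at zero TOA,
and recovers with τ ≈ 4.9 s: by TOA = 15 s the response has nearly
returned to baseline.  `coef()`, `predict()`, `residuals()`,
`summary()`, `plot()` and `simulate()` behave as for any fitted model.

End to end on a small synthetic cohort (8 + 8 subjects, 6³ grid, one
run each, with a 54-voxel box ROI):

```r
cfg <- pipeline_config(n_control = 8, n_dyslexic = 8,
                       design = list(grid_dim = c(6, 6, 6), n_runs = 1),
                       mc_iter = 500, seed = 1)
roi <- make_box_roi(c(6, 6, 6), start = c(2, 2, 1), size = c(3, 3, 6), name = "A1")
res <- run_pipeline(cfg, rois = list(A1 = roi))
res
#> Adaptation-decay pipeline result
#> Synthetic cohort: 8 control + 8 dyslexic subjects, 1 run(s) of 4 blocks, grid 6x6x6
#>   task-responsive voxels: 216
#>   cluster extent threshold k = 8; surviving clusters: 1
#> ROI 'A1' group comparison of tau (Mann-Whitney)
#>   median tau: control = 10.72 s, dyslexic = 5.59 s
#>   U = 64, z = 3.31, p = 0.0009391, effect size r = 0.83
```

The generator gave the control group τ = 10 s and the dyslexic group
τ = 5 s; the recovered medians (10.7 s vs 5.6 s) track the truth, the
ROI rank test detects the difference (p < 0.001, r = 0.83), and one
whole-brain cluster survives the Monte-Carlo extent threshold of 8
voxels.  Rerunning with the same `seed` reproduces every number
exactly.

The methods vignette (`vignettes/adaptation-decay-methods.Rmd`)
explains the model, every tunable parameter, the synthetic generator's
scope, and the numerical choices.

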