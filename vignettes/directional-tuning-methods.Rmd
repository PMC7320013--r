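---
title: "Methods: kernel-based encoding models of directional tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kernel-based encoding models of directional tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhdtune)
```

## Scientific question

During free navigation in a virtual arena, the virtual head direction
(vHD) sweeps the circle. A voxel is *directionally tuned* if its time
series is better predicted by a direction-based encoding model than by
chance; the *tuning width* is read out by repeating the whole analysis
with basis sets of systematically varied kernel width and asking which
width predicts best. Because ground truth is unknowable in real
recordings, `vhdtune` ships generators for both the behavior and the
voxels, and validates every estimator by simulation-based parameter
recovery.

## Conventions

Angles are degrees in [0, 360), with 0 = arena north and angles
increasing clockwise; the unit direction vector is (sin θ, cos θ), and
bearings are `atan2(dx, dy)`. Positions are in arbitrary virtual units.

## Behavior generator

`simulate_session()` produces a self-paced object-location memory session
in a circular arena (radius 100 units, 12 landmarks every 30° on the
perimeter, 6 object locations in the central 80%): on each trial the
agent rotates toward the remembered location in 10° steps at a sustained
50°/s, translates along its (quantized) facing direction with a 500 ms
linear speed ramp and then a constant 10 units/s, indicates the location
(1 s pause), receives feedback (2 s), then collects the object at the
true location; a 4 s fixation block follows every 2–4 trials. The log
spans exactly `n_runs * trs_per_run * tr` seconds (defaults 5 × 210 ×
2.756 s) at 50 Hz.

Remembered locations err from the truth by a displacement whose expected
magnitude decays exponentially across trials from 40 to an asymptote of 8
units (rate 0.02/trial; configurable fast/slow learners), multiplied by
mean-one gamma jitter (shape 6), in a uniformly random direction. Because
the agent aims at the *erroneous* target along a quantized heading, the
path itself carries realistic aiming error.

Default calibration (a priori, from stated task conditions, never tuned
against outcomes): translation speed 10 units/s and rotation speed 50°/s
yield roughly 155–180 completed trials per session (target: mean 179,
range 94–253 across participants) and ~54% of session time spent
translating. Known limits of the generator: vHD is piecewise constant
(no smooth turning), there is no path curvature during a leg, no
head-direction jitter while stationary, and fixation "direction" simply
freezes the last facing.

## Basis sets and design pipeline

Each basis uses peak-normalized von Mises kernels
`f(Δ) = exp(κ (cos Δ − 1))` with `κ = ln 2 / (1 − cos(fwhm/2))`, so the
kernel is 1 at its center and exactly ½ at half a FWHM away. Spacing
equals the FWHM, hence `K = 360 / fwhm` kernels; the standard widths are
{10, 15, 20, 24, 30, 36, 45, 60}°, all divisors of 360.

Per basis, the design is built as: kernel activities at the sampling
rate → within-TR **median** over the half-open window `[k·tr, (k+1)·tr)`
→ per-run min–max scaling to [0, 1] (constant columns become zeros) →
causal convolution with a double-gamma HRF, truncated at each run
boundary so nothing bleeds across runs. The HRF is a difference of unit-
scale gamma densities with modes exactly at 6 s (peak) and 16 s
(undershoot, amplitude ratio 6), sampled on the TR grid over 32 s.

A movement covariate — the within-TR **mean** of the translating flag,
scaled and convolved identically — is fit alongside the kernels and
discarded at prediction. For behavioral-state analyses the kernel medians
are restricted to locomotion or stationary samples (TRs without
qualifying samples get zeros), while the movement covariate always uses
all samples, keeping every state design on the identical TR grid.

## Training

Per voxel, weights solve the ridge problem on the z-scored design with an
unpenalized intercept (the response mean). The penalty grid is 10 values
log-spaced from 1 to 1e7. Within the four training runs, each run serves
once as validation fold: weights are fit on the remaining three and
scored by the Pearson correlation of the kernel-only prediction with the
held-out run. A voxel's penalty is the argmax of its fold-averaged score,
ties toward the smaller penalty; voxels whose best score never exceeds
zero are flagged *excluded*. The final penalty is the **geometric mean**
over non-excluded voxels (the grid is log-spaced, so averaging in log
space respects its geometry), and final weights are fit for *all* voxels
on the full training set at that single penalty. The solver takes one SVD
of the standardized design and reuses it across all penalties and voxels.

On 200 pure-noise voxels roughly 36% are excluded — the ten per-penalty
validation scores of a null voxel are highly correlated, so the
probability that all stay ≤ 0 sits just below 0.4.

## Testing

Forward: the test-run prediction uses the training standardization, the
kernel weights only, and the training intercept; performance is Pearson
r. Each voxel's null shuffles its kernel-weight vector (500 unique
non-identity permutations, capped at `K! − 1`) and recomputes the
prediction, giving `z = (r_obs − mean(null)) / sd(null)`; constant weight
vectors have a degenerate null and get z = 0 with a flag. The ROI-level
strength is the mean z over the top `ceiling(0.25 n)` voxels by training
score, and `select_tuning_width()` takes the argmax over bases, ties
toward the narrower kernel (the conservative claim, since narrow kernels
approximate wide ones).

Inverted: the Moore–Penrose pseudoinverse of the selected voxels' weight
matrix, applied to the intercept-removed test patterns, reconstructs
kernel-by-TR activities, scored by 2-D Pearson correlation against the
standardized convolved test design. The null permutes the kernel columns
of the weight matrix; because permutation matrices are orthogonal,
`pinv(W P) = t(P) pinv(W)`, so each shuffled reconstruction is exactly
the row-permuted original.

Two width read-outs coexist deliberately. Parameter recovery
(`run_recovery`) scores each basis by the voxel-averaged test r and, in
the 27-cell validation grid (3 profiles × widths 10/30/60° × noise 1/3/6
signal SDs, 200 voxels per cell), the true width wins every cell. The
ROI-z argmax, in contrast, is biased toward narrow bases on noisy data:
narrow kernels fit wide profiles almost as well, and a larger K yields a
richer permutation null with a tighter SD, hence larger z. Both follow
their definitions; recovery claims should use the voxel-averaged r.

## Group inference and calibration

The one-sample test sign-flips participant scores; with `2^n ≤ k` all
assignments are enumerated (identity included), so for n = 10 the
smallest attainable one-sided p is exactly 1/1024 ≈ 0.000977. The sum of
squares is sign-invariant, so the t statistic depends on the flipped mean
alone, making enumeration a single matrix product. Two-sample tests
permute group labels (pooled t, observed labeling included); paired tests
sign-flip differences; rank correlations permute one variable
(exhaustively when `n! ≤ k`). FDR control is Benjamini–Hochberg via
`stats::p.adjust` (checked in the tests against a hand-built step-up
oracle). Effect sizes are Cohen's d with percentile-bootstrap intervals.

Null calibration: selecting voxels by *training* score is independent of
the *test* run under the null, so the expected ROI z on pure-noise ROIs
is 0 (no selection inflation); across 100 replicate 50-voxel ROIs the
observed mean is within ±0.15 with SD near `1/sqrt(13)` (13 averaged,
near-independent, unit-variance voxel z's). The sign-flip test rejects
1000 null replicates at the 5% level with frequency inside [0.03, 0.07].

## Numerical and reproducibility choices

- All stochastic steps take explicit seeds; an internal helper evaluates
  under a temporary RNG state and restores the caller's, so library calls
  never perturb user RNG streams. Recovery cells derive their seeds from
  the master seed, so cells are independent but reproducible.
- `pracma::pinv` supplies the pseudoinverse, `pracma::perms` small-n
  enumeration; everything else is base R.
- Scales used in validation: desk-scale fixtures (5 runs × 24 TRs, 20 Hz)
  in the unit tests; full scale (5 × 210 TRs, 50 Hz, 200 voxels/cell) in
  the acceptance suite and `scripts/acceptance.R` (~1 minute total).

```{r example, eval = FALSE}
log <- simulate_session(sim_config(), seed = 1)
rec <- run_recovery(profiles = "unimodal", widths = 30, noises = 1,
                    n_voxels = 100, seed = 1, log = log)
rec$cells
```
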