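# vhdtune

Voxel-wise encoding models of world-centered directional tuning during
virtual navigation.

During free navigation in a virtual arena, a participant's virtual head
direction (vHD) sweeps the full circle. `vhdtune` asks whether an
fMRI-like voxel time series carries information about that direction, how
strong the tuning is, and — via basis sets of systematically varied kernel
width — how *wide* it is. Because ground-truth tuning is unknowable in
vivo, the package pairs the analysis pipeline with simulators for both the
behavior and the voxels, so every estimator can be validated by parameter
recovery.

## The model

Direction is encoded with a basis of peak-normalized circular (von Mises)
kernels

&nbsp;&nbsp;&nbsp;&nbsp;f(Δ) = exp(κ (cos Δ − 1)),&nbsp;&nbsp;
κ = ln 2 / (1 − cos(fwhm / 2)),

so each kernel is 1 at its preferred direction and exactly ½ at half a
full-width-at-half-maximum (FWHM) away. Kernel spacing equals the FWHM,
giving K = 360/fwhm kernels per basis; the procedure iterates over the
widths {10, 15, 20, 24, 30, 36, 45, 60}°.

For each basis, the design pipeline is: kernel activities at the
behavioral sampling rate → within-TR median → per-run min–max scaling to
[0, 1] → causal convolution with a canonical double-gamma HRF, per run. A
movement covariate (within-TR fraction of time spent translating,
processed identically) is fit alongside the kernels and discarded at
prediction time.

Voxel-wise kernel weights are estimated by ridge regression on the
z-scored design. The penalty is chosen per voxel by leave-one-run-out
cross-validation *within the training runs* over a fixed grid
(10 values, log-spaced 1…10⁷); voxels whose best cross-validated score
never exceeds zero are excluded from the penalty averaging, and the final
model is fit on all training runs at the geometric-mean penalty.

Model tests on the held-out run (the middle run of five):

- **Forward**: the predicted time course is correlated with the observed
  one; significance per voxel comes from a null of 500 unique shuffles of
  the voxel's kernel-weight vector (z score against the shuffle null). The
  ROI-level tuning *strength* is the mean z over the top 25% of voxels by
  training predictability, and the tuning *width* is the basis FWHM that
  maximizes it.
- **Inverted (IEM)**: the Moore–Penrose pseudoinverse of the trained
  weights reconstructs kernel activities from the test-run multivoxel
  patterns; the reconstruction is scored by 2-D correlation with the test
  design, against the same kind of shuffle null.
- **Group level**: exhaustive one-sample sign-flip permutation t tests
  (1024 sign assignments for n = 10, minimum one-sided p = 1/1024 ≈
  0.000977), two-sample and rank-correlation permutation tests, Cohen's d
  with bootstrap intervals, and Benjamini–Hochberg FDR control.

## Worked example

```r
library(vhdtune)

# 1. Simulate a session: self-paced object-location memory trials in a
#    circular arena, logged at 50 Hz over 5 runs x 210 TRs (TR 2.756 s).
log <- simulate_session(sim_config(), seed = 1)
log
#> Behavior log: 144690 samples at 50 Hz, 158 completed trials
#>   5 run(s) x 210 TRs at TR 2.756 s

# 2. Simulate 100 voxels tuned at 30 deg FWHM (unit noise), run the full
#    pipeline over all 8 basis widths, and recover the tuning width as the
#    basis with the best voxel-averaged test performance.
rec <- run_recovery(profiles = "unimodal", widths = 30, noises = 1,
                    n_voxels = 100, seed = 1, log = log)
rec
#> Recovery report: 1 cells x 100 voxels; true width won in 1/1
rec$cells[, c("winner_fwhm", "mean_r_true", "roi_z", "iem_z")]
#>   winner_fwhm mean_r_true    roi_z    iem_z
#> 1          30   0.6484424 2.842409 2.392786

# 3. For a dataset with unknown tuning, run_pipeline() fits all bases and
#    returns the per-basis ROI table, the ROI-z-selected width, and the
#    inverted-encoding reconstruction of the held-out run.
voxels <- simulate_voxels(log, make_ground_truth("unimodal", 30, seed = 2),
                          n_voxels = 100, seed = 99)
res <- run_pipeline(log, voxels, experiment_config(seed = 7))
res$curve$table   # fwhm, roi_z, mean_r, lambda, n_excluded per basis

# 4. Group inference over, e.g., per-participant tuning strengths.
signflip_ttest(c(1.2, 0.8, 2.1, 0.4, 1.7, 0.9, 1.1, 0.6, 1.4, 1.0))
#> Permutation t test (one-tailed): t = 6.952, p = 0.0009766
#>   (exhaustive 1024 perms), d = 2.20
```

The two width read-outs differ in character: the voxel-averaged test
correlation is an unbiased recovery criterion (used by `run_recovery`),
while the shuffle-null ROI z favors narrower bases on noisy data because
narrow kernels both approximate wider profiles well and carry a richer
permutation null; the methods vignette discusses this.

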