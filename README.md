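# veinpulse

Detection and characterization of cardiac-locked flow pulsatility in small
cerebral cortical veins from cardiac-gated 2D phase-contrast MRI (pcMRI).

Small cortical veins (0.6–2 mm, on the order of one in-plane voxel) carry
slow flow (~0.3–2 cm/s) whose cardiac pulsatility is informative about
intracranial compliance, but is hard to separate from noise. `veinpulse`
implements a complete vessel-level analysis for this problem:

- **Segmentation** — vessels are selected from the cycle-averaged pcMRI
  magnitude image as voxels brighter than the image mean + 2 SD, then
  grouped into clusters by 8-connected (edge- or corner-adjacent)
  component labeling.
- **Velocimetry** — background phase offsets are removed with a 17 × 17
  voxel (10 mm) median filter, phase is unwrapped voxelwise along the
  cardiac-phase axis, and each cluster's spatial-mean phase is scaled by
  venc/π to cm/s (venc = 10 cm/s, chosen for slow venous flow). A
  dedicated pathway builds the superior sagittal sinus timing reference
  from the 20 brightest sinus voxels, aligning their wrapping point by
  subtracting 2π from positive-phase voxels and taking a voxelwise median.
- **Pulsatility statistics** — each waveform v(t) is low-pass filtered
  (Savitzky–Golay, order 3, frame 15) and scored with the pulsatility
  contrast-to-noise ratio

      PCNR = Δv / sqrt( Σ res_t² / (N − 1) ),

  where Δv is the range of the filtered curve and res the residuals
  between unfiltered and filtered timepoints. The detection threshold is
  calibrated by Monte Carlo simulation of the PCNR null distribution on
  Gaussian noise waveforms; its 99th percentile is ≈ 3.9, insensitive to
  noise level (exactly, by scale invariance) and to the number of cardiac
  phases. Pulsatility index is PI = Δv / mean(|v|), and the temporal lag
  of each vessel relative to the sinus is the peak of the circular
  cross-correlation of the unfiltered waveforms.
- **Cohort statistics** — per-subject medians across vessels, one-sample
  t-tests of lag against zero (Bonferroni-corrected for four vessel
  groupings), paired t-tests (small vs surface vein PI, pulsatile vs
  non-pulsatile vein speed), and one-way ANOVAs across vascular
  territories (ACA / L MCA / R MCA / PCA).
- **Synthetic scenes** — a generator renders gated magnitude/phase series
  with known vessel footprints, waveforms, lags, partial-volume weights,
  smooth polynomial background phase, phase wrapping in fast vessels, and
  Gaussian noise, with full ground truth for end-to-end validation.

## Worked example

```r
library(veinpulse)

cfg <- demo_scene_config(seed = 7)   # one synthetic subject
run <- run_pipeline(cfg)

print(run$calibration)
#> PCNR null calibration: threshold 3.885 at alpha = 0.01 (N = 38, 100000 reps)

head(run$results[, c("cluster", "class_label", "size", "pcnr",
                     "pulsatile", "pi", "lag_ms")], 5)
#>   cluster  class_label size  pcnr pulsatile    pi lag_ms
#> 1       1   small_vein    1  3.25     FALSE 0.321   92.4
#> 2       2   small_vein    8  5.58      TRUE 0.327   69.3
#> 3       3   small_vein    3  3.82     FALSE 0.384   69.3
#> 4       4 surface_vein   15 10.69      TRUE 0.285   69.3
#> 5       5 surface_vein    9 10.50      TRUE 0.315   69.3

run$summary$groups
#>          group  n n_pulsatile median_pi median_lag_ms
#> 1   small_vein  8           5     0.286          69.3
#> 2 surface_vein  4           4     0.313          69.3
#> 3    all_veins 12           9     0.292          69.3
#> 4       artery  3           3        NA           0.0
```

The scene injects veins delayed ~60 ms behind the sinus with PI ≈ 0.3:
9 of 12 veins are flagged pulsatile (PCNR > 3.885), their median PI is
0.29, and their median lag is 69.3 ms — one 23.1 ms cardiac phase above
the injected delay's lower quantization step. Arteries (whose phase wraps
at this venc) are characterized for PCNR and lag but not PI. A cohort of
subjects goes through `simulate_cohort()` and `run_cohort()`, which add
the group statistics table.

A thin command-line wrapper is installed at `inst/cli/veinpulse.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/veinpulse.R", package="veinpulse"))')" \
    --simulate-demo --seed 7 --out demo-out
```

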