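---
title: "Measuring flow pulsatility in small cerebral veins: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring flow pulsatility in small cerebral veins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinpulse)
```

## The measurement problem

Cardiac-gated 2D phase-contrast MRI encodes the through-slice blood
velocity of every voxel into the phase of the complex MR signal: a voxel
moving at the velocity-encoding speed `venc` acquires a signal phase of π
radians, and faster flow wraps around. With `venc = 10` cm/s the
measurement is sensitive to the slow (≲ 2 cm/s) flow of small cortical
veins, at the price of phase wrapping in arteries and the superior
sagittal sinus. One gated acquisition yields, for each of N cardiac
phases (33–45 per cardiac cycle, 23.1 ms each — two repetition times of
11.55 ms, one flow-compensated and one flow-encoded readout), a magnitude
image and a phase image.

The scientific question is binary per vessel — is its flow waveform
cardiac-locked, i.e. pulsatile? — followed by two descriptive statistics,
the pulsatility index and the timing of the waveform relative to the
sinus. The difficulty is that small veins span only 1–30 voxels and their
pulsatile amplitude is comparable to the phase noise, so detection needs
an explicit, calibrated statistic rather than visual inspection.

## Pipeline

1. **Segmentation.** The magnitude stack is averaged over the cardiac
   cycle; voxels strictly brighter than mean + k·SD (default k = 2) are
   vessel candidates, and 8-connected components become vessel clusters.
   The threshold statistics can be restricted to an ROI (a brain mask);
   by default they use the whole image, and which convention was used is
   recorded in the run provenance. Cluster ids are assigned in scan order
   of the first-encountered voxel so that labeling is deterministic.
   Vessel class (artery / small vein / surface vein / sinus) and vascular
   territory come from a reference label image — in real use a manual
   classification, in synthetic use the generator truth. A cluster
   overlapping reference vessels of two different classes is discarded,
   as is one overlapping none.

2. **Velocimetry.** Each phase image is high-pass filtered by
   subtracting its 17 × 17 voxel (10 mm at 0.6 mm voxels) median filter,
   removing smooth background phase offsets while leaving sparse vessels
   intact (a vessel of ≤ 30 voxels can never dominate a 289-voxel
   window). Phase is then unwrapped voxelwise along the cardiac-phase
   dimension (jumps greater than π between successive samples are
   reduced by the nearest multiple of 2π). The order — filter first,
   then unwrap — is deliberate and pinned by tests: the median filter
   operates on the raw wrapped phase, where the background is smooth,
   and robustly ignores wrapped vessel voxels in its window. Cluster
   velocity is the spatial mean phase over the cluster's voxels scaled
   by venc/π.

3. **Sinus reference.** The sinus flows fast enough to wrap multiple
   times, and different voxels wrap to different branches, so its
   waveform is built for *timing*, not absolute speed: the 20 brightest
   sinus voxels (cycle-averaged magnitude; ties broken in scan order)
   are filtered and temporally unwrapped as above, any voxel-timepoint
   with positive phase is shifted down by 2π (the posterior sinus
   encodes negative phase; the sign convention is an argument for other
   geometries), and the voxelwise median across the 20 voxels is scaled
   by venc/π. The median across voxels makes the reference robust to
   residual wrap errors in single voxels.

4. **Pulsatility.** The waveform is split into a low-frequency pulsatile
   component and high-frequency residuals by a Savitzky–Golay filter
   (polynomial order 3, frame 15). The statistic

   PCNR = Δv / √( Σ resₜ² / (N−1) ),

   with Δv the peak-to-trough range of the filtered curve, behaves like
   a t-statistic for cardiac-locked variation and — unlike PI — is not
   inflated for slow vessels, because it normalizes by the residual
   noise rather than the mean velocity. Its null distribution is
   calibrated by Monte Carlo: PCNR of i.i.d. standard Gaussian waveforms
   (default 10⁵ draws, fixed seed), thresholded at the empirical
   (1 − α) quantile, α = 0.01. PI = Δv / mean(|v|) uses the filtered
   range in the numerator and the unfiltered waveform in the
   denominator. Temporal lag is the argmax of the circular
   cross-correlation of the mean-subtracted unfiltered waveforms,
   restricted to [−N/2, N/2) samples.

5. **Cohort statistics.** PI and lag distributions across vessels are
   skewed, so each subject contributes the median across its vessels
   (over pulsatile vessels only). Across subjects: one-sample two-tailed
   t-tests of lag against zero for small veins, surface veins, all
   veins, and arteries, Bonferroni-corrected for the four comparisons;
   a paired t-test of PI between small and surface veins; one-way ANOVAs
   of vein lag, artery lag, and vein PI across the four vascular
   territories on subject-by-territory medians; and a paired t-test of
   mean |v| between pulsatile and non-pulsatile veins.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `venc` | 10 | cm/s | sensitivity to slow venous flow; arteries/sinus wrap |
| `phase_duration` | 23.1 (= 2 × TR) | ms | one cardiac phase spans a flow-compensated/encoded TR pair |
| `threshold_sd` (k) | 2 | SD | vessel conspicuity threshold on the averaged magnitude |
| median filter window | 17 | voxels | 10 mm at 0.6 mm voxels; background smooth at this scale |
| SG order / frame | 3 / 15 | — / timepoints | passes waveforms with a few cardiac harmonics, rejects high-frequency noise |
| `alpha` | 0.01 | — | pulsatility significance level |
| `mc_reps` | 10⁵ | draws | quantile Monte Carlo error small against the ±0.3 tolerance used in tests |

## Numerical decisions

**Savitzky–Golay boundary handling.** A gated waveform is one cardiac
cycle, which suggests circular (wrap-around) extension; but the
calibrated detection threshold of ≈ 3.9 at α = 0.01 belongs to the
*classical* filter convention, in which the first and last half-frames
are smoothed by the asymmetric polynomial edge fits (the behaviour of
`sgolayfilt` in common signal-processing toolboxes). The two conventions
genuinely differ: under edge fits the null 99th percentile is ≈ 3.9,
under circular extension ≈ 2.5, because edge fits track the noise more
closely at the boundaries (inflating Δv and deflating the residual).
The package therefore defaults to `boundary = "edgefit"`, which keeps
the conventional threshold meaningful, and exposes
`boundary = "circular"` as a sensitivity check — with the rule that
thresholds must always come from `calibrate_null()` run with the same
settings as the analysis. `run_pipeline()` enforces this by construction.

**Degenerate waveforms.** PCNR is exactly invariant to scale and offset,
so the statistic is computed on the mean-centered waveform; a constant
waveform then yields exactly Δv = 0, residual 0, and PCNR 0 rather than
0/0 rounding noise. A zero residual with positive range is flagged as
infinite PCNR and treated as pulsatile (unambiguous signal). PI is an
error for an identically-zero waveform; lag is an error for
zero-variance waveforms (the cross-correlation is undefined).

**Lag quantization and ties.** No sub-sample interpolation is performed:
lag is an integer number of cardiac phases (quantized to 23.1 ms),
matching the acquisition's temporal resolution. Cross-correlation ties —
which arise exactly for symmetric or harmonic waveforms — are broken
toward the smallest |lag| and then toward positive lag, with a small
relative tolerance so that floating-point rounding cannot hide an exact
tie. Antiphase waveforms therefore report ±N/2 deterministically.

**Median filter edges.** Reflection (symmetric) padding, to avoid the
edge bias of zero padding. The filter is applied per cardiac phase, not
to the time-averaged phase, since background offsets may drift over the
cycle.

**Thresholding.** Strict inequality at mean + k·SD, so a uniform image
yields an empty mask with no special-casing.

**ANOVA missing cells.** When a subject has no pulsatile vein in some
territory, only that subject-territory cell is omitted from the affected
ANOVA; the subject's other cells still contribute. Groupings absent from
an entire cohort yield NA test rows rather than failures.

## The synthetic scene generator

The generator is the package's test bed: it renders gated
magnitude/phase stacks for a configurable vessel population and records
complete ground truth (label image, class/territory table, per-vessel
waveforms and lags). It emulates the features the pipeline must cope
with:

- vessel clusters of 1–30 8-connected voxels, with partial-volume
  attenuation as a single scalar weight per vessel;
- venous speeds of ~0.3–2 cm/s (superior-to-inferior, negative phase)
  and artery/sinus speeds beyond venc, so that phase genuinely wraps;
- cardiac-locked pulse waveforms built from 1–3 harmonics with dominant
  fundamental, unit peak-to-trough range, controllable amplitude and
  (fractional-sample) lag; an optional circular uniform smoothing of the
  template emulates the temporal blurring of prospective gating under
  heart-rate variability (off by default);
- a smooth degree-≤3 polynomial background phase field, removable at
  the 17 × 17 scale;
- additive Gaussian noise on phase and magnitude, independently.

The magnitude model gives vessel voxels a *compressive* contrast,
`gain · vf · (min(|v|, venc)/venc)^(1/3)` above the tissue baseline.
The compression is deliberate: real complex-difference magnitude images
show slow veins and the fast sinus within a narrow conspicuity range,
and a response linear in |v| would let a handful of bright artery/sinus
voxels inflate the image SD until slow veins could no longer exceed the
mean + 2 SD threshold on a desk-sized grid. With the default contrast,
every vessel voxel with volume fraction 1 exceeds the threshold — a
property the tests assert.

What the generator does *not* emulate: k-space acquisition, coil
sensitivities, Rician magnitude noise (the PCNR null assumes Gaussian
waveform noise, and velocity noise enters through phase), sub-voxel
vessel geometry, cross-sectional-area change over the cycle, motion, and
tissue texture. Passing tests therefore demonstrate the correctness of
the *analysis* under controlled conditions — recovery of known
waveforms, lags, and detection rates — not robustness to every artifact
of in vivo data.

## Validation-study sizes

The test suite runs entirely on synthetic data at desk scale, chosen to
keep the default suite fast while leaving the statistics meaningful:

- null calibration and its N-insensitivity at 10⁵ Monte Carlo draws
  (N = 33, 38, 45); type-I error on 10⁴ independent noise waveforms;
- PCNR cross-checked against an independently coded brute-force
  implementation (explicit least-squares kernels, per-window polynomial
  fits) on 100 random waveforms at 10⁻¹² relative tolerance;
- connected-component labeling against a flood-fill oracle on 1000
  random 12 × 12 masks;
- lag recovery on 200 single-vein scenes (40 × 40 voxels, 38 phases)
  with injected lags −5…+5 samples and phase noise 0.02 rad, giving
  vein PCNR ≈ 10–19 — comfortably above the PCNR ≥ 5 regime the check
  conditions on. Near the detection threshold (PCNR ≈ 5) the
  cross-correlation argmax jitters by ±1 sample in roughly a tenth of
  runs, an intrinsic limit of peak-picking on a first-harmonic-dominant
  waveform at 23.1 ms resolution, so exact-integer recovery claims
  require that headroom;
- an 8-subject cohort (64 × 64 scenes, 33–45 phases, ~60 ms injected
  venous delay, arteries at 0 ms) for the qualitative cohort-level
  pattern: a majority of veins flagged pulsatile, the vein-lag test
  significant after Bonferroni correction, the artery-lag test not.

## Known limitations

- Absolute flow (mL/s) is out of scope: vein cross-sectional area is
  unmeasurable at this resolution, and partial-volume weights attenuate
  velocity amplitudes (they cancel in PI but lower PCNR).
- Arterial mean velocity and PI are unreliable at the venous venc
  because of wrapping; the package computes only PCNR and lag for
  arteries.
- Lag is quantized to one cardiac phase; systematic sub-sample delays
  smaller than ~23 ms are not resolvable (a parabolic peak refinement
  could be added, but is deliberately not the default).
- The cohort statistics assume each subject's vessel medians are
  exchangeable across subjects; no covariate adjustment is provided.
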