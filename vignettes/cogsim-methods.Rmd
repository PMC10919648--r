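---
title: "Methods: EEG-fMRI similarity analysis for cognitive state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG-fMRI similarity analysis for cognitive state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogsim)
```

## The analysis

`cogsim` quantifies how well windowed EEG descriptors track the BOLD signal
of a volume of interest (VOI) recorded simultaneously with fMRI while a
programmer reads text, comprehends code, and inspects code for bugs. The
chain is:

1. **Feature bank.** For each of 60 scalp channels (10-10 montage), 35
   descriptors are computed on contiguous 1-second windows: 8 linear
   time-domain (mean of the raw and run-normalized signal, SD, skewness,
   non-excess kurtosis, and the Hjorth parameters Activity, Mobility,
   Complexity), 25 linear frequency-domain (total power; absolute and
   relative power in delta 0–4, theta 4–8, alpha 8–13, beta 13–30 and
   gamma 30–45 Hz; the 10 unordered band-power ratios oriented
   lower/higher; spectral mean frequency; alpha peak frequency; and the two
   engagement indexes beta/(theta+alpha) and theta/(alpha+beta)), and 2
   nonlinear (Higuchi fractal dimension, rescaled-range Hurst exponent) —
   2,100 descriptors in total.
2. **Repair.** Missing feature samples (e.g. from upstream epoch rejection)
   are linearly interpolated per descriptor, with nearest-value fill at the
   edges. Then, time points flagged as outliers (beyond the descriptor's
   median ± 3 IQR) in more than 25% of all descriptors are linearly
   interpolated in every descriptor.
3. **Second-order transform.** Non-overlapping triples of consecutive 1-s
   samples are summarized by their mean, maximum and minimum, aligning the
   feature time base to the 3-second fMRI repetition time (TR) and tripling
   the bank to 6,300 descriptors.
4. **Hemodynamic convolution.** Each second-order time course is
   standardized and convolved (causally, zero pre-padding, same length)
   with a canonical double-gamma haemodynamic response function (HRF)
   parameterized by its peak delay, over the delay grid {4, 5, 6, 7} s.
5. **Similarity mapping.** Every regressor is Pearson-correlated with every
   voxel time series of every run; two-sided p-values use the exact t
   transform with T − 2 degrees of freedom; each map is thresholded with
   Benjamini–Hochberg FDR at α = 0.05 (the family is all voxels of one
   map). Over voxels that are significant *and* inside the VOI we record
   the mean and maximum |r| and the overlap portion
   d = |sig ∩ VOI| / |VOI|.
6. **Delay optimization and ranking.** Per descriptor, the delay
   maximizing the run-averaged mean |r| wins (ties to the smaller delay).
   Descriptors are ranked by that score; a cutoff is the elbow of the score
   curve (first window of `w = 10` successive differences all below
   `eps = 0.002`), capped at 100 for individual and 200 for group rankings.
   Occurrence summaries report the top features by type, scalp region
   (prefix-based: FT/TP/T temporal, FC/CP/C central, AF/Fp/F frontal, PO/P
   parietal, O occipital) and optimized delay. Group ranking scores each
   descriptor by the mean over all subjects' runs of mean |r| at each
   subject's own optimized delay.

## The synthetic-data generator

Real simultaneous EEG–fMRI at this scale cannot ship with a package, so the
generator plants a known ground truth and the test suite scores the full
pipeline by parameter recovery.

* **Protocol structure.** A run interleaves 30-s fixation baselines with
  three main conditions in seed-randomized order. The desk-scale default is
  60 s text + 120 s comprehension + 240 s inspection = 540 s per run, four
  runs per subject — the same structure as the acquisition protocol at a
  scale that keeps a full-pipeline run in tens of seconds.
* **Latent load.** Piecewise-constant per-condition levels (baseline 0,
  text 0.3, comprehension 0.6, inspection 1), Gaussian-smoothed with SD 3 s
  (state changes are not instantaneous) plus white noise of SD 0.05, at
  1 Hz.
* **EEG.** Every channel carries a 1/f-shaped Gaussian background (Kellet
  pink-noise filter) band-limited to 1–45 Hz with RMS 10 µV, plus a
  sinusoidal rhythm at the responsive band's center frequency with random
  phase and equal RMS. On responsive channels (default F4, FC4, C4) the
  rhythm's envelope is 1 + gain · load, held per 1-s block; elsewhere it is
  constant 1. Two consequences are deliberate: at gain 0 responsive and
  non-responsive channels are statistically exchangeable, and the planted
  signature is concentrated in the planted band so band-power descriptors
  can recover it. An earlier design using band-limited *noise* as the
  rhythm made 1-s band-power estimates so variable that broadband variance
  descriptors always outranked the planted band's own power — a
  deterministic carrier is the cleaner planted signal.
* **BOLD.** VOI voxels follow the load convolved at 1 Hz with the HRF at
  the planted delay, sampled at the TR-window centers, standardized, plus
  Gaussian noise of SD 1/snr (snr = SD(signal)/SD(noise), default 2);
  non-VOI voxels are unit-SD noise. Default grid 16×16×8 with a 64-voxel
  VOI block.
* **Randomness.** All draws flow from one integer seed through keyed
  splitmix64 streams; the package never touches R's global RNG, and
  identical seeds give bit-identical datasets.

### What the generator does not emulate

No scanner artifacts (gradient, ballistocardiogram), eye blinks, muscle or
motion artifacts — upstream correction of these is out of scope and the
generator emulates *cleaned* EEG. No spatial autocorrelation in BOLD noise,
no drift, no subject covariance beyond independent seeds. Passing recovery
tests therefore demonstrates the analysis machinery is correct, not that
the pipeline is robust to real-world contamination.

## Numerical and design choices

* **PSD estimator.** Welch within each 1-s window: 0.5-s Hamming segments,
  50% overlap, 2 Hz grid. Band integrals use half-open bins [lo, hi) with
  gamma closed at 45 Hz, so the five bands exactly partition [0, 45] and
  absolute powers sum to the total by construction.
* **"Mean of normalized signal"** z-scores the window mean with *run-level*
  statistics (window-level normalization would make it identically zero).
* **Hjorth derivatives** are first differences scaled by the sampling rate,
  so Mobility of a sinusoid of frequency f is 2πf rad/s.
* **Higuchi kmax** defaults to 10 for 1000-sample windows; **Hurst** uses
  dyadic block sizes 16…n/2 with population-SD rescaling. Plain R/S slopes
  carry the well-known small-sample upward bias (about +0.06 at n = 1000
  for white noise); the tests calibrate against the estimator's actual
  sampling distribution rather than the asymptotic 0.5.
* **HRF.** Difference of gamma densities with unit rate: shape delay+1 puts
  the positive mode exactly at the delay; undershoot mode at delay+10 s
  with ratio 1/6; 32-s span; sampled weights scaled to unit peak
  (correlation is scale-invariant; unit peak eases plotting). Convolution
  happens on the 3-s second-order grid, matching the stated order of
  operations; a 1-s path would resolve delays better but is not the
  default.
* **Degenerate inputs.** Constant windows flag skewness, kurtosis,
  mobility, complexity, fractal dimension and Hurst as missing (activity
  0 is returned); zero band totals flag relative powers and dependent
  descriptors; constant voxels get r = 0, p = 1; constant regressors score
  zero. All such flags propagate to the missing mask rather than raising
  mid-pipeline.
* **Tie-breaking.** Delay ties go to the smaller delay; ranking ties break
  by maximum |r|, then descriptor id — determinism the tests rely on.
* **BH implementation.** The reference path is `p.adjust(method = "BH")`;
  the bulk scanner exploits that the p-value is strictly decreasing in |r|
  at fixed degrees of freedom and performs the step-up on |r| against
  per-rank critical values, which reproduces the standard procedure
  exactly (tested against an exhaustive step-up oracle).
* **Baselines** are included in the correlated timelines by default: the
  fixation intervals carry most of the load contrast.

## Subject-level delay recovery

The per-feature delay optimizer is unbiased: on synthetic data the
run-averaged score profile of a strong mean-transform descriptor peaks at
the planted delay. Two systematic effects complicate a *subject-level*
delay estimate. First, max3/min3 descriptors time-stretch their regressor
(rising edges move late, falling edges early), which mimics a wider, later
HRF and biases their optimized delay upward by about one grid step.
Second, adjacent delays differ by correlations of ~0.997 at the 3-s grid,
so single-feature delay choices sit on margins of ~0.003 in mean |r|.
`recovery_check()` therefore estimates the subject's delay by *pooling*:
it averages the per-delay score profiles of the subject's top-ranked
features and takes the argmax — the same maximization principle as the
per-feature optimizer, with selection noise averaged out.

## Problem sizes used by the tests

Unit tests run on miniature recordings (seconds of 4-channel EEG at
200 Hz, 6×6×4 grids). The recovery study in the acceptance tests uses the
generator's defaults — 60 channels at 1000 Hz, 4 runs of 540 s, 16×16×8
grid with a 64-voxel VOI, gain 1, snr 2 — over 10 cohorts of 5 subjects;
individual recovery is scored on 20 of those subject datasets (distinct
derived seeds) and group recovery on the 10 cohort rankings. The
`scripts/acceptance.R` report runs one cohort plus four extra subjects.

## Known limitations

* The 3-s convolution grid limits delay resolution; with realistic noise,
  adjacent-delay confusions are the dominant recovery failure mode.
* The elbow parameters (w = 10, eps = 0.002) and the 100/200 caps are
  operating-point choices; score curves from other data may elbow very
  differently.
* The EDF writer quantizes to 16 bits over each channel's observed range;
  round-trips are exact only to that quantization.
* Group analysis assumes all subjects share one descriptor inventory
  (identical montages).
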