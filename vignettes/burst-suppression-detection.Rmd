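---
title: "Detecting burst-suppression from BOLD fMRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting burst-suppression from BOLD fMRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsdetect)
```

## The problem

Under deep anesthesia the brain's electrical activity alternates between
high-amplitude bursts and quasi-isoelectric suppressions. Because
neurovascular coupling survives this state, the alternation drives a large,
slow, spatially widespread fluctuation of the BOLD fMRI signal. `bsdetect`
identifies that hemodynamic signature directly from an fMRI run — no
concurrent EEG required — and provides the companion tools to validate the
detection against EEG where it exists, to map the engaged voxels, and to
quantify regional amplitude and spectra.

The intended user is an fMRI researcher (human or animal imaging) who wants
to screen anesthetized runs for burst-suppression, or to map its spatial
distribution once detected.

## The detection model

Let $X \in \mathbb{R}^{V \times T}$ hold the preprocessed time series of $V$
retained cortical voxels over $T$ frames (repetition time $\mathrm{TR}$).
The pipeline in `bs_detect()` is:

1. **Voxel retention.** Temporal SNR is the voxelwise ratio of temporal mean
   to temporal SD. Voxels with $\mathrm{tSNR} < 15$, voxels outside the
   cortical mask, and constant/non-finite voxels are dropped. Exactly 15 is
   retained (the cutoff omits strictly smaller values).
2. **Detrend + bandpass.** Each row is residualized, in one joint
   least-squares projection, against Legendre polynomials of degree
   $0..3$ and all discrete Fourier regressors *outside* the passband
   (0.005–0.12 Hz; 0.008–0.15 Hz for rats). This is the exact orthogonal
   projector onto the in-band spectral subspace intersected with the
   polynomial complement: idempotent, transient-free, and testably
   orthogonal to every removed regressor. Band edges are inclusive.
3. **Z-scoring.** Each row is normalized to mean 0, population SD 1
   (denominator $n$; the same SD convention is used everywhere in the
   package for self-consistency between tSNR, z-scoring and ROI SD).
4. **Carpet ordering.** Rows are sorted by decreasing Pearson correlation
   with the mean cortical time series — a display ordering only (a
   permutation view); nothing downstream depends on it.
5. **Temporal PCA.** SVD of the z-scored matrix. The temporal PCs are the
   right singular vectors (unit norm; the PCs are only ever used as
   correlation/regression targets, which are scale-invariant). Explained
   variance ratios are $\sigma_k^2 / \sum_j \sigma_j^2$. Five components
   are extracted by default.
6. **Asymmetry scoring.** Each PC is correlated with every retained voxel.
   If the median correlation is negative the PC and its correlations are
   sign-flipped, so PC polarity matches the majority of voxels. The median
   cortex-wide $r$ is the PC's asymmetry score; a 50-bin histogram of $r$
   over $[-1, 1]$ is attached (equal-width bins, right-open except the last).
7. **Classification.** With $m_1 \ge m_2$ the two largest scores, the run
   is burst-suppression iff $m_1 > \theta$ and, where an exclusion margin
   $\Delta$ applies, $m_1 - m_2 \ge \Delta$. The presets are
   $\theta = 0.45$ (human), $0.15$ (macaque), $0.22$ (marmoset), and
   $0.2$ with $\Delta = 0.15$ (rat). The thresholds are deliberately
   heuristic and species-specific; the package does not attempt data-driven
   threshold selection. A gap of exactly $\Delta$ is accepted — "within
   $\Delta$" is read as a strict inequality — and exact score ties resolve
   toward the lower PC rank.

## The EEG-derived hemodynamic model

For validation against concurrent EEG, `segment_eeg()` converts a
microvolt trace into a per-frame binary envelope: for each frame a 6 s Hann
window is extracted, its power spectral density computed (single-window
Welch periodogram, density scaling), and power integrated by trapezoid over
0.5–8 Hz; frames below 100 µV² are suppressions (0), the rest bursts (1).

The window is centered on the **midpoint** of each volume's acquisition
interval ($k \cdot \mathrm{TR} + \mathrm{TR}/2$). A per-volume state
describes the whole interval $[k\,\mathrm{TR}, (k{+}1)\,\mathrm{TR})$, so a
midpoint-centered window samples the interval symmetrically; onset-centered
windows straddle two states at every frame boundary and measurably blur the
segmentation. EEG timestamps are assumed aligned to volume onsets
(`t0` shifts the window centers when they are not); alignment is the
caller's responsibility.

`envelope_to_model()` convolves the envelope with a two-gamma HRF

$$h(t) = g(t;\,a_1, b_1) - c\, g(t;\,a_2, b_2),$$

with gamma densities $g$ and defaults $a_1 = 6, b_1 = 1$ (peak near 5 s),
$a_2 = 16, b_2 = 1$ (undershoot near 15 s), $c = 1/6$ — the widely used
canonical shape, all exposed through `hrf_params()` since anesthesia is
known to slow the HRF. The kernel is sampled at the frame rate over 32 s
and scaled to peak 1. Before convolution the envelope is extended into the
past with its initial state for one kernel duration: the run starts
mid-anesthesia, not at stimulus onset, so the steady-state convolution is
the right boundary model (and a constant envelope then maps to a constant,
which the subsequent bandpass projection removes exactly). The result is
passed through the same bandpass projector as the fMRI data (polynomial
order 0) and is therefore zero-mean.

`crosscorrelate()` reports the Pearson correlation at zero lag, the maximum
over integer frame lags within ±30 s (overlapping segments only, no
padding), and the lag at the maximum, ties resolving toward the smallest
magnitude. Positive lag means the PC is delayed relative to the model,
the direction anesthesia-slowed hemodynamics produce.

## Maps and ROI metrics

`voxelwise_regression()` produces single-run maps: per-voxel Pearson $r$
against a regressor and $z = \operatorname{atanh}(r)\sqrt{T - 3}$, with
$|z|$ capped at 40 so volumes stay finite and unretained voxels set to
`NA`. This is a deliberate simplification of a prewhitened GLM: for a
single regressor, OLS correlation and GLM $t$ are monotonically equivalent,
and group-level permutation inference is out of this package's scope.

`neighborhood_cross_correlation()` compares two maps as the mean of local
Pearson correlations over cubic neighborhoods (half-width 4 voxels by
default, configurable; clipped at edges, masked voxels only, neighborhoods
with fewer than 5 valid voxels or zero variance skipped). It is symmetric
and invariant to per-map affine rescaling. The implementation uses
cumulative-sum box filters; the unit tests pin it to a direct
per-neighborhood loop. Cross-tool numerical identity with other software's
windowing internals is not claimed.

`roi_signal()` returns the ROI-mean series as percent signal change about
the temporal mean; `roi_metrics()` gives its population SD, a Welch PSD
(Hann windows, 100-point segments, 50-point overlap, density scaling), and
trapezoid-integrated $\log_{10}$ PSD over a low (0.005–0.05 Hz) and high
(0.05–0.12 Hz) band; bins with power below 1e-300 are excluded and counted.
No installed Welch estimator was available in R, so the estimator is
implemented here and verified against Parseval and sine-peak oracles.

## The synthetic phantom

`simulate_bold()` generates the ground-truthed data every test runs on:

- **Envelope**: an alternating renewal process, epoch durations uniform on
  mean ± jitter quantized to frames — the simplest process with
  controllable mean durations. Defaults: 20 ± 10 s bursts and
  suppressions, i.e. suppression roughly half the time and an alternation
  timescale (~0.025 Hz) inside the analysis band, human-like at TR 2 s
  over 300 frames (10 min).
- **Engaged voxels** (60% of a central cortical box by default) carry the
  envelope convolved with the HRF, peak-normalized, scaled to 1% of a
  baseline of 1000, optionally delayed by `hemo_lag_s` (fractional-frame
  shifts via linear interpolation).
- **All voxels** receive temporally white Gaussian noise (1% default,
  matched between engaged and non-engaged voxels — SNR 1) plus a random
  quadratic polynomial drift (0.5% coefficients). The bandpass step imposes
  realistic temporal smoothness on the white noise.
- **EEG** (`simulate_eeg()`): 0.5–8 Hz-limited Gaussian noise amplitude-
  modulated so integrated band power is 300 µV² in bursts and 20 µV² in
  suppressions, with 0.5 s raised-cosine cross-fades.
- All randomness derives from one seed through fixed per-component
  sub-seeds, so phantoms are exactly reproducible.

What the phantom does **not** emulate: spatially structured physiological
noise, motion, temporal autocorrelation of scanner noise (an AR structure
would shrink effective degrees of freedom and lower real-data SNR),
regionally varying HRFs, partial-volume effects, and registration error.
Passing the synthetic suite therefore demonstrates the algorithm's
correctness and its power/specificity under the stated noise model, not
performance on any particular scanner dataset; the species thresholds in
particular remain heuristic choices whose appropriateness depends on
acquisition parameters.

## Numerical choices and degenerate inputs

- SDs are population SDs (denominator $n$) throughout.
- The bandpass projector keeps DFT frequencies $j/(T\,\mathrm{TR})$ with
  band-edge comparisons at tolerance 1e-12; the Nyquist sine column (even
  $T$) is dropped as identically zero.
- Constant rows abort z-scoring with an error rather than silently
  producing NaNs; `build_voxel_set()` removes them beforehand (non-finite
  voxels are zeroed at load and flagged constant).
- Empty voxel selections raise an error naming the filter that removed
  everything.
- Smoothing uses constant-zero padding at volume edges; masks are applied
  before smoothing when given.
- `classify_run()` with a single PC treats the second score as $-\infty$
  (no exclusion possible).
- Cross-correlation at extreme lags with constant overlapping segments
  yields `NA` for that lag and is ignored in the maximum.

## Problem sizes in the test suite

The suite validates on grids of $12 \times 12 \times 6$ voxels (a
$6 \times 6 \times 3$ cortical box, 108 voxels) at 300 frames — small
enough that the 100-phantom power and specificity experiments and the
oracle sweeps complete in a few minutes on one core, while keeping the
frames-to-voxels ratio and band geometry of a real 10-minute acquisition.
Oracle comparisons (PCA vs. eigendecomposition, map vs. per-voxel loop,
neighborhood correlation vs. per-neighborhood loop) run on random matrices
up to $60 \times 50$ and a $20^3$ grid.

## A worked run

```{r}
ph <- simulate_bold(phantom_config(seed = 42))
fit <- bs_detect(ph$run, ph$truth$cortex_mask, species = "human")
summary(fit)
```

```{r}
eeg <- simulate_eeg(ph$truth$envelope, fs = 200, seed = 42)
bs_validate_eeg(fit, eeg)
```

## Known limitations

- The detector is a heuristic screen, not an automated classifier: the
  median-$r$ thresholds are species-, agent- and acquisition-dependent.
- Runs in near-constant suppression with a single brief burst can evade
  detection (little variance for the PC to capture).
- Single-run maps use correlation/Fisher-Z, not prewhitened GLM $t$; use a
  dedicated stats package for inference across runs.
- Preprocessing before the package boundary (slice timing, motion,
  registration) is assumed done by standard neuroimaging tools.
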