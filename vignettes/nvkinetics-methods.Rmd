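---
title: "Models and methods behind nvkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nvkinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvkinetics)
```

# The problem

Concurrent widefield calcium fluorescence and BOLD fMRI recordings make it
possible to watch neuronal (RCaMP), astrocytic (GCaMP) and hemodynamic
activity respond to the same stimulus in the same animal. The quantitative
questions are always the same: how large and how fast is each cell type's
stimulus-evoked response (activation intensity, time-to-peak, width,
decay), how strongly are the signals coupled across modalities (per-cycle
correlation), and by how much does one signal lead another
(cross-correlation latency). `nvkinetics` implements that analysis chain —
stimulus-cycle epoching and fractional change, per-trial kinetic
descriptors, first-level GLM activation mapping for the 4-D BOLD data,
rigid mutual-information coregistration, and the cross-modal statistics —
together with a synthetic-data generator that produces every input with
known ground truth, so each stage is verifiable without any acquisition.

# The stimulation paradigm

Electrical forepaw stimulation: 0.5 ms, 0.5 mA pulses at 4 Hz for 8 s,
repeated every 90 s for 9 cycles after an 82 s baseline lead. The paradigm
object stores the onset times; every modality derives its regressors and
epochs from this shared clock. The total duration is the exact sum of the
components (82 + 9 x 90 = 892 s); protocols usually quote the rounded
900 s acquisition length. Pulse-level detail is metadata only — responses
are driven per onset, because at these indicator and hemodynamic time
scales individual 0.5 ms pulses are far below temporal resolution.

# The single-cycle response waveform

No ground-truth cellular waveform is observable, so the generator uses a
compactly supported pulse with independently controllable descriptors:

* rise on `[0, ttp]`: `A * sin(pi t / (2 ttp))^p` — smooth,
  gamma-variate-like onset, exactly `A` at the peak;
* return on `[ttp, ttp + decay]`: `A * (1 - u)^q` with
  `u = (t - ttp)/decay` — an exponential-like relaxation that reaches
  baseline *exactly* at `ttp + decay`.

A literal exponential return never reaches baseline, which would make the
decay-time descriptor (first return to baseline) undefined; the power-law
return keeps the descriptor's geometry exact. `p` and `q` have closed
forms given the half-maximum half-widths, and the full width at half
maximum is split between rise and return in proportion to `ttp` and
`decay`. `calibrate_waveform()` verifies by round-trip that
`compute_metrics()` on the sampled waveform reproduces every descriptor to
within one sample period.

# Trace generation and the noise model

Each channel's trace is `1 + sum of lag-shifted waveforms at the onsets +
drift + noise`, in fractional units around unit baseline. Per-cycle
response amplitudes share a latent cycle strength `s_k ~ N(1, 0.1)`; the
astrocytic and hemodynamic channels add a small independent jitter
(SD 0.02) on top of `s_k`, so neuronal and astrocytic activation peaks are
linearly coupled across cycles by construction — the mechanism believed to
underlie the observed neuron-astrocyte correlation. Noise is i.i.d.
Gaussian per sample at the native rate (40 Hz fluorescence, 1 Hz BOLD)
with SD defaulting to one tenth of the channel's response amplitude
(single-trial peak SNR of about 10).

The BOLD channel has two generation modes. The default (`"profile"`) uses
its own calibrated waveform, so noiseless extraction recovers the BOLD
descriptors exactly and the group recovery study is well posed. The
mechanistic mode (`"hrf"`) convolves the neuronal waveform train with the
rodent HRF and rescales the single-cycle peak — the linear time-invariant
model used for predicted-hemodynamic comparisons. The two modes answer
different questions: the first "what do the analysis stages recover of
known kinetics", the second "how does a hemodynamic transform distort the
neuronal signal".

What the generator does *not* emulate: photon/shot-noise optics,
per-pulse electrophysiology, spatially structured physiological noise,
indicator saturation, and nonlinear neurovascular coupling. Passing tests
therefore demonstrate correctness of the analysis chain on idealized
signals with realistic first-order statistics, not robustness to every
artifact of real recordings.

# The packaged calibrations

`kinetics_group_targets()` holds the group-level descriptor table
(mean ± SEM over 8 animals x 9 cycles) that the packaged simulation is
meant to reproduce. Extracting descriptors from *noisy single trials* is
not bias-free: the maximum of a noisy trace overshoots the peak, Gaussian
denoising widens the width slightly, and the first return to baseline is a
first-passage statistic that waits on the noise floor. The packaged
generator inputs (`group_profiles()`) are therefore *pipeline-calibrated*:
`calibrate_generator_profiles()` iterates simulate → extract → compare →
adjust until the across-trial means extracted under the default study
conditions land on the targets, and the frozen result ships in the
package (`analysis/01_calibrate_generator.R` regenerates it). The inputs
differ from the targets by at most a few hundred milliseconds — exactly
the estimator offsets they absorb.

`single_subject_profiles()` is the calibration for the cross-modal
correlation/latency analyses: neuronal and astrocytic channels share one
waveform shape with the astrocytic one lagged by 0.2889 s, isolating the
latency as a pure time shift (a cross-correlation latency between
different waveform *shapes* would conflate shape and lag).

# Kinetics extraction

Per-trial analysis treats one stimulation cycle as one trial. Each trace
is epoched into a 10 s pre / 8 s on / 60 s post window; fractional change
`(signal - baseline)/baseline` uses each cycle's own 10 s pre-stimulus
baseline, in percent. Descriptors:

* **intensity** — maximum of the post-onset trace;
* **TTP** — time of that maximum, referenced to stimulation onset (the
  onset start is the unambiguous reference on the shared clock);
* **FWHM** — width at half the maximum, linearly interpolated, taking the
  outermost crossings that bracket the global peak if noise produces
  several;
* **decay time** — first post-peak return to baseline (0%), linearly
  interpolated; a trace that never returns inside the window reports the
  window limit with a flag. A half-return variant is available
  (`decay_mode = "half"`); the baseline-return definition is the default.

`trial_metrics()` denoises each cycle with a 0.25 s Gaussian kernel before
applying these definitions. The width was chosen from a bias/variance
study on synthetic data with known truth: it suppresses the peak-picking
noise bias while distorting a 6.5 s wide response by well under one
sample-equivalent; `compute_metrics()` itself never smooths, so noiseless
round-trips are exact.

# First-level GLM

The BOLD path mirrors a standard first-level analysis: drop the first 5 s
of scans, realign (6-parameter rigid, sum-of-squared-differences cost,
Nelder-Mead simplex, two passes with the mean image as reference,
trilinear resampling), reslice to 0.2 mm isotropic voxels, smooth with a
0.6 mm FWHM Gaussian. The design holds the task regressor (boxcar for
signals with unknown response functions, HRF-convolved boxcar for BOLD, or
a measured response resampled to the scan grid), an explicit constant,
optionally the six motion parameters, and a discrete-cosine high-pass
basis of order `floor(2 n TR / 200 + 1)` (1/200 Hz cut-on). Including the
DCT columns in the design is equivalent to pre-filtering by
residualization, and keeps the degrees of freedom bookkeeping explicit.
Per voxel, ordinary least squares gives `beta = (X'X)^{-1} X'y` and the
contrast t statistic with `n - rank(X)` degrees of freedom (one-sided
activation p-values). Family-wise error control is Bonferroni —
`p < alpha/m` over the m tested voxels — rather than random-field theory:
conservative, assumption-free and exactly testable; on the generator's
compact activation with smoothing it recovers the full activated block
while staying within one voxel of it. For fluorescence frames (a 4-D
lattice with a single slice) the same path applies and the task beta map
is used directly as the activation map.

The rodent HRF is the SPM-convention double gamma
`h(t) = g(t; p1/p3, p3) - (1/p5) g(t; p2/p4, p4)` with parameters
`[2.3, 16, 0.34, 1, 6, 0, 8]`, peaking at `p1 - p3 = 1.96 s`. The 8 s
kernel length truncates before the 16 s undershoot peak, so the rodent
kernel is effectively a single positive lobe; the human default
`[6, 16, 1, 1, 6, 0, 32]` retains the undershoot, and a 32 s rodent
variant is one parameter away. Kernels are normalized to unit peak so that
regression coefficients stay in fractional-change units (SPM normalizes by
sum; `normalize = "sum"` reproduces that).

# Coregistration and parcellation

Cross-modal alignment uses the shared vascular structure: a rigid 2-D
transform (rotation + translation; the full 3-D SPM chain is out of scope)
maximizing mutual information between 32-bin joint histograms with linear
partial-volume binning. The optimizer is a deterministic coarse-to-fine
pattern search (4 px / 2 deg initial steps halved to 0.05 px / 0.02 deg),
which avoids the flat-gradient pathologies of histogram-based costs. Links
of the fluorescence → angiography → anatomical → functional chain compose
by matrix multiplication. On shared-vessel-tree phantoms with a known
transform the search recovers (5 px, 3 deg) to within 0.05 px / 0.05 deg.

The miniature atlas stands in for a real labelled brain atlas (which is
deliberately not downloaded or redistributed): contiguous cortical regions
over depth-indexed layers 1–6, always including an S1FL (forelimb
somatosensory) region. Projection to the 2-D fluorescence template takes,
per surface pixel, the majority region label among layer 1–4 voxels —
the superficial layers that dominate widefield fluorescence — with ties
resolved to the lowest label id; deep layers never contribute.

ROI time courses use world coordinates with half-open bounds
`[center - size/2, center + size/2)` and voxel centres at
`(index - 1/2) * voxel`, so a 0.6 mm cube at 0.2 mm voxels averages
exactly 27 voxels.

# Cross-modal statistics

Per-cycle Pearson correlations are Fisher z-transformed
(`z = atanh r`; `|r| = 1` maps to a capped z with a flag) and averaged
with SEM across cycles. Cross-rate pairs are block-averaged down to the
coarser rate. The packaged analysis correlates the evoked-response window
(2 s before onset to 20 s after) rather than the full 78 s epoch: over the
full window the statistic is dominated by the baseline noise floor, whose
attenuation depends on the sampling rate and masks the response
co-variation of interest; the full-window variant remains available
(`window = NULL`, the function default).

Latency uses the normalized cross-correlation over lags up to ±5 s with
3-point parabolic sub-sample interpolation, after denoising both signals
with an identical Gaussian kernel (identical kernels leave the
cross-correlation peak of a pure time shift in place) and restricting to
the same evoked-response window. Positive lag means the second signal
follows the first. At the default noise level the 9-cycle mean lag has a
standard deviation of roughly 10 ms across simulations — about the
information-theoretic limit for a shift estimate between two noisy copies
of a ~4 s rise waveform — so single-simulation recoveries of the 0.2889 s
astrocytic lag scatter by a few tens of milliseconds.

Group comparisons use the two-tailed Mann-Whitney U test (midrank ties):
exact enumeration when the pooled sample is at most 12 without ties,
otherwise the normal approximation with tie and continuity corrections.
Linear couplings are summarized by least squares with
`R^2 = 1 - SS_res/SS_tot`.

# Numerical choices and degenerate inputs

Interpolation is trilinear/bilinear with edge-clamped (volumes) or
zero-filled (2-D transforms) boundaries; spatial smoothing uses
replicate padding so constant images are preserved exactly. Constant
images yield zero mutual information with a warning; constant cycles are
skipped in correlation with a warning; a constant 4-D series realigns to
identity motion with a warning. Epochs truncated by the trace bounds are
dropped with a warning, and a single surviving cycle reports SEM 0 with an
explicit flag. All simulations are driven by explicit integer seeds and
are bit-reproducible; `run_pipeline()` embeds an MD5 hash of its
configuration in every output.

# Problem sizes

The packaged studies are sized so a complete run stays light: the group
recovery study simulates 8 subjects x 9 cycles x 3 channels
(~36,000 samples per fluorescence trace), the volume analyses use a
24 x 16 x 4 lattice with the full 892-scan series (the geometry scales to
80 x 40 x 11 unchanged), and registration phantoms are 128 px square.
`analysis/01_calibrate_generator.R`, the only heavier computation,
re-derives the frozen calibration from ~370,000 simulated trials worth of
extractions in a few minutes.

# Known limitations

* The decay-time estimator is a first-passage statistic; on noisy single
  trials its error is not monotone in the noise level (positive
  noise-floor waits and negative early-dip crossings partially cancel),
  which is why the packaged generator is calibrated through the full
  pipeline rather than descriptor-by-descriptor.
* Rotation parameters of the realignment are weakly constrained on small
  test lattices (sub-degree accuracy only); translations are accurate to
  well under a tenth of a voxel.
* Bonferroni FWE is conservative under the spatial correlation introduced
  by smoothing; detection power on small activations is correspondingly
  pessimistic relative to random-field thresholds.
* The 2-D rigid registration does not model the out-of-plane component of
  a real fluorescence-to-MRI alignment; the phantom chain emulates its
  logic, not its geometry.
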