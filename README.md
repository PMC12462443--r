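# nvkinetics

Quantitative analysis of concurrently recorded neuronal (RCaMP),
astrocytic (GCaMP) widefield calcium fluorescence and BOLD fMRI responses
to cyclic sensory stimulation in rodents — for researchers studying
neurovascular coupling who need the full chain from raw multimodal
recordings to cell-type-specific response kinetics, activation maps and
cross-modal statistics, plus a ground-truth simulator to validate every
stage.

## What it computes

**Stimulus-cycle kinetics.** Traces are epoched per stimulation cycle
(10 s pre / 8 s on / 60 s post), converted to percent fractional change
ΔF/F = (signal − baseline)/baseline against each cycle's own pre-stimulus
baseline, and summarized per trial by four descriptors: activation
intensity (peak ΔF/F), time-to-peak (TTP, from stimulation onset), full
width at half maximum (FWHM, interpolated crossings) and decay time
(first interpolated return of the post-peak trace to baseline).

**First-level GLM.** For the 4-D BOLD series: scan dropping, rigid-body
realignment, reslicing, Gaussian smoothing (0.6 mm FWHM), then per voxel
ordinary least squares y = Xβ + ε with a design of task regressor,
constant, optional motion parameters and a discrete-cosine high-pass
basis (1/200 Hz cut-on). The task contrast c = (1, 0, …)ᵀ gives
t = cᵀβ̂ / √(σ̂² cᵀ(XᵀX)⁻¹c), thresholded at a Bonferroni family-wise
error level of p < 0.05. The hemodynamic response function is the
SPM-convention double gamma with the rodent-adapted parameter vector
[2.3, 16, 0.34, 1, 6, 0, 8] (peak at 1.96 s), unit-peak normalized.

**Coregistration and parcellation.** Rigid 2-D mutual-information
registration (32-bin partial-volume joint histograms, deterministic
coarse-to-fine search) along a fluorescence → angiography → anatomy →
functional chain with transform composition, plus projection of a layered
atlas to a superficial-layer (1–4) surface template and world-coordinate
ROI extraction (0.6 mm cube).

**Cross-modal statistics.** Per-cycle Pearson correlation with Fisher
z = atanh(r), cross-correlation latency with parabolic sub-sample
interpolation, least-squares couplings with R², and two-tailed
Mann-Whitney U comparisons (exact for small untied samples).

**Synthetic data.** All inputs are generable with known ground truth:
stimulus paradigm (0.5 ms / 0.5 mA pulses at 4 Hz, 8 s trains, 90 s
cycles, 9 cycles), calibrated single-cycle waveforms, multi-channel
traces, structured 4-D BOLD volumes with optional rigid motion,
fluorescence frame stacks under a Gaussian PSF, shared-vasculature
registration phantoms and a miniature layered atlas. The packaged
per-channel profiles are calibrated so the pipeline's extracted group
statistics reproduce the reference group-level kinetics; see the methods
vignette (`vignettes/nvkinetics-methods.Rmd`).

## Worked example

```r
library(nvkinetics)

paradigm <- make_paradigm()                       # 9 x 90 s cycles, 82 s lead
traces <- synth_traces(paradigm, group_profiles(), seed = 1)

ep <- fractional_change(epoch_cycles(traces$RCaMP, paradigm))
summarize_metrics(trial_metrics(ep))
#> Kinetics over 9 trials (mean +/- SEM):
#>   intensity (%)    3.869 +/- 0.100
#>   TTP (s)          3.844 +/- 0.038
#>   FWHM (s)         6.516 +/- 0.077
#>   decay (s)        8.834 +/- 0.189

lat_tr <- synth_traces(paradigm, single_subject_profiles(), seed = 1)
eR <- fractional_change(epoch_cycles(lat_tr$RCaMP, paradigm))
eG <- fractional_change(epoch_cycles(lat_tr$GCaMP, paradigm))
latency_analysis(eR, eG)$mean_lag
#> [1] 0.3052
```

One subject's nine neuronal trials recover the configured group kinetics
(intensity ≈ 3.87 %, TTP ≈ 3.84 s, FWHM ≈ 6.52 s, decay ≈ 8.83 s), and the
per-cycle cross-correlation estimates the configured 0.2889 s astrocytic
lag to within a few tens of milliseconds — the precision limit at the
default single-trial SNR of 10.

The numbered scripts under `analysis/` run the complete workflow
(generator calibration, group cohort, GLM activation mapping,
coregistration, cross-modal statistics) and write their tables and maps
to `results/`.

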