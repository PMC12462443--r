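Package: nvkinetics
Title: Kinetics of Concurrent Neuronal, Astrocytic and Hemodynamic Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of concurrently recorded widefield
    calcium fluorescence (neuronal RCaMP, astrocytic GCaMP) and BOLD fMRI
    responses to a cyclic forepaw stimulation paradigm in rodents. Provides a
    synthetic-data generator with known ground truth (stimulus paradigm,
    calibrated single-cycle response waveforms, multi-trial traces, 4-D BOLD
    volumes, fluorescence frame stacks, vascular registration phantoms and a
    miniature layered atlas), a rodent-adapted double-gamma hemodynamic
    response function, first-level GLM activation mapping (realignment,
    reslicing, Gaussian smoothing, DCT high-pass, OLS t-contrasts, Bonferroni
    family-wise-error masks), mutual-information rigid 2-D coregistration with
    cortical-layer atlas projection, stimulus-cycle kinetics extraction
    (activation intensity, time-to-peak, FWHM, decay time), and cross-modal
    statistics (per-cycle Pearson correlation with Fisher z, sub-sample
    cross-correlation latency, linear fits, Mann-Whitney tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    RNifti,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
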