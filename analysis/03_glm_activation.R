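#!/usr/bin/env Rscript
# First-level activation mapping on a simulated BOLD acquisition: drop the
# initial scans, smooth, build the design (HRF-convolved task regressor +
# DCT high-pass), fit the voxel-wise GLM, threshold at FWE p < 0.05
# (Bonferroni) and extract the activated-ROI time course. A reduced
# lattice (24 x 16 x 4 voxels) keeps the run light; the geometry scales
# to the full 80 x 40 x 11 acquisition unchanged.

suppressPackageStartupMessages(library(nvkinetics))
dir.create("results", showWarnings = FALSE)

paradigm <- make_paradigm()
center <- (floor(c(24, 16, 4) / 2) - 0.5) * c(0.25, 0.25, 0.7)
vol <- synth_bold_volume(paradigm, activation_center = center,
                         activation_profile = group_profiles()$BOLD,
                         dim = c(24, 16, 4), voxel = c(0.25, 0.25, 0.7),
                         noise_sd = 0.5, seed = 1)
truth <- attr(vol, "activation_mask")

vol2 <- smooth_volume(drop_initial_scans(vol, 5), 0.6)
n <- dim(vol2$data)[4]
task <- build_regressor(paradigm, fs = 1, kind = "convolved")[6:(5 + n)]
X <- build_design(task, highpass = dct_highpass_basis(n, 1, 200))
fit <- fit_glm(vol2, X, contrast = c(1, 0))
mask <- fwe_mask(fit, alpha = 0.05)

write_volume(volume4d(array(fit$tmap, c(dim(fit$tmap), 1)), vol$voxel),
             "results/tmap.nii.gz")
write_volume(volume4d(array(as.numeric(mask), c(dim(mask), 1)), vol$voxel),
             "results/fwe_mask.nii.gz")
write.csv(cbind(scan = seq_len(n), unclass(X)), "results/design_matrix.csv",
          row.names = FALSE)

roi <- extract_roi_timecourse(vol2, center, size_mm = 0.6)
ep <- fractional_change(epoch_cycles(roi, paradigm))
m <- compute_metrics(average_cycles(ep))

cat(sprintf("Design: %d scans x %d regressors (task, constant, %d DCT)\n",
            n, ncol(X), ncol(X) - 2))
cat(sprintf("FWE mask: %d voxels (true activated block: %d voxels)\n",
            sum(mask), sum(truth)))
cat(sprintf("  detects the whole block: %s; within 1-voxel dilation: see tests\n",
            all(mask[truth])))
cat(sprintf("Activated-ROI mean response: %.2f%% peak, TTP %.1f s, FWHM %.1f s\n",
            m$intensity, m$ttp, m$fwhm))
cat("  (the 0.6 mm kernel dilutes the peak of a 0.6 mm activation block;\n")
cat("   timing descriptors are unaffected)\n")
cat("Wrote results/tmap.nii.gz, results/fwe_mask.nii.gz, results/design_matrix.csv\n")
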