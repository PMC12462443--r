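#' Sampled signal trace
#'
#' Lightweight container for a regularly sampled signal: channel label,
#' sampling rate, sample values and the time of the first sample.
#'
#' @param values Numeric vector of samples.
#' @param fs Sampling rate, Hz.
#' @param channel Channel label (e.g. `"RCaMP"`, `"GCaMP"`, `"BOLD"`).
#' @param t0 Time of the first sample, seconds (default 0).
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(values, fs, channel = "trace", t0 = 0) {
  stop_if(!is_number(fs) || fs <= 0, "`fs` must be > 0")
  structure(list(values = as.numeric(values), fs = fs, channel = channel,
                 t0 = t0), class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %s: %d samples at %g Hz (t0 = %g s, %.1f s)\n",
              x$channel, length(x$values), x$fs, x$t0,
              length(x$values) / x$fs))
  invisible(x)
}

#' Time axis of a trace
#' @param trace A [trace_set()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace)
  trace$t0 + (seq_along(trace$values) - 1L) / trace$fs

#' Packaged kinetic-profile calibrations
#'
#' `group_profiles()` returns the per-channel *generator inputs* of the
#' packaged group-level simulation (8 mice x 9 cycles): neuronal RCaMP with
#' the highest amplitude and fastest time-to-peak, astrocytic GCaMP
#' intermediate, and the BOLD response slowest and weakest. The numbers are
#' the frozen output of [calibrate_generator_profiles()]: generator
#' descriptors adjusted so that the across-trial means *extracted by the
#' analysis pipeline* under the default study conditions (default noise,
#' per-trial smoothing) reproduce the group targets in
#' [kinetics_group_targets()]. They therefore differ slightly from those
#' targets, absorbing the small systematic offsets of the per-trial
#' estimators on noisy data.
#'
#' `single_subject_profiles()` returns the representative single-subject
#' calibration used for the cross-modal correlation/latency analyses: the
#' astrocytic channel shares the neuronal waveform shape but lags it by
#' 0.2889 s, so the cross-correlation latency between the two channels is
#' the configured lag by construction.
#'
#' @return Named list of [kinetic_profile()] objects
#'   (`RCaMP`, `GCaMP`, `BOLD`).
#' @export
group_profiles <- function() {
  ## frozen output of calibrate_generator_profiles(); regenerate with
  ## analysis/01_calibrate_generator.R
  list(
    RCaMP = kinetic_profile(3.8545, 3.9475, 6.5187,  8.1665, lag = 0,
                            channel = "RCaMP"),
    GCaMP = kinetic_profile(2.0795, 6.0102, 6.5189, 10.3655, lag = 0,
                            channel = "GCaMP"),
    BOLD  = kinetic_profile(1.2001, 7.4303, 10.2520, 12.0909, lag = 0,
                            channel = "BOLD"))
}

#' @rdname group_profiles
#' @export
single_subject_profiles <- function() {
  list(
    RCaMP = kinetic_profile(1.8908, 3.8357, 6.572,  8.953, lag = 0,
                            channel = "RCaMP"),
    GCaMP = kinetic_profile(1.9578, 3.8357, 6.572,  8.953, lag = 0.2889,
                            channel = "GCaMP"),
    BOLD  = kinetic_profile(1.3436, 8.1111, 10.120, 12.530, lag = 0,
                            channel = "BOLD"))
}

#' Simulate multi-cycle traces for all channels
#'
#' Each channel is generated as `baseline 1.0 + sum over cycles of the
#' lag-shifted calibrated waveform (fractional units) + linear drift +
#' i.i.d. Gaussian noise`. Per-cycle response amplitudes share a latent
#' cycle strength: the neuronal amplitude of cycle k is
#' `amplitude * s_k` with `s_k ~ N(1, amp_cv)`, and the astrocytic and
#' hemodynamic amplitudes follow the same `s_k` plus a small coupling
#' jitter — so neuronal and astrocytic activation peaks are linearly
#' related across cycles by construction. True per-cycle amplitudes are
#' recorded as ground truth.
#'
#' By default the BOLD channel carries its own calibrated waveform
#' (`bold_mode = "profile"`), so noiseless kinetics extraction recovers its
#' profile exactly. `bold_mode = "hrf"` instead convolves the neuronal
#' percent-signal train with the rodent HRF and rescales the single-cycle
#' peak to the BOLD profile amplitude — the mechanistic
#' linear-time-invariant route used for predicted-hemodynamic analyses.
#'
#' @param paradigm A [make_paradigm()] object.
#' @param profiles Named list of [kinetic_profile()]s; names must be among
#'   `RCaMP`, `GCaMP`, `BOLD`.
#' @param noise_sd Per-channel i.i.d. Gaussian noise SD in percent of
#'   baseline; a single number recycles. Default `NULL` uses
#'   `amplitude / 10` per channel (single-trial peak SNR of about 10).
#' @param drift Linear drift slope, fractional signal per second.
#' @param seed Integer seed; identical seeds reproduce identical traces.
#' @param amp_cv SD of the latent per-cycle strength (relative).
#' @param coupling_jitter SD of the non-neuronal channels' extra amplitude
#'   jitter (relative).
#' @param fs_fluo,fs_bold Sampling rates, Hz (40 fluorescence, 1 BOLD).
#' @param bold_mode `"profile"` or `"hrf"` (see Details).
#' @param hrf HRF parameters for `bold_mode = "hrf"`.
#' @return Named list of [trace_set()]s with attributes
#'   `cycle_amplitudes` (matrix channel x cycle, percent) and
#'   `cycle_strength` (latent `s_k`).
#' @export
synth_traces <- function(paradigm, profiles = group_profiles(),
                         noise_sd = NULL, drift = 0, seed = NULL,
                         amp_cv = 0.1, coupling_jitter = 0.02,
                         fs_fluo = 40, fs_bold = 1,
                         bold_mode = c("profile", "hrf"),
                         hrf = hrf_params()) {
  stopifnot(inherits(paradigm, "stim_paradigm"))
  stop_if(length(profiles) == 0, "`profiles` must be nonempty")
  bold_mode <- match.arg(bold_mode)
  known <- c("RCaMP", "GCaMP", "BOLD")
  bad <- setdiff(names(profiles), known)
  stop_if(length(bad) > 0,
          paste0("unknown channel label(s): ", paste(bad, collapse = ", ")))
  if (is.null(noise_sd))
    noise_sd <- vapply(profiles, function(p) p$amplitude / 10, 0)
  noise_sd <- rep_len(noise_sd, length(profiles))
  names(noise_sd) <- names(profiles)
  stop_if(any(noise_sd < 0), "`noise_sd` must be >= 0")

  with_seed(seed, {
    nc <- paradigm$n_cycles
    s <- 1 + stats::rnorm(nc, 0, amp_cv)
    amps <- matrix(NA_real_, length(profiles), nc,
                   dimnames = list(names(profiles), NULL))
    out <- list()
    for (ch in names(profiles)) {
      pr <- profiles[[ch]]
      fs <- if (ch == "BOLD") fs_bold else fs_fluo
      n <- round(paradigm$total_duration * fs)
      t <- (seq_len(n) - 1L) / fs
      scale_k <- if (ch == "RCaMP") s
                 else s + stats::rnorm(nc, 0, coupling_jitter)
      amps[ch, ] <- pr$amplitude * scale_k
      y <- numeric(n)
      if (ch == "BOLD" && bold_mode == "hrf" &&
          (profiles$RCaMP %||% pr)$amplitude > 0) {
        ## neuronal percent train at BOLD rate, convolved with the HRF
        neu <- profiles$RCaMP %||% pr
        f <- waveform_fun(kinetic_profile(neu$amplitude, neu$ttp, neu$fwhm,
                                          neu$decay_half))
        for (k in seq_len(nc))
          y <- y + scale_k[k] * f(t - paradigm$onsets[k] - pr$lag)
        kern <- double_gamma_hrf(hrf, dt = 1 / fs)$values
        y <- stats::convolve(y, rev(kern), type = "open")[seq_len(n)]
        one <- stats::convolve(
          f(t - paradigm$onsets[1]), rev(kern), type = "open")[seq_len(n)]
        y <- y * pr$amplitude / max(one)
      } else {
        f <- waveform_fun(kinetic_profile(1, pr$ttp, pr$fwhm, pr$decay_half))
        for (k in seq_len(nc))
          y <- y + pr$amplitude * scale_k[k] *
            f(t - paradigm$onsets[k] - pr$lag)
      }
      values <- 1 + y / 100 + drift * t +
        stats::rnorm(n, 0, noise_sd[[ch]] / 100)
      out[[ch]] <- trace_set(values, fs, channel = ch)
    }
    attr(out, "cycle_amplitudes") <- amps
    attr(out, "cycle_strength") <- s
    out
  })
}
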