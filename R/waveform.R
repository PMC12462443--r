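#' Kinetic profile of a stimulus-evoked response
#'
#' Descriptor set driving the trace generator and serving as recovery
#' ground truth: peak fractional-change amplitude (percent), time-to-peak
#' from stimulation onset, full width at half maximum, decay time (peak back
#' to baseline level), and an optional lag relative to the neuronal channel.
#'
#' @param amplitude Peak fractional change, percent (> 0).
#' @param ttp Time-to-peak from onset start, seconds (> 0).
#' @param fwhm Full width at half maximum, seconds (> 0).
#' @param decay_half Time from peak back to baseline, seconds (> 0).
#' @param lag Lag relative to the neuronal channel, seconds.
#' @param channel Optional channel label.
#' @return An object of class `kinetic_profile`.
#' @export
kinetic_profile <- function(amplitude, ttp, fwhm, decay_half, lag = 0,
                            channel = NULL) {
  ## amplitude 0 is allowed as a null (no-response) profile; waveform
  ## calibration itself requires a positive amplitude
  stop_if(!is_number(amplitude) || amplitude < 0, "`amplitude` must be >= 0")
  stop_if(!is_number(ttp) || ttp <= 0, "`ttp` must be > 0")
  stop_if(!is_number(fwhm) || fwhm <= 0, "`fwhm` must be > 0")
  stop_if(!is_number(decay_half) || decay_half <= 0, "`decay_half` must be > 0")
  stop_if(!is_number(lag), "`lag` must be finite")
  structure(list(amplitude = amplitude, ttp = ttp, fwhm = fwhm,
                 decay_half = decay_half, lag = lag, channel = channel),
            class = "kinetic_profile")
}

## Closed-form shape calibration shared by waveform_fun / calibrate_waveform.
## The single-cycle response is compactly supported on [0, ttp + decay_half]:
##   rise  (0 <= t <= ttp):            A * sin(pi * t / (2 ttp))^p
##   return (ttp < t <= ttp + decay):  A * (1 - (t - ttp)/decay)^q
## p and q are solved so the half-maximum crossings sit at ttp - wr and
## ttp + wf with wr + wf = fwhm; fwhm is split between rise and return in
## proportion to their time scales (ttp vs decay_half), clamped to the
## feasible open intervals.
waveform_shape <- function(profile) {
  ttp <- profile$ttp; fwhm <- profile$fwhm; dec <- profile$decay_half
  if (fwhm >= ttp + dec)
    stop(sprintf(paste0(
      "infeasible kinetic profile: fwhm (%.3f s) must be smaller than ",
      "ttp + decay_half (%.3f s)"), fwhm, ttp + dec), call. = FALSE)
  wr <- fwhm * ttp / (ttp + dec)
  ## clamp so both half-widths stay strictly inside their feasible ranges
  eps <- 1e-6
  wr <- min(max(wr, fwhm - (1 - eps) * dec), (1 - eps) * ttp)
  wr <- max(wr, eps * fwhm)
  wf <- fwhm - wr
  p <- log(0.5) / log(sin(pi * (ttp - wr) / (2 * ttp)))
  q <- log(0.5) / log(1 - wf / dec)
  list(wr = wr, wf = wf, p = p, q = q)
}

#' Continuous single-cycle waveform evaluator
#'
#' Returns a vectorized function `f(t)` giving the noiseless single-cycle
#' response in percent fractional change at time `t` seconds after
#' stimulation onset (the profile's `lag` is not applied here). The waveform
#' is nonnegative, compactly supported on `[0, ttp + decay_half]`, peaks at
#' exactly `(ttp, amplitude)`, has half-maximum width `fwhm`, and returns to
#' baseline exactly `decay_half` after the peak — so the kinetics extractor
#' recovers the profile's descriptors from it by construction.
#'
#' @param profile A [kinetic_profile()].
#' @return Function mapping seconds-from-onset to percent.
#' @export
waveform_fun <- function(profile) {
  stopifnot(inherits(profile, "kinetic_profile"))
  sh <- waveform_shape(profile)
  A <- profile$amplitude; ttp <- profile$ttp; dec <- profile$decay_half
  function(t) {
    y <- numeric(length(t))
    r <- t >= 0 & t <= ttp
    y[r] <- A * sin(pi * t[r] / (2 * ttp))^sh$p
    f <- t > ttp & t < ttp + dec
    y[f] <- A * (1 - (t[f] - ttp) / dec)^sh$q
    y
  }
}

#' Calibrate a single-cycle waveform to a kinetic profile
#'
#' Samples the calibrated waveform at rate `fs` over one response support
#' and verifies by round-trip that [compute_metrics()] on the sampled
#' waveform reproduces the profile's descriptors to within one sample
#' period.
#'
#' @param profile A [kinetic_profile()].
#' @param fs Sampling rate, Hz; must satisfy `fs * ttp >= 4`.
#' @param check Run the round-trip verification (default `TRUE`).
#' @return Object of class `cycle_waveform`: `t` (seconds from onset),
#'   `values` (percent), `fs`, `profile`, `shape` (internal rise/return
#'   parameters), and `metrics` (round-trip check) when `check` is `TRUE`.
#' @export
calibrate_waveform <- function(profile, fs, check = TRUE) {
  stopifnot(inherits(profile, "kinetic_profile"))
  stop_if(profile$amplitude <= 0,
          "calibration failure: `amplitude` must be > 0 for a waveform")
  stop_if(!is_number(fs) || fs * profile$ttp < 4,
          "`fs` too low: need fs * ttp >= 4 samples on the rise")
  f <- waveform_fun(profile)
  sh <- waveform_shape(profile)
  t <- seq(0, profile$ttp + profile$decay_half + 2 / fs, by = 1 / fs)
  w <- structure(list(t = t, values = f(t), fs = fs, profile = profile,
                      shape = sh), class = "cycle_waveform")
  if (check) {
    ## prepend a short zero baseline so onset-referenced metrics apply
    pre <- round(2 * fs)
    m <- compute_metrics(c(numeric(pre), w$values), fs = fs,
                         onset_index = pre + 1L)
    ## ttp/fwhm quantize to half a sample; the baseline-return crossing can
    ## additionally land a full sample late on the compact support boundary;
    ## the peak sample undershoots the true amplitude by at most the local
    ## curvature over half a sample
    tol <- 1 / fs + 1e-9
    tol_int <- profile$amplitude -
      min(f(profile$ttp - 0.5 / fs), f(profile$ttp + 0.5 / fs)) + 1e-9
    bad <- c(intensity = abs(m$intensity - profile$amplitude) > tol_int,
             ttp = abs(m$ttp - profile$ttp) > tol,
             fwhm = abs(m$fwhm - profile$fwhm) > tol,
             decay_half = abs(m$decay_half - profile$decay_half) / 2 > tol)
    if (any(bad))
      stop("waveform calibration failed the metric round-trip for: ",
           paste(names(bad)[bad], collapse = ", "), call. = FALSE)
    w$metrics <- m
  }
  w
}
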