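#' Electrical forepaw stimulation paradigm
#'
#' Describes the cyclic stimulation protocol shared by all modalities: brief
#' unipolar current pulses delivered in trains ("onsets") repeated over a
#' fixed cycle period, after an initial baseline recording lead.
#'
#' The defaults encode the protocol used throughout the package: 0.5 ms /
#' 0.5 mA pulses at 4 Hz for 8 s, repeated every 90 s for 9 cycles, with the
#' first 82 s reserved for baseline. Total duration is the exact sum of the
#' component timings, `baseline_lead + n_cycles * cycle_period` (892 s with
#' the defaults; acquisition protocols often quote this rounded to 900 s).
#'
#' @param pulse_width Single pulse duration in seconds (metadata only).
#' @param pulse_amplitude Pulse current in mA (metadata only).
#' @param pulse_rate Pulse repetition rate within an onset, Hz.
#' @param onset_duration Duration of each stimulation train, seconds.
#' @param cycle_period Stimulus repetition period, seconds.
#' @param n_cycles Number of stimulation cycles.
#' @param baseline_lead Baseline recording before the first onset, seconds.
#' @return An object of class `stim_paradigm` with the fields above plus
#'   `onsets` (onset start times in seconds) and `total_duration`.
#' @examples
#' p <- make_paradigm()
#' p$onsets[1]            # 82
#' length(p$onsets)       # 9
#' @export
make_paradigm <- function(pulse_width = 5e-4, pulse_amplitude = 0.5,
                          pulse_rate = 4, onset_duration = 8,
                          cycle_period = 90, n_cycles = 9,
                          baseline_lead = 82) {
  for (nm in c("pulse_width", "pulse_rate", "onset_duration", "cycle_period")) {
    v <- get(nm)
    stop_if(!is_number(v) || v <= 0,
            sprintf("invalid paradigm config: `%s` must be a positive number", nm))
  }
  stop_if(!is_number(baseline_lead) || baseline_lead < 0,
          "invalid paradigm config: `baseline_lead` must be >= 0")
  stop_if(!is_number(n_cycles) || n_cycles < 1,
          "invalid paradigm config: `n_cycles` must be >= 1")
  stop_if(onset_duration >= cycle_period,
          "invalid paradigm config: `onset_duration` must be < `cycle_period`")
  n_cycles <- as.integer(n_cycles)
  onsets <- baseline_lead + (seq_len(n_cycles) - 1L) * cycle_period
  structure(list(
    pulse_width = pulse_width, pulse_amplitude = pulse_amplitude,
    pulse_rate = pulse_rate, onset_duration = onset_duration,
    cycle_period = cycle_period, n_cycles = n_cycles,
    baseline_lead = baseline_lead, onsets = onsets,
    total_duration = baseline_lead + n_cycles * cycle_period
  ), class = "stim_paradigm")
}

#' @export
print.stim_paradigm <- function(x, ...) {
  cat(sprintf(
    "Stimulation paradigm: %d cycles of %g s on / %g s period (%.1f ms pulses at %g Hz),\n  %g s baseline lead, total %g s\n",
    x$n_cycles, x$onset_duration, x$cycle_period, 1000 * x$pulse_width,
    x$pulse_rate, x$baseline_lead, x$total_duration))
  invisible(x)
}

#' Binary stimulus vector at a given sampling rate
#'
#' Samples the paradigm's on/off state on the acquisition clock: 1 while a
#' stimulation train is on, 0 otherwise. Sample i covers time
#' `[(i-1)/fs, i/fs)`; membership uses the sample start time (half-open
#' onset intervals).
#'
#' @param paradigm A [make_paradigm()] object.
#' @param fs Sampling rate in Hz.
#' @return Integer vector of length `round(total_duration * fs)`.
#' @export
stimulus_vector <- function(paradigm, fs) {
  stopifnot(inherits(paradigm, "stim_paradigm"))
  stop_if(!is_number(fs) || fs <= 0, "invalid-config: `fs` must be > 0")
  n <- round(paradigm$total_duration * fs)
  t <- (seq_len(n) - 1L) / fs
  on <- rep(0L, n)
  for (o in paradigm$onsets)
    on[t >= o & t < o + paradigm$onset_duration] <- 1L
  on
}

#' Pulse times of the paradigm
#'
#' Individual pulse start times; each onset contains
#' `pulse_rate * onset_duration` pulses.
#'
#' @inheritParams stimulus_vector
#' @return Numeric vector of pulse start times in seconds.
#' @export
pulse_times <- function(paradigm) {
  stopifnot(inherits(paradigm, "stim_paradigm"))
  per_onset <- round(paradigm$pulse_rate * paradigm$onset_duration)
  as.numeric(vapply(paradigm$onsets, function(o)
    o + (seq_len(per_onset) - 1L) / paradigm$pulse_rate,
    numeric(per_onset)))
}

#' USAF-1951 resolution target line-pair period
#'
#' The USAF-1951 chart encodes spatial frequency as
#' `2^(group + (element - 1)/6)` line pairs per mm; the period of one line
#' pair is its reciprocal. Resolving group 3, element 6 corresponds to a
#' ~70 um period.
#'
#' @param group Chart group number (integer, may be negative).
#' @param element Element within the group, 1..6.
#' @return List with `period_um` (exact) and `period_rounded_um` (nearest
#'   10 um).
#' @examples
#' usaf_resolution(3, 6)$period_rounded_um  # 70
#' @export
usaf_resolution <- function(group, element) {
  stop_if(!is_number(group) || group != round(group),
          "`group` must be an integer")
  stop_if(!is_number(element) || !(element %in% 1:6),
          "`element` must be an integer in 1..6")
  period <- 1000 / 2^(group + (element - 1) / 6)
  list(period_um = period, period_rounded_um = round(period / 10) * 10)
}
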