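#' Epoch a trace into stimulation cycles
#'
#' Cuts one row per stimulation cycle out of a trace, aligned to the onset,
#' covering a window of `pre` seconds before the onset, the `on` seconds of
#' stimulation and `post` seconds after it (default 10/8/60 s, a 78 s
#' epoch). Cycles whose window extends beyond the trace are dropped with a
#' warning.
#'
#' @param trace A [trace_set()].
#' @param paradigm A [make_paradigm()] object.
#' @param window Named numeric vector `c(pre =, on =, post =)`, seconds.
#' @return Object of class `epoched_cycles`: `cycles` (matrix
#'   n_cycles x samples), `fs`, `window`, `onset_index` (first sample at or
#'   after the onset), `percent` (FALSE until [fractional_change()]).
#' @export
epoch_cycles <- function(trace, paradigm, window = c(pre = 10, on = 8,
                                                     post = 60)) {
  stopifnot(inherits(trace, "trace_set"), inherits(paradigm, "stim_paradigm"))
  stop_if(!all(c("pre", "on", "post") %in% names(window)),
          "`window` needs named elements pre, on, post")
  fs <- trace$fs
  len <- round(sum(window) * fs)
  pre_n <- round(window[["pre"]] * fs)
  n <- length(trace$values)
  rows <- list()
  dropped <- 0L
  for (o in paradigm$onsets) {
    start <- round((o - window[["pre"]] - trace$t0) * fs) + 1L
    if (start < 1L || start + len - 1L > n) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- trace$values[start:(start + len - 1L)]
  }
  if (dropped > 0L)
    warning(sprintf("%d cycle(s) truncated by the trace bounds were dropped",
                    dropped), call. = FALSE)
  stop_if(length(rows) == 0, "no complete stimulation cycle inside the trace")
  structure(list(cycles = do.call(rbind, rows), fs = fs, window = window,
                 onset_index = pre_n + 1L, percent = FALSE,
                 channel = trace$channel),
            class = "epoched_cycles")
}

#' Per-cycle fractional signal change
#'
#' Converts each epoch row to percent fractional change
#' `(signal(t) - baseline) / baseline * 100`, with the baseline taken as the
#' mean of that cycle's pre-stimulation window. The pre-window mean of the
#' output is zero by construction.
#'
#' @param ep An [epoch_cycles()] object holding raw signal.
#' @return The same object with `cycles` in percent and `percent = TRUE`.
#' @export
fractional_change <- function(ep) {
  stopifnot(inherits(ep, "epoched_cycles"))
  stop_if(isTRUE(ep$percent), "cycles are already in percent units")
  pre_n <- ep$onset_index - 1L
  stop_if(pre_n < 1L, "no pre-stimulation samples to estimate the baseline")
  base <- rowMeans(ep$cycles[, seq_len(pre_n), drop = FALSE])
  stop_if(any(base <= 0),
          "baseline mean <= 0: raw signal expected to be positive")
  ep$cycles <- 100 * sweep(sweep(ep$cycles, 1, base, "-"), 1, base, "/")
  ep$percent <- TRUE
  ep
}

#' Cycle-averaged time course with SEM
#'
#' Pointwise mean across cycles and standard error of the mean
#' `sd / sqrt(n)`. With a single cycle the SEM is reported as zero and the
#' result carries the attribute `sem_undefined = TRUE`.
#'
#' @param ep An [epoched_cycles()] object.
#' @return List with `mean`, `sem` (vectors), `n_cycles`, `fs`,
#'   `onset_index`.
#' @export
average_cycles <- function(ep) {
  stopifnot(inherits(ep, "epoched_cycles"))
  n <- nrow(ep$cycles)
  m <- colMeans(ep$cycles)
  sem <- if (n > 1) apply(ep$cycles, 2, stats::sd) / sqrt(n)
         else numeric(length(m))
  out <- list(mean = m, sem = sem, n_cycles = n, fs = ep$fs,
              onset_index = ep$onset_index)
  if (n == 1) attr(out, "sem_undefined") <- TRUE
  out
}

#' Kinetic descriptors of an activation time course
#'
#' Extracts the four response descriptors from a fractional-change trace
#' (percent units): activation intensity (maximum of the post-onset trace),
#' time-to-peak referenced to stimulation onset, full width at half maximum
#' with linearly interpolated crossings (outermost crossings around the
#' global peak when noise produces several), and decay time — the linearly
#' interpolated first return of the post-peak trace to baseline level (0%).
#' If the trace never returns to baseline inside the window, the decay is
#' reported as the window limit with `decay_truncated = TRUE`.
#'
#' @param trace Numeric vector in percent fractional change (or the result
#'   of [average_cycles()], from which `fs` and `onset_index` are taken).
#' @param fs Sampling rate, Hz.
#' @param onset_index 1-based index of the first sample at/after onset.
#' @param decay_mode `"baseline"` (default; return to 0%) or `"half"`
#'   (return to half the peak).
#' @return List: `intensity` (percent), `ttp`, `fwhm`, `decay_half`
#'   (seconds), `decay_truncated` (logical).
#' @export
compute_metrics <- function(trace, fs = NULL, onset_index = NULL,
                            decay_mode = c("baseline", "half")) {
  decay_mode <- match.arg(decay_mode)
  if (is.list(trace) && !is.null(trace$mean)) {
    fs <- fs %||% trace$fs
    onset_index <- onset_index %||% trace$onset_index
    trace <- trace$mean
  }
  stop_if(is.null(fs) || is.null(onset_index),
          "`fs` and `onset_index` required for vector input")
  n <- length(trace)
  stop_if(onset_index < 1L || onset_index > n, "onset outside the trace")
  post <- trace[onset_index:n]
  ipk_rel <- which.max(post)
  peak <- post[ipk_rel]
  stop_if(!is.finite(peak) || peak <= 0,
          "no positive post-onset peak in the trace")
  ipk <- onset_index + ipk_rel - 1L
  ttp <- (ipk - onset_index) / fs
  half <- peak / 2

  ## FWHM: outermost half-maximum crossings bracketing the global peak,
  ## searched within the post-onset segment only
  seg <- trace[onset_index:n]
  ip <- ipk_rel
  up <- which(seg[-length(seg)] < half & seg[-1] >= half)   # upward at i -> i+1
  dn <- which(seg[-length(seg)] >= half & seg[-1] < half)   # downward
  up <- up[up < ip]
  dn <- dn[dn >= ip]
  left <- if (length(up)) cross_index(seg[min(up)], seg[min(up) + 1L],
                                      min(up), half) else 1
  right <- if (length(dn)) cross_index(seg[max(dn)], seg[max(dn) + 1L],
                                       max(dn), half) else length(seg)
  fwhm <- (right - left) / fs

  ## decay: first post-peak return to the reference level
  lev <- if (decay_mode == "baseline") 0 else half
  tail_idx <- which(post[ipk_rel:length(post)] <= lev)
  if (length(tail_idx) == 0) {
    decay <- (length(post) - ipk_rel) / fs
    truncated <- TRUE
  } else {
    j <- ipk_rel + tail_idx[1L] - 1L
    cj <- if (j == ipk_rel) j else cross_index(post[j - 1L], post[j], j - 1L, lev)
    decay <- (cj - ipk_rel) / fs
    truncated <- FALSE
  }
  list(intensity = peak, ttp = ttp, fwhm = fwhm, decay_half = decay,
       decay_truncated = truncated)
}

#' Per-trial kinetic metrics
#'
#' Applies [compute_metrics()] to every cycle of an epoched, fractional-
#' change trace, treating one stimulation cycle as one trial. Each cycle is
#' first denoised with a short Gaussian kernel (`smooth_sigma` seconds)
#' matched to the sub-second rise of the responses; the raw descriptor
#' definitions are then applied to the smoothed trace. `smooth_sigma = 0`
#' disables smoothing.
#'
#' @param ep An [epoched_cycles()] object in percent units (raw input is
#'   converted via [fractional_change()] first).
#' @param smooth_sigma Gaussian smoothing SD in seconds (default 0.25).
#' @param decay_mode Passed to [compute_metrics()].
#' @return `data.frame` with one row per cycle: `cycle`, `intensity`,
#'   `ttp`, `fwhm`, `decay_half`, `decay_truncated`.
#' @export
trial_metrics <- function(ep, smooth_sigma = 0.25,
                          decay_mode = c("baseline", "half")) {
  stopifnot(inherits(ep, "epoched_cycles"))
  decay_mode <- match.arg(decay_mode)
  if (!isTRUE(ep$percent)) ep <- fractional_change(ep)
  res <- lapply(seq_len(nrow(ep$cycles)), function(k) {
    y <- gauss_smooth(ep$cycles[k, ], smooth_sigma * ep$fs)
    m <- compute_metrics(y, fs = ep$fs, onset_index = ep$onset_index,
                         decay_mode = decay_mode)
    data.frame(cycle = k, intensity = m$intensity, ttp = m$ttp,
               fwhm = m$fwhm, decay_half = m$decay_half,
               decay_truncated = m$decay_truncated)
  })
  do.call(rbind, res)
}

#' Across-trial summary of kinetic metrics
#'
#' Mean and SEM of each descriptor across trials (rows of a
#' [trial_metrics()] table, possibly pooled over subjects).
#'
#' @param df A data frame with columns `intensity`, `ttp`, `fwhm`,
#'   `decay_half`.
#' @return List of class `kinetics_metrics` with `mean` and `sem` named
#'   vectors and `n_trials`.
#' @export
summarize_metrics <- function(df) {
  cols <- c("intensity", "ttp", "fwhm", "decay_half")
  stop_if(!all(cols %in% names(df)), "missing descriptor columns")
  n <- nrow(df)
  m <- vapply(df[cols], mean, 0)
  s <- if (n > 1) vapply(df[cols], stats::sd, 0) / sqrt(n)
       else stats::setNames(numeric(4), cols)
  structure(list(mean = m, sem = s, n_trials = n), class = "kinetics_metrics")
}

#' @export
print.kinetics_metrics <- function(x, ...) {
  cat(sprintf("Kinetics over %d trials (mean +/- SEM):\n", x$n_trials))
  lab <- c(intensity = "intensity (%)", ttp = "TTP (s)", fwhm = "FWHM (s)",
           decay_half = "decay (s)")
  for (k in names(lab))
    cat(sprintf("  %-14s %7.3f +/- %.3f\n", lab[[k]], x$mean[[k]], x$sem[[k]]))
  invisible(x)
}
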