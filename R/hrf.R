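#' Double-gamma hemodynamic response function parameters
#'
#' Seven-parameter HRF in the SPM `spm_hrf` convention: delay and dispersion
#' of the positive response and of the undershoot, response/undershoot
#' ratio, onset delay, and kernel length. The defaults are the
#' rodent-adapted vector `[2.3, 16, 0.34, 1, 6, 0, 8]`, tailored to the fast
#' small-animal BOLD response; [hrf_params_spm()] returns the human default
#' `[6, 16, 1, 1, 6, 0, 32]`.
#'
#' Note the rodent vector's 8 s kernel length truncates the kernel before
#' the 16 s undershoot peak, so the rodent kernel is effectively a single
#' positive lobe. Use `p7 = 32` to retain the undershoot.
#'
#' @param p1,p2 Response and undershoot delay, seconds.
#' @param p3,p4 Response and undershoot dispersion, seconds.
#' @param p5 Response/undershoot amplitude ratio.
#' @param p6 Onset delay, seconds.
#' @param p7 Kernel length, seconds.
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(p1 = 2.3, p2 = 16, p3 = 0.34, p4 = 1, p5 = 6,
                       p6 = 0, p7 = 8) {
  p <- c(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5, p6 = p6, p7 = p7)
  stop_if(!all(is.finite(p)), "HRF parameters must be finite")
  stop_if(any(p[c("p1", "p2", "p3", "p4", "p5", "p7")] <= 0),
          "HRF delays, dispersions, ratio and kernel length must be > 0")
  stop_if(p["p6"] < 0, "HRF onset `p6` must be >= 0")
  structure(as.list(p), class = "hrf_params")
}

#' @rdname hrf_params
#' @export
hrf_params_spm <- function() hrf_params(6, 16, 1, 1, 6, 0, 32)

#' Sample the double-gamma HRF kernel
#'
#' `h(t) = dgamma(t - p6, shape = p1/p3, scale = p3) -
#' (1/p5) * dgamma(t - p6, shape = p2/p4, scale = p4)` sampled on
#' `[0, p7]` at step `dt`. The positive lobe peaks at `p6 + p1 - p3` (mode
#' of a gamma with shape `p1/p3`, scale `p3`). By default the kernel is
#' normalized to unit peak so that regression coefficients against a
#' fractional-change signal stay in fractional-change units; `"sum"`
#' reproduces the SPM normalization, `"none"` leaves raw density units.
#'
#' @param params An [hrf_params()] object.
#' @param dt Sampling step, seconds (`0 < dt <= p7`).
#' @param normalize One of `"peak"` (default), `"sum"`, `"none"`.
#' @return List with `t` (times), `values`, `dt`, `params`.
#' @examples
#' k <- double_gamma_hrf(hrf_params(), dt = 0.01)
#' k$t[which.max(k$values)]   # ~1.96 s = p1 - p3
#' @export
double_gamma_hrf <- function(params = hrf_params(), dt = 1 / 40,
                             normalize = c("peak", "sum", "none")) {
  stopifnot(inherits(params, "hrf_params"))
  normalize <- match.arg(normalize)
  stop_if(!is_number(dt) || dt <= 0 || dt > params$p7,
          "`dt` must satisfy 0 < dt <= p7")
  t <- seq(0, params$p7, by = dt)
  tt <- t - params$p6
  h <- stats::dgamma(tt, shape = params$p1 / params$p3, scale = params$p3) -
    (1 / params$p5) *
      stats::dgamma(tt, shape = params$p2 / params$p4, scale = params$p4)
  h[tt < 0] <- 0
  h <- switch(normalize,
              peak = h / max(h),
              sum  = h / sum(h),
              none = h)
  list(t = t, values = h, dt = dt, params = params, normalize = normalize)
}

#' Predicted hemodynamic response by linear convolution
#'
#' Models the hemodynamic response as the output of a linear time-invariant
#' system: the input trace, detrended to a zero baseline, is convolved with
#' the HRF kernel sampled at the trace's rate, truncated to the input
#' length, and the baseline is restored.
#'
#' @param trace A [trace_set()] (or plain numeric vector with `fs`).
#' @param params An [hrf_params()] object.
#' @param baseline Baseline level removed before and restored after the
#'   convolution. Default 0 (an impulse input returns the kernel itself);
#'   use 1 for raw-signal traces around unit baseline.
#' @param fs Sampling rate, required when `trace` is a bare vector.
#' @return Same type as the input: a `trace_set` with channel suffix
#'   `"*HRF"`, or a numeric vector.
#' @export
predict_hemodynamic <- function(trace, params = hrf_params(), baseline = 0,
                                fs = NULL) {
  is_ts <- inherits(trace, "trace_set")
  x <- if (is_ts) trace$values else trace
  if (is_ts) fs <- trace$fs
  stop_if(length(x) == 0, "empty trace")
  stop_if(is.null(fs), "`fs` required for vector input")
  k <- double_gamma_hrf(params, dt = 1 / fs)$values
  y0 <- x - baseline
  out <- stats::convolve(y0, rev(k), type = "open")[seq_along(y0)] + baseline
  if (is_ts) {
    trace$values <- out
    trace$channel <- paste0(trace$channel, "*HRF")
    trace
  } else out
}

#' Build a task regressor column
#'
#' Three regressor kinds used for first-level analysis: a boxcar of the
#' stimulation onsets (used when the cellular response function is unknown,
#' e.g. astrocytic GCaMP), the boxcar convolved with the HRF (BOLD), or a
#' measured/assumed response resampled onto the scan grid (neuronal RCaMP).
#' Columns are returned unscaled and uncentred; the GLM design always
#' includes an explicit constant, so centring does not change the task
#' contrast.
#'
#' @param paradigm A [make_paradigm()] object.
#' @param fs Sampling rate of the scan grid, Hz.
#' @param kind `"boxcar"`, `"convolved"` or `"measured"`.
#' @param params HRF parameters for `kind = "convolved"`.
#' @param measured Numeric vector (with sampling rate `measured_fs`) for
#'   `kind = "measured"`; linearly resampled to the scan grid.
#' @param measured_fs Sampling rate of `measured`, Hz.
#' @return Numeric vector of length `round(total_duration * fs)`.
#' @export
build_regressor <- function(paradigm, fs,
                            kind = c("boxcar", "convolved", "measured"),
                            params = hrf_params(), measured = NULL,
                            measured_fs = NULL) {
  kind <- match.arg(kind)
  box <- as.numeric(stimulus_vector(paradigm, fs))
  n <- length(box)
  switch(kind,
    boxcar = box,
    convolved = {
      k <- double_gamma_hrf(params, dt = 1 / fs)$values
      stats::convolve(box, rev(k), type = "open")[seq_len(n)]
    },
    measured = {
      stop_if(is.null(measured), "`measured` response required")
      stop_if(is.null(measured_fs), "`measured_fs` required")
      t_scan <- (seq_len(n) - 1L) / fs
      t_meas <- (seq_along(measured) - 1L) / measured_fs
      stats::approx(t_meas, measured, xout = t_scan, rule = 2)$y
    })
}
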