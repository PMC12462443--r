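#' Fisher z-transformation
#'
#' Variance-stabilizing transform of a correlation coefficient,
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`.
#'
#' @param r Correlation coefficient(s), `|r| < 1`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  stop_if(any(!is.finite(r)) || any(abs(r) >= 1),
          "Fisher z requires |r| < 1")
  atanh(r)
}

## cap used when a per-cycle correlation is exactly +/-1
.z_cap <- atanh(1 - 1e-12)

## block-average x down to an integer factor
downsample_mean <- function(x, factor) {
  if (factor == 1) return(x)
  n <- floor(length(x) / factor) * factor
  colMeans(matrix(x[seq_len(n)], nrow = factor))
}

#' Per-cycle Pearson correlation with Fisher z
#'
#' Pearson's correlation between two epoched signals, computed cycle by
#' cycle over the full epoch window, then Fisher z-transformed; the mean
#' and SEM of z (and of r) across cycles are reported. When the two signals
#' have different sampling rates the finer one is block-averaged down to
#' the coarser rate. Cycles where either signal is constant are skipped
#' with a warning; `|r| = 1` maps to a capped z with `capped = TRUE`.
#'
#' @param a,b [epoch_cycles()] objects with the same number of cycles.
#' @param window Optional `c(before_onset, after_onset)` seconds restricting
#'   the correlated segment to the evoked-response support; `NULL` (default)
#'   correlates the full epoch window.
#' @return List of class `correlation_result`: `r_per_cycle`,
#'   `z_per_cycle`, `mean_r`, `mean_z`, `sem_z`, `capped`, `skipped`.
#' @export
pearson_per_cycle <- function(a, b, window = NULL) {
  stopifnot(inherits(a, "epoched_cycles"), inherits(b, "epoched_cycles"))
  stop_if(nrow(a$cycles) != nrow(b$cycles),
          "cycle counts differ between the two signals")
  if (!is.null(window)) {
    clip <- function(ep) {
      idx <- max(1, ep$onset_index - round(window[1] * ep$fs)):
        min(ncol(ep$cycles), ep$onset_index + round(window[2] * ep$fs))
      ep$cycles <- ep$cycles[, idx, drop = FALSE]
      ep
    }
    a <- clip(a); b <- clip(b)
  }
  fs <- min(a$fs, b$fs)
  fa <- a$fs / fs; fb <- b$fs / fs
  stop_if(abs(fa - round(fa)) > 1e-8 || abs(fb - round(fb)) > 1e-8,
          "sampling rates must be integer multiples of the coarser rate")
  r <- rep(NA_real_, nrow(a$cycles))
  for (k in seq_len(nrow(a$cycles))) {
    xa <- downsample_mean(a$cycles[k, ], round(fa))
    xb <- downsample_mean(b$cycles[k, ], round(fb))
    m <- min(length(xa), length(xb))
    xa <- xa[seq_len(m)]; xb <- xb[seq_len(m)]
    if (stats::sd(xa) == 0 || stats::sd(xb) == 0) next
    r[k] <- stats::cor(xa, xb)
  }
  skipped <- which(is.na(r))
  if (length(skipped))
    warning(sprintf("%d constant cycle(s) skipped", length(skipped)),
            call. = FALSE)
  ok <- !is.na(r)
  capped <- abs(r) >= 1 & ok
  z <- ifelse(capped, sign(r) * .z_cap, suppressWarnings(atanh(r)))
  zs <- z[ok]
  structure(list(r_per_cycle = r, z_per_cycle = z,
                 mean_r = mean(r[ok]), mean_z = mean(zs),
                 sem_z = if (sum(ok) > 1) stats::sd(zs) / sqrt(sum(ok)) else 0,
                 capped = any(capped), skipped = skipped),
            class = "correlation_result")
}

#' Cross-correlation latency with sub-sample interpolation
#'
#' Normalized cross-correlation between two equally sampled signals over
#' lags in `[-max_lag, max_lag]`; the lag of the correlation maximum is
#' refined by parabolic interpolation through the peak and its two
#' neighbours. Positive lag means `b` lags (comes later than) `a`.
#'
#' @param a,b Numeric vectors of equal length (or [trace_set()]s).
#' @param fs Sampling rate, Hz (taken from `a` if it is a `trace_set`).
#' @param max_lag Maximum |lag| searched, seconds (default 5).
#' @return List: `lag` (seconds), `r_max`, `lags`, `r` (the correlation
#'   function).
#' @export
xcorr_latency <- function(a, b, fs = NULL, max_lag = 5) {
  if (inherits(a, "trace_set")) { fs <- fs %||% a$fs; a <- a$values }
  if (inherits(b, "trace_set")) b <- b$values
  stop_if(is.null(fs), "`fs` required")
  stop_if(length(a) != length(b), "signals must have equal length")
  a <- a - mean(a); b <- b - mean(b)
  stop_if(stats::sd(a) == 0 || stats::sd(b) == 0,
          "flat signal: latency undefined")
  L <- round(max_lag * fs)
  n <- length(a)
  stop_if(L >= n - 1, "`max_lag` too large for the signal length")
  lags <- (-L):L
  r <- vapply(lags, function(l) {
    if (l >= 0) {
      ia <- seq_len(n - l); ib <- ia + l
    } else {
      ib <- seq_len(n + l); ia <- ib - l
    }
    suppressWarnings(stats::cor(a[ia], b[ib]))
  }, 0)
  r[!is.finite(r)] <- -Inf
  i <- which.max(r)
  delta <- 0
  if (i > 1 && i < length(r)) {
    y1 <- r[i - 1]; y2 <- r[i]; y3 <- r[i + 1]
    den <- y1 - 2 * y2 + y3
    if (is.finite(den) && den < 0) delta <- 0.5 * (y1 - y3) / den
  }
  list(lag = (lags[i] + delta) / fs, r_max = r[i], lags = lags / fs, r = r)
}

#' Per-cycle cross-correlation latency
#'
#' [xcorr_latency()] applied cycle by cycle to two epoched signals sampled
#' at the same rate, with mean and SEM of the per-cycle lags.
#'
#' @param a,b [epoch_cycles()] objects (equal `fs` and cycle count).
#' @param max_lag Maximum |lag| searched, seconds.
#' @return List of class `latency_result`: `lag_per_cycle`, `mean_lag`,
#'   `sem_lag`.
#' @export
xcorr_latency_cycles <- function(a, b, max_lag = 5) {
  stopifnot(inherits(a, "epoched_cycles"), inherits(b, "epoched_cycles"))
  stop_if(a$fs != b$fs, "sampling rates differ")
  stop_if(nrow(a$cycles) != nrow(b$cycles), "cycle counts differ")
  lag <- vapply(seq_len(nrow(a$cycles)), function(k)
    xcorr_latency(a$cycles[k, ], b$cycles[k, ], fs = a$fs,
                  max_lag = max_lag)$lag, 0)
  structure(list(lag_per_cycle = lag, mean_lag = mean(lag),
                 sem_lag = if (length(lag) > 1)
                   stats::sd(lag) / sqrt(length(lag)) else 0),
            class = "latency_result")
}

#' Least-squares line with R-squared
#'
#' Simple linear regression `y ~ x` with the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param x,y Numeric vectors, at least 3 points, `var(x) > 0`.
#' @return List: `slope`, `intercept`, `r_squared`.
#' @export
linear_fit_r2 <- function(x, y) {
  stop_if(length(x) != length(y), "lengths differ")
  stop_if(length(x) < 3, "need at least 3 points")
  stop_if(stats::var(x) == 0, "var(x) = 0: slope undefined")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = 1 - ss_res / ss_tot)
}

#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples: the U statistic with
#' midrank ties, an exact two-tailed p-value by complete enumeration when
#' the pooled size is at most 12 and there are no ties, and the normal
#' approximation with tie and continuity correction otherwise (the
#' [stats::wilcox.test()] machinery).
#'
#' @param x,y Nonempty numeric samples.
#' @return List: `U`, `p`, `exact` (logical).
#' @export
mann_whitney <- function(x, y) {
  stop_if(length(x) == 0 || length(y) == 0, "samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Cross-modal latency analysis on epoched cycles
#'
#' The packaged latency estimator: per cycle, both fractional-change
#' signals are restricted to a window around the evoked response (default
#' 2 s before onset to 20 s after), denoised with an identical Gaussian
#' kernel (which leaves the cross-correlation peak position of a pure time
#' shift unchanged), and the lag maximizing the normalized
#' cross-correlation is refined by parabolic interpolation; the mean and
#' SEM over cycles are reported.
#'
#' @param a,b [epoch_cycles()] objects in percent units, same rate and
#'   cycle count; positive lag means `b` lags `a`.
#' @param max_lag Maximum |lag| searched, seconds.
#' @param smooth_sigma Gaussian denoising SD, seconds (same kernel on both
#'   signals).
#' @param window Seconds `c(before_onset, after_onset)` retained around the
#'   stimulation onset.
#' @return List of class `latency_result`: `lag_per_cycle`, `mean_lag`,
#'   `sem_lag`.
#' @export
latency_analysis <- function(a, b, max_lag = 5, smooth_sigma = 0.5,
                             window = c(2, 20)) {
  stopifnot(inherits(a, "epoched_cycles"), inherits(b, "epoched_cycles"))
  stop_if(a$fs != b$fs, "sampling rates differ")
  stop_if(nrow(a$cycles) != nrow(b$cycles), "cycle counts differ")
  fs <- a$fs
  idx <- max(1, a$onset_index - round(window[1] * fs)):
    min(ncol(a$cycles), a$onset_index + round(window[2] * fs))
  lag <- vapply(seq_len(nrow(a$cycles)), function(k) {
    xa <- gauss_smooth(a$cycles[k, idx], smooth_sigma * fs)
    xb <- gauss_smooth(b$cycles[k, idx], smooth_sigma * fs)
    xcorr_latency(xa, xb, fs = fs, max_lag = max_lag)$lag
  }, 0)
  structure(list(lag_per_cycle = lag, mean_lag = mean(lag),
                 sem_lag = if (length(lag) > 1)
                   stats::sd(lag) / sqrt(length(lag)) else 0),
            class = "latency_result")
}
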