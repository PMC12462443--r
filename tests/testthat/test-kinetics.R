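test_that("epoching matches the window arithmetic at both rates", {
  p <- make_paradigm()
  tr40 <- synth_traces(p, seed = 1)
  ep <- epoch_cycles(tr40$RCaMP, p)
  expect_equal(dim(ep$cycles), c(9, 78 * 40))
  expect_equal(ep$onset_index, 10 * 40 + 1)
  epB <- epoch_cycles(tr40$BOLD, p)
  expect_equal(dim(epB$cycles), c(9, 78))
})

test_that("cycles truncated by the trace bounds are dropped with a warning", {
  p <- make_paradigm(baseline_lead = 5)   # pre-window extends before t = 0
  tr <- synth_traces(p, seed = 1)
  expect_warning(ep <- epoch_cycles(tr$RCaMP, p), "dropped")
  expect_equal(nrow(ep$cycles), 8)
  expect_error(
    suppressWarnings(epoch_cycles(trace_set(rep(1, 10), 40), p)),
    "no complete")
})

test_that("fractional change normalizes each cycle to its own baseline", {
  p <- short_paradigm()
  n <- round(p$total_duration * 40)
  ep <- epoch_cycles(trace_set(rep(100, n), 40), p)
  fc <- fractional_change(ep)
  expect_true(all(fc$cycles == 0))
  # baseline 100, plateau 102 -> 2%
  v <- rep(100, n)
  v[stimulus_vector(p, 40) == 1] <- 102
  fc2 <- fractional_change(epoch_cycles(trace_set(v, 40), p))
  expect_equal(max(fc2$cycles), 2)
  ep0 <- epoch_cycles(trace_set(rep(0, n), 40), p)
  expect_error(fractional_change(ep0), "baseline")
  # pre-window mean is zero by construction
  tr <- synth_traces(p, seed = 3)
  fc3 <- fractional_change(epoch_cycles(tr$RCaMP, p))
  expect_equal(rowMeans(fc3$cycles[, 1:(fc3$onset_index - 1), drop = FALSE]),
               rep(0, nrow(fc3$cycles)), tolerance = 1e-10)
})

test_that("cycle averaging reports mean and SEM", {
  p <- short_paradigm()
  ep <- fractional_change(epoch_cycles(synth_traces(p, noise_sd = 0,
                                                    amp_cv = 0,
                                                    coupling_jitter = 0,
                                                    seed = 1)$RCaMP, p))
  av <- average_cycles(ep)
  expect_equal(av$sem, numeric(length(av$sem)), tolerance = 1e-10)
  ep$cycles <- rbind(rep(0, 4), rep(2, 4))
  av2 <- average_cycles(ep)
  expect_equal(av2$mean, rep(1, 4))
  expect_equal(av2$sem, rep(1, 4))     # sd = sqrt(2), / sqrt(2)
  ep$cycles <- ep$cycles[1, , drop = FALSE]
  av1 <- average_cycles(ep)
  expect_true(isTRUE(attr(av1, "sem_undefined")))
  expect_equal(av1$sem, rep(0, 4))
})

test_that("metrics of a piecewise-linear triangle match its geometry", {
  fs <- 40
  rise <- seq(0, 1, length.out = 5 * fs + 1)
  fall <- seq(1, 0, length.out = 10 * fs + 1)[-1]
  tr <- c(numeric(2 * fs), rise, fall, numeric(fs))
  m <- compute_metrics(tr, fs = fs, onset_index = 2 * fs + 1)
  expect_equal(m$intensity, 1)
  expect_equal(m$ttp, 5)
  expect_equal(m$fwhm, 7.5, tolerance = 1e-6)
  expect_equal(m$decay_half, 10, tolerance = 1e-6)
  expect_false(m$decay_truncated)
  expect_error(compute_metrics(numeric(100), fs = fs, onset_index = 1),
               "peak")
})

test_that("decay falls back to the window limit with a flag", {
  fs <- 10
  tr <- c(numeric(10), seq(0, 1, length.out = 21), rep(1, 50))
  m <- compute_metrics(tr, fs = fs, onset_index = 11)
  expect_true(m$decay_truncated)
  m2 <- compute_metrics(tr, fs = fs, onset_index = 11, decay_mode = "half")
  expect_true(m2$decay_truncated)
})

test_that("metrics are invariant to baseline offset and scale correctly", {
  p <- short_paradigm()
  base <- synth_traces(p, noise_sd = 0, amp_cv = 0, coupling_jitter = 0,
                       seed = 1)$RCaMP
  shifted <- trace_set(base$values + 0.5, base$fs, base$channel)
  m1 <- compute_metrics(average_cycles(fractional_change(
    epoch_cycles(base, p))))
  # fractional change uses the shifted baseline, so times are unchanged and
  # the intensity rescales by the baseline ratio
  m2 <- compute_metrics(average_cycles(fractional_change(
    epoch_cycles(shifted, p))))
  expect_equal(m2$ttp, m1$ttp)
  expect_equal(m2$fwhm, m1$fwhm, tolerance = 1e-6)
  expect_equal(m2$decay_half, m1$decay_half, tolerance = 1e-6)
  expect_equal(m2$intensity, m1$intensity / 1.5, tolerance = 1e-6)
  # doubling the waveform amplitude doubles intensity, times unchanged
  prof2 <- lapply(group_profiles(), function(pr)
    kinetic_profile(2 * pr$amplitude, pr$ttp, pr$fwhm, pr$decay_half,
                    pr$lag, pr$channel))
  tr2 <- synth_traces(p, prof2, noise_sd = 0, amp_cv = 0,
                      coupling_jitter = 0, seed = 1)$RCaMP
  m3 <- compute_metrics(average_cycles(fractional_change(
    epoch_cycles(tr2, p))))
  expect_equal(m3$intensity, 2 * m1$intensity, tolerance = 1e-3)
  expect_equal(m3$ttp, m1$ttp, tolerance = 1 / 40)
  expect_equal(m3$fwhm, m1$fwhm, tolerance = 1 / 40)
})

test_that("noiseless extraction recovers every packaged profile", {
  p <- make_paradigm()
  tr <- synth_traces(p, noise_sd = 0, amp_cv = 0, coupling_jitter = 0,
                     seed = 1)
  for (ch in names(tr)) {
    pr <- group_profiles()[[ch]]
    fs <- tr[[ch]]$fs
    m <- compute_metrics(average_cycles(fractional_change(
      epoch_cycles(tr[[ch]], p))))
    expect_lt(abs(m$ttp - pr$ttp), 1 / fs + 1e-9)
    expect_lt(abs(m$fwhm - pr$fwhm), 1 / fs + 1e-9)
    expect_lt(abs(m$decay_half - pr$decay_half), 2 / fs + 1e-9)
    expect_equal(m$intensity, pr$amplitude, tolerance = 0.01)
  }
})

test_that("metric error grows with the noise level", {
  p <- short_paradigm()
  pr <- list(RCaMP = group_profiles()$RCaMP)
  truth <- unlist(group_profiles()$RCaMP[c("amplitude", "ttp", "fwhm",
                                           "decay_half")])
  err <- sapply(c(0, 0.2, 0.8), function(ns) {
    e <- NULL
    for (s in 1:25) {
      tr <- synth_traces(p, pr, noise_sd = ns, amp_cv = 0,
                         coupling_jitter = 0, seed = 1000 + s)
      tm <- trial_metrics(fractional_change(epoch_cycles(tr$RCaMP, p)))
      e <- rbind(e, as.matrix(tm[, c("intensity", "ttp", "fwhm",
                                     "decay_half")]))
    }
    sqrt(colMeans(sweep(e, 2, truth)^2))   # per-trial RMSE vs ground truth
  })
  # root-mean-square trial error nondecreasing in noise; the decay time is
  # a first-passage statistic whose positive noise-floor wait and negative
  # early-dip bias partially cancel at high noise, so for that descriptor
  # only the noiseless-vs-noisy comparison is meaningful
  for (k in 1:3) {
    expect_lte(err[k, 1], err[k, 2] + 1e-9)
    expect_lte(err[k, 2], err[k, 3] + 1e-9)
  }
  expect_lte(err[4, 1], err[4, 2] + 1e-9)
  expect_lte(err[4, 1], err[4, 3] + 1e-9)
})

test_that("group-level ordering of kinetics holds in every seeded run", {
  p <- make_paradigm()
  for (s in 1:5) {
    tr <- synth_traces(p, seed = s)
    tm <- lapply(tr, function(x)
      trial_metrics(fractional_change(epoch_cycles(x, p))))
    ttp <- vapply(tm, function(d) mean(d$ttp), 0)
    amp <- vapply(tm, function(d) mean(d$intensity), 0)
    expect_true(ttp[["RCaMP"]] < ttp[["GCaMP"]])
    expect_true(ttp[["GCaMP"]] < ttp[["BOLD"]])
    expect_true(amp[["RCaMP"]] > amp[["GCaMP"]])
    expect_true(amp[["GCaMP"]] > amp[["BOLD"]])
  }
})

test_that("per-cycle amplitudes of neurons and astrocytes are linearly coupled", {
  p <- make_paradigm()
  tr <- synth_traces(p, seed = 9)
  amps <- attr(tr, "cycle_amplitudes")
  fit <- linear_fit_r2(amps["RCaMP", ], amps["GCaMP", ])
  expect_gt(fit$r_squared, 0.9)
})
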