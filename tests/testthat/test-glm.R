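test_that("GLM estimates match the closed-form OLS oracle exactly", {
  # small worked design: 5 scans, task + constant
  X <- build_design(task = c(0, 1, 0, 1, 1))
  y <- c(1.0, 3.2, 0.8, 3.1, 2.9)
  fit <- fit_glm(matrix(y, ncol = 1), X, contrast = c(1, 0))
  oracle <- ols_bruteforce(unclass(X), y)
  expect_equal(fit$beta[, 1], oracle$beta, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fit$tmap, oracle$tstat(c(1, 0)), tolerance = 1e-12)
  expect_equal(fit$dof, oracle$dof)
  # richer design with drift columns, many voxels
  set.seed(5)
  n <- 60
  X2 <- build_design(task = rep(c(0, 1), 30),
                     highpass = dct_highpass_basis(n, 1, 40))
  Y <- matrix(rnorm(n * 7), n)
  fit2 <- fit_glm(Y, X2)
  for (v in 1:7) {
    o <- ols_bruteforce(unclass(X2), Y[, v])
    expect_equal(fit2$beta[, v], o$beta, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(fit2$tmap[v], o$tstat(fit2$contrast), tolerance = 1e-10)
  }
})

test_that("noiseless task data recover the amplitude with zero residue", {
  X <- build_design(task = rep(c(0, 1), 10))
  y <- 2 * rep(c(0, 1), 10) + 1
  fit <- fit_glm(matrix(y, ncol = 1), X)
  expect_equal(fit$beta[1, 1], 2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fit$beta[2, 1], 1, tolerance = 1e-12, ignore_attr = TRUE)
  # constant data: task effect 0
  fit0 <- fit_glm(matrix(rep(3, 20), ncol = 1), X)
  expect_equal(fit0$beta[1, 1], 0, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("residuals are orthogonal to the design and t is scale-free", {
  set.seed(8)
  n <- 50
  X <- build_design(task = rnorm(n), highpass = dct_highpass_basis(n, 1, 25))
  Y <- matrix(rnorm(n * 4), n)
  fit <- fit_glm(Y, X)
  res <- Y - unclass(X) %*% fit$beta
  expect_lt(max(abs(crossprod(unclass(X), res))) /
              max(abs(crossprod(unclass(X), Y))), 1e-10)
  fit2 <- fit_glm(7.3 * Y, X)
  expect_equal(fit2$tmap, fit$tmap, tolerance = 1e-10)
})

test_that("null data give calibrated type-I rates", {
  set.seed(12)
  n <- 40
  X <- build_design(task = rep(c(0, 1), n / 2))
  Y <- matrix(rnorm(n * 1000), n)
  fit <- fit_glm(Y, X)
  expect_lt(abs(mean(fit$tmap)), 0.1)
  rate <- mean(fit$pmap < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("design assembly enforces rank and column structure", {
  task <- rep(c(0, 1), 10)
  expect_equal(colnames(build_design(task)), c("task", "constant"))
  hp <- dct_highpass_basis(20, 1, 8)
  mot <- matrix(rnorm(120), 20)
  X <- build_design(task, motion = mot, highpass = hp)
  expect_equal(ncol(X), 2 + 6 + ncol(hp))
  expect_error(build_design(task, motion = cbind(mot, task)), "6 motion")
  expect_error(build_design(rep(1, 20)), "collinear|rank")
})

test_that("DCT basis size, orthonormality and drift removal", {
  B <- dct_highpass_basis(900, 1, 200)
  expect_equal(ncol(B), 10)   # floor(2*900/200 + 1)
  expect_equal(crossprod(B), diag(10), tolerance = 1e-10,
               ignore_attr = TRUE)
  # projecting out the basis removes nearly all of a linear drift
  n <- 300
  B2 <- dct_highpass_basis(n, 1, 100)
  drift <- seq(-1, 1, length.out = n)
  resid <- drift - B2 %*% crossprod(B2, drift) - mean(drift)
  expect_lt(max(abs(resid)) / max(abs(drift)), 0.05)
  expect_error(dct_highpass_basis(300, 1, -5), "cutoff")
})

test_that("Bonferroni FWE mask thresholds at alpha over m", {
  set.seed(3)
  X <- build_design(task = rep(c(0, 1), 10))
  Y <- matrix(rnorm(20 * 100), 20)
  fit <- fit_glm(Y, X)
  mk <- fwe_mask(fit, alpha = 0.05)
  expect_equal(attr(mk, "threshold"), 5e-4)
  fit$pmap[] <- 1
  expect_equal(sum(fwe_mask(fit)), 0)
  fit$pmap[] <- 0.5
  fit$pmap[37] <- 1e-6
  mk2 <- fwe_mask(fit, alpha = 0.05)
  expect_equal(which(mk2), 37)
})

test_that("FWE-masked detection is exhaustive and tight on generator data", {
  p <- short_paradigm(3)
  vol <- synth_bold_volume(p, dim = c(12, 10, 3), voxel = c(0.3, 0.3, 0.7),
                           activation_center = c(1.95, 1.35, 1.05),
                           activation_profile =
                             kinetic_profile(4, 7.4, 10.3, 12.1),
                           noise_sd = 0.4, seed = 21)
  truth <- attr(vol, "activation_mask")
  task <- build_regressor(p, 1 / vol$tr, "convolved")
  X <- build_design(task, highpass = dct_highpass_basis(dim(vol$data)[4],
                                                        vol$tr, 200))
  fit <- fit_glm(vol, X)
  mk <- fwe_mask(fit)
  expect_true(all(mk[truth]))          # contains the true block
  # and stays within a 1-voxel dilation of it
  dil <- truth
  idx <- which(truth, arr.ind = TRUE)
  for (r in seq_len(nrow(idx)))
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      v <- idx[r, ] + c(dx, dy, dz)
      if (all(v >= 1) && all(v <= dim(truth))) dil[v[1], v[2], v[3]] <- TRUE
    }
  expect_true(all(dil[mk]))
})

test_that("FWE false-positive rate over null simulations stays below alpha", {
  set.seed(77)
  n <- 30; m <- 60
  X <- build_design(task = rep(c(0, 1), n / 2))
  hits <- vapply(seq_len(200), function(i) {
    fit <- fit_glm(matrix(rnorm(n * m), n), X)
    sum(fwe_mask(fit, 0.05)) > 0
  }, NA)
  rate <- mean(hits)
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lte(rate, 0.05 + 3 * se)
})

test_that("beta map localizes the activation with the injected amplitude", {
  p <- short_paradigm(3)
  prof <- kinetic_profile(3, 3.9, 6.5, 8.2)
  vol <- synth_bold_volume(p, dim = c(10, 8, 3), voxel = c(0.3, 0.3, 0.7),
                           activation_center = c(1.65, 1.05, 1.05),
                           activation_profile = prof, noise_sd = 0,
                           seed = 2)
  truth <- attr(vol, "activation_mask")
  # task regressor = the injected response itself (measured kind)
  resp <- attr(vol, "response")
  task <- build_regressor(p, 1 / vol$tr, "measured", measured = resp,
                          measured_fs = 1 / vol$tr)
  fit <- fit_glm(vol, build_design(task))
  b <- beta_activation_map(fit)
  expect_true(all(abs(b[!truth]) < 1e-8))
  # slope of each activated voxel = its local baseline / 100 (raw units per
  # percent fractional change); frame 1 carries the pure baseline
  base1 <- array(vol$data[, , , 1], dim(truth))
  expect_equal(b[truth], base1[truth] / 100, tolerance = 1e-6)
})

test_that("smoothing preserves the mean and realizes the nominal width", {
  p <- short_paradigm(1)
  vol <- volume4d(array(rnorm(20 * 16 * 5, 100), c(20, 16, 5, 1)),
                  c(0.25, 0.25, 0.25))
  sm <- smooth_volume(vol, 0.6)
  expect_equal(mean(sm$data), mean(vol$data), tolerance = 1e-3)
  expect_identical(smooth_volume(vol, 0)$data, vol$data)
  # delta image -> Gaussian whose measured FWHM is 0.6 mm +/- half a voxel
  delta <- volume4d(array(0, c(41, 41, 1, 1)), c(0.1, 0.1, 0.1))
  delta$data[21, 21, 1, 1] <- 1
  smd <- smooth_volume(delta, 0.6)
  prof <- smd$data[, 21, 1, 1]
  half <- max(prof) / 2
  above <- range(which(prof >= half))
  width_mm <- (diff(above)) * 0.1
  expect_lt(abs(width_mm - 0.6), 0.05 + 0.1)
  expect_error(smooth_volume(vol, -1), "fwhm")
})

test_that("reslicing preserves extent and content", {
  p <- short_paradigm(1)
  vol <- synth_bold_volume(p, dim = c(16, 8, 4), voxel = c(0.25, 0.25, 0.7),
                           activation_center = c(2, 1, 1.05),
                           noise_sd = 0, seed = 4)
  rs <- reslice(vol, c(0.2, 0.2, 0.2))
  expect_equal(dim(rs$data)[1:3], c(20, 10, 14))
  expect_equal(volume_extent(rs), volume_extent(vol), tolerance = 0.2)
  # same-grid reslice is the identity up to interpolation tolerance
  same <- reslice(vol, vol$voxel)
  expect_equal(same$data, vol$data, tolerance = 1e-6)
  const <- volume4d(array(5, c(8, 8, 4, 2)), c(0.5, 0.5, 0.5))
  expect_equal(range(reslice(const, c(0.3, 0.3, 0.3))$data), c(5, 5))
})

test_that("realignment recovers injected translations", {
  p <- make_paradigm(n_cycles = 1, cycle_period = 20, baseline_lead = 4,
                     onset_duration = 4)
  vol <- synth_bold_volume(p, dim = c(16, 12, 5), voxel = c(0.5, 0.5, 0.7),
                           activation_center = c(4, 3, 1.75),
                           noise_sd = 0.1, seed = 7)
  vol$data <- vol$data[, , , 1:8, drop = FALSE]
  # motion-free, noise-free series: parameters stay at the identity
  still <- synth_bold_volume(p, dim = c(16, 12, 5),
                             voxel = c(0.5, 0.5, 0.7),
                             activation_center = c(4, 3, 1.75),
                             noise_sd = 0, seed = 7)
  still$data <- still$data[, , , 1:6, drop = FALSE]
  ra0 <- realign(still, passes = 1)
  expect_lt(max(abs(ra0$motion[, 1:3])), 0.05)
  expect_lt(max(abs(ra0$motion[, 4:6])), 0.05)
  expect_equal(nrow(ra0$motion) * ncol(ra0$motion), 6 * 6)
  # injected 0.5 mm x-translation on volume 5
  vol$data[, , , 5] <- apply_rigid3d(vol$data[, , , 5], c(0.5, 0, 0, 0, 0, 0),
                                     vol$voxel)
  ra <- realign(vol)
  expect_lt(abs(ra$motion[5, 1] - 0.5), 0.1)
  expect_lt(max(abs(ra$motion[-5, 1])), 0.15)
  # constant series: warning and identity motion
  const <- volume4d(array(1, c(6, 6, 3, 4)), c(0.5, 0.5, 0.5))
  expect_warning(rc <- realign(const), "constant")
  expect_true(all(rc$motion == 0))
})

test_that("initial scans are dropped before preprocessing", {
  vol <- volume4d(array(rnorm(4 * 4 * 2 * 20), c(4, 4, 2, 20)),
                  c(0.5, 0.5, 0.5), tr = 1)
  d5 <- drop_initial_scans(vol, 5)
  expect_equal(dim(d5$data)[4], 15)
  expect_equal(attr(d5, "scans_dropped"), 5)
  expect_error(drop_initial_scans(vol, 25), "drop")
})
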