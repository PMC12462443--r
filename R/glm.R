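#' Drop initial scans
#'
#' Discards the first seconds of a 4-D acquisition before preprocessing
#' (signal not yet at steady state); default 5 s.
#'
#' @param vol A [volume4d()].
#' @param seconds Duration to discard.
#' @return The shortened [volume4d()] with attribute `scans_dropped`.
#' @export
drop_initial_scans <- function(vol, seconds = 5) {
  stopifnot(inherits(vol, "volume4d"))
  k <- round(seconds / vol$tr)
  n <- dim(vol$data)[4]
  stop_if(k >= n, "cannot drop all scans")
  out <- volume4d(vol$data[, , , (k + 1):n, drop = FALSE], vol$voxel, vol$tr,
                  t0 = (vol$t0 %||% 0) + k * vol$tr)
  attr(out, "scans_dropped") <- k
  out
}

#' Rigid-body realignment of a 4-D series
#'
#' Estimates a 6-parameter rigid transform per volume (3 translations in
#' mm, 3 rotations in degrees) by minimizing the sum of squared intensity
#' differences against the mean image with a derivative-free simplex
#' search, then resamples each volume with the inverse transform
#' (trilinear). Parameters are reported relative to the first volume, so
#' the first row is the identity.
#'
#' @param vol A [volume4d()].
#' @param subsample Integer stride over voxels for the cost function
#'   (speed/accuracy trade-off).
#' @param passes Estimation passes; the second pass re-estimates against
#'   the mean of the realigned series.
#' @return List: `volumes` (realigned [volume4d()]), `motion`
#'   (n_volumes x 6 matrix, mm and deg).
#' @export
realign <- function(vol, subsample = 1L, passes = 2L) {
  stopifnot(inherits(vol, "volume4d"))
  d <- dim(vol$data)
  stop_if(d[4] < 2, "realignment needs at least 2 volumes")
  if (stats::sd(vol$data) == 0) {
    warning("constant series: identity motion assumed", call. = FALSE)
    return(list(volumes = vol, motion = matrix(0, d[4], 6)))
  }
  voxel <- vol$voxel
  ctr <- d[1:3] * voxel / 2
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  keep <- seq(1, nrow(g), by = subsample)
  w <- cbind((g$x[keep] - 0.5) * voxel[1], (g$y[keep] - 0.5) * voxel[2],
             (g$z[keep] - 0.5) * voxel[3])
  lin <- g$x[keep] + d[1] * (g$y[keep] - 1L) +
    d[1] * d[2] * (g$z[keep] - 1L)
  ## sample v3 after moving its content by -p (i.e. undoing motion p)
  resample_inv <- function(v3, p) {
    R <- rotation3d(p[4], p[5], p[6])
    src <- sweep(w, 2, ctr) %*% t(R)
    src <- sweep(src, 2, ctr + p[1:3], "+")
    sample_trilinear(v3, src[, 1] / voxel[1] + 0.5,
                     src[, 2] / voxel[2] + 0.5, src[, 3] / voxel[3] + 0.5)
  }
  vol3 <- function(i) array(vol$data[, , , i], d[1:3])
  pars <- matrix(0, d[4], 6)
  for (pass in seq_len(passes)) {
    ref <- if (pass == 1) array(apply(vol$data, 1:3, mean), d[1:3])
           else {
             acc <- array(0, d[1:3])
             for (i in seq_len(d[4]))
               acc <- acc + apply_rigid3d(vol3(i), -pars[i, ], voxel)
             acc / d[4]
           }
    refv <- ref[lin]
    for (i in seq_len(d[4])) {
      v3 <- vol3(i)
      fit <- stats::optim(pars[i, ],
                          function(p) sum((resample_inv(v3, p) - refv)^2),
                          method = "Nelder-Mead",
                          control = list(reltol = 1e-10, maxit = 500,
                                         parscale = rep(0.2, 6)))
      pars[i, ] <- fit$par
    }
  }
  out <- vol
  for (i in seq_len(d[4]))
    if (any(pars[i, ] != 0))
      out$data[, , , i] <- apply_rigid3d(vol3(i), -pars[i, ], voxel)
  motion <- sweep(pars, 2, pars[1, ])
  list(volumes = out, motion = motion)
}

#' Reslice a volume onto a new voxel grid
#'
#' Trilinear interpolation onto a lattice with the requested voxel sizes;
#' the world extent is preserved to within one target voxel (new dimensions
#' are `round(extent / target_voxel)`).
#'
#' @param vol A [volume4d()].
#' @param target_voxel Numeric triple, mm.
#' @return Resliced [volume4d()].
#' @export
reslice <- function(vol, target_voxel) {
  stopifnot(inherits(vol, "volume4d"))
  stop_if(length(target_voxel) != 3 || any(target_voxel <= 0),
          "`target_voxel` must be 3 positive sizes")
  d <- dim(vol$data)
  ext <- volume_extent(vol)
  nd <- pmax(1L, round(ext / target_voxel))
  ci <- lapply(1:3, function(k)
    ((seq_len(nd[k]) - 0.5) * target_voxel[k]) / vol$voxel[k] + 0.5)
  g <- expand.grid(x = ci[[1]], y = ci[[2]], z = ci[[3]])
  out <- array(0, c(nd, d[4]))
  for (i in seq_len(d[4]))
    out[, , , i] <- array(sample_trilinear(array(vol$data[, , , i], d[1:3]),
                                           g$x, g$y, g$z), nd)
  volume4d(out, target_voxel, vol$tr)
}

## 1-D Gaussian convolution along one axis of a 3-D array, replicate padding
conv_axis <- function(arr, sigma_vox, axis) {
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- dnorm(seq(-r, r), sd = sigma_vox); k <- k / sum(k)
  d <- dim(arr)
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  n <- da[1]
  mp <- rbind(m[rep(1, r), , drop = FALSE], m,
              m[rep(n, r), , drop = FALSE])
  sm <- apply(mp, 2, function(col)
    as.numeric(stats::filter(col, k, sides = 2))[(r + 1):(r + n)])
  aperm(array(sm, da), order(perm))
}

#' Spatial Gaussian smoothing
#'
#' Separable Gaussian smoothing with the kernel width given as full width
#' at half maximum in mm (`sigma = fwhm / 2.3548` per axis, converted to
#' voxels). Replicate-padding at the boundaries preserves the mean of
#' smooth images; `fwhm = 0` is the identity.
#'
#' @param vol A [volume4d()].
#' @param fwhm_mm Kernel FWHM in mm (scalar, applied to every axis).
#' @return Smoothed [volume4d()].
#' @export
smooth_volume <- function(vol, fwhm_mm = 0.6) {
  stopifnot(inherits(vol, "volume4d"))
  stop_if(!is_number(fwhm_mm) || fwhm_mm < 0, "`fwhm_mm` must be >= 0")
  if (fwhm_mm == 0) return(vol)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / vol$voxel
  out <- vol
  d3 <- dim(vol$data)[1:3]
  for (i in seq_len(dim(vol$data)[4])) {
    v <- array(vol$data[, , , i], d3)
    for (ax in 1:3) v <- conv_axis(v, sig[ax], ax)
    out$data[, , , i] <- v
  }
  out
}

#' Discrete-cosine high-pass basis
#'
#' Orthonormal DCT regressors spanning fluctuations slower than the cut-off
#' period; the order is `floor(2 * n_scans * tr / cutoff_period + 1)` (the
#' SPM convention). The constant term is not included (the design carries
#' an explicit constant). Including these columns in the design removes
#' slow drifts by residualization, equivalent to pre-filtering.
#'
#' @param n_scans Number of scans (>= 2).
#' @param tr Repetition time, seconds.
#' @param cutoff_period Cut-off period, seconds (default 200, i.e. a
#'   1/200 Hz cut-on frequency).
#' @return Matrix `n_scans x k` with orthonormal columns (`k` may be 0).
#' @export
dct_highpass_basis <- function(n_scans, tr, cutoff_period = 200) {
  stop_if(!is_number(n_scans) || n_scans < 2, "`n_scans` must be >= 2")
  stop_if(!is_number(cutoff_period) || cutoff_period <= 0,
          "`cutoff_period` must be > 0")
  k <- floor(2 * n_scans * tr / cutoff_period + 1)
  t <- seq_len(n_scans) - 1L
  B <- vapply(seq_len(k), function(r)
    sqrt(2 / n_scans) * cos(pi * (2 * t + 1) * r / (2 * n_scans)),
    numeric(n_scans))
  colnames(B) <- paste0("dct", seq_len(k))
  B
}

#' Assemble a first-level design matrix
#'
#' Column order: task regressor, constant, six motion parameters (optional)
#' and the DCT high-pass basis (optional). Errors on rank deficiency,
#' naming the offending columns.
#'
#' @param task Numeric task regressor (length `n_scans`).
#' @param motion Optional `n_scans x 6` motion-parameter matrix.
#' @param highpass Optional DCT basis from [dct_highpass_basis()].
#' @return Object of class `design_matrix`: the numeric matrix with named
#'   columns.
#' @export
build_design <- function(task, motion = NULL, highpass = NULL) {
  n <- length(task)
  X <- cbind(task = task, constant = rep(1, n))
  if (!is.null(motion)) {
    stop_if(nrow(motion) != n, "motion parameter length mismatch")
    stop_if(ncol(motion) != 6, "expected 6 motion parameters")
    colnames(motion) <- paste0("motion", 1:6)
    X <- cbind(X, motion)
  }
  if (!is.null(highpass) && ncol(highpass) > 0) {
    stop_if(nrow(highpass) != n, "high-pass basis length mismatch")
    X <- cbind(X, highpass)
  }
  stop_if(any(apply(X, 2, function(c) all(c == 0))),
          "all-zero design column")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(X, class = c("design_matrix", "matrix"))
}

#' Fit a voxel-wise general linear model
#'
#' Ordinary least squares per voxel, `beta = (X'X)^{-1} X'y`, with the
#' t statistic of a contrast `c`:
#' `t = c'beta / sqrt(sigma2 * c'(X'X)^{-1}c)` and one-sided (activation)
#' p-values from the Student-t distribution on `n - rank(X)` degrees of
#' freedom.
#'
#' @param data A [volume4d()], [trace_set()] or numeric matrix
#'   (`n_scans x voxels`).
#' @param design A [build_design()] matrix.
#' @param contrast Contrast weights; shorter vectors are zero-padded to the
#'   full design width (default `c(1, 0)`: the task effect).
#' @return Object of class `glm_result`: `beta`, `tmap`, `pmap` (arrays
#'   shaped like the input space), `dof`, `contrast`, `design`,
#'   `space_dim`.
#' @export
fit_glm <- function(data, design, contrast = c(1, 0)) {
  X <- unclass(design)
  if (inherits(data, "volume4d")) {
    d <- dim(data$data)
    space <- d[1:3]
    Y <- t(matrix(data$data, nrow = prod(space)))
  } else if (inherits(data, "trace_set")) {
    space <- 1L
    Y <- matrix(data$values, ncol = 1)
  } else {
    Y <- as.matrix(data)
    space <- ncol(Y)
  }
  stop_if(nrow(Y) != nrow(X), "data length != design rows")
  stop_if(qr(X)$rank < ncol(X), "singular design matrix")
  cvec <- numeric(ncol(X))
  cvec[seq_along(contrast)] <- contrast
  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% beta
  dof <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / dof
  cXXc <- drop(t(cvec) %*% XtXi %*% cvec)
  se <- sqrt(sigma2 * cXXc)
  tval <- drop(crossprod(cvec, beta)) / se
  tval[se == 0] <- 0
  p <- stats::pt(tval, df = dof, lower.tail = FALSE)
  shape <- function(v) if (length(space) == 3) array(v, space) else v
  structure(list(beta = beta, tmap = shape(tval), pmap = shape(p),
                 dof = dof, contrast = cvec, design = X,
                 space_dim = space), class = "glm_result")
}

#' Family-wise-error-corrected activation mask
#'
#' Bonferroni control of the family-wise error rate across the in-mask
#' voxels: a voxel survives iff `p < alpha / m` where `m` is the number of
#' voxels tested.
#'
#' @param result A [fit_glm()] result.
#' @param alpha Family-wise error level (default 0.05).
#' @param mask Optional logical array restricting the tested voxels.
#' @return Logical array of surviving voxels, attribute `threshold`.
#' @export
fwe_mask <- function(result, alpha = 0.05, mask = NULL) {
  stopifnot(inherits(result, "glm_result"))
  p <- result$pmap
  if (is.null(mask)) mask <- !is.na(p) & is.finite(p)
  m <- sum(mask)
  stop_if(m == 0, "empty voxel mask")
  thr <- alpha / m
  out <- (p < thr) & mask
  attr(out, "threshold") <- thr
  out
}

#' Task beta map
#'
#' The parametric (beta) map of the task regressor, used directly to infer
#' activation for fluorescence recordings.
#'
#' @param result A [fit_glm()] result.
#' @param positive_only Zero out negative effects.
#' @return Array (or vector) of task-effect estimates in the input units.
#' @export
beta_activation_map <- function(result, positive_only = FALSE) {
  stopifnot(inherits(result, "glm_result"))
  b <- result$beta[1, ]
  if (positive_only) b <- pmax(b, 0)
  if (length(result$space_dim) == 3) array(b, result$space_dim) else b
}
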