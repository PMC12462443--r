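#' 4-D volume container
#'
#' Scalar lattice over space and time with isotropic-in-plane voxel sizes
#' in mm and a repetition time in seconds. Voxel centers sit at world
#' coordinates `(i - 0.5) * voxel` along each axis (cell-centred, 0-based
#' world origin at the corner of the field of view), so the world extent is
#' exactly `dim * voxel`.
#'
#' @param data 4-D numeric array (x, y, z, t); a 3-D array is promoted to a
#'   single time point.
#' @param voxel Numeric triple of voxel sizes, mm.
#' @param tr Repetition time, seconds.
#' @param t0 Acquisition time of the first volume, seconds (nonzero after
#'   dropping initial scans).
#' @return An object of class `volume4d` with an `affine` (RAS, mm) matrix.
#' @export
volume4d <- function(data, voxel, tr = 1, t0 = 0) {
  if (length(dim(data)) == 3) dim(data) <- c(dim(data), 1L)
  stop_if(length(dim(data)) != 4, "`data` must be a 3-D or 4-D array")
  stop_if(length(voxel) != 3 || any(voxel <= 0), "`voxel` must be 3 positive sizes")
  stop_if(!is_number(tr) || tr <= 0, "`tr` must be > 0")
  affine <- diag(c(voxel, 1))
  affine[1:3, 4] <- -voxel / 2   # voxel (1,1,1) centre at voxel/2
  structure(list(data = data, voxel = as.numeric(voxel), tr = tr,
                 t0 = t0, affine = affine), class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume4d> %dx%dx%d voxels x %d volumes, voxel %gx%gx%g mm, TR %g s\n",
    d[1], d[2], d[3], d[4], x$voxel[1], x$voxel[2], x$voxel[3], x$tr))
  invisible(x)
}

#' World extent of a volume
#' @param vol A [volume4d()].
#' @return Numeric triple, mm.
#' @export
volume_extent <- function(vol) dim(vol$data)[1:3] * vol$voxel

## Trilinear sampling of a 3-D array at continuous (1-based) voxel indices.
## Coordinates outside the lattice are clamped to the edge.
sample_trilinear <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  xi <- pmin(pmax(xi, 1), d[1]); yi <- pmin(pmax(yi, 1), d[2])
  zi <- pmin(pmax(zi, 1), d[3])
  x0 <- pmin(floor(xi), d[1] - 1L); y0 <- pmin(floor(yi), d[2] - 1L)
  z0 <- pmin(floor(zi), d[3] - 1L)
  if (d[1] == 1L) x0 <- rep(1, length(xi))
  if (d[2] == 1L) y0 <- rep(1, length(yi))
  if (d[3] == 1L) z0 <- rep(1, length(zi))
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  at <- function(i, j, k) arr[cbind(i, j, k)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(x0, y0, z0) + fx * at(x1, y0, z0)) +
              fy * ((1 - fx) * at(x0, y1, z0) + fx * at(x1, y1, z0))) +
    fz * ((1 - fy) * ((1 - fx) * at(x0, y0, z1) + fx * at(x1, y0, z1)) +
          fy * ((1 - fx) * at(x0, y1, z1) + fx * at(x1, y1, z1)))
}

## 3-D rotation matrix from rotations (deg) about x, y, z axes (applied in
## that order: R = Rz %*% Ry %*% Rx)
rotation3d <- function(rx, ry, rz) {
  a <- rx * pi / 180; b <- ry * pi / 180; c <- rz * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Apply a rigid-body transform to a 3-D volume
#'
#' Moves the image content by the 6-parameter rigid transform
#' (translations in mm, rotations in degrees about the volume centre):
#' `out(x) = in(R^{-1} (x - c - t) + c)` with trilinear resampling and
#' edge-clamped boundaries.
#'
#' @param arr 3-D array.
#' @param params Numeric 6-vector `(tx, ty, tz, rx, ry, rz)` (mm, deg).
#' @param voxel Voxel sizes, mm.
#' @return Transformed 3-D array.
#' @export
apply_rigid3d <- function(arr, params, voxel) {
  d <- dim(arr)
  ctr <- d * voxel / 2
  R <- rotation3d(params[4], params[5], params[6])
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  w <- cbind((g$x - 0.5) * voxel[1], (g$y - 0.5) * voxel[2],
             (g$z - 0.5) * voxel[3])
  w <- sweep(w, 2, ctr + params[1:3])
  src <- t(t(R) %*% t(w)) + rep(ctr, each = nrow(w))
  v <- sample_trilinear(arr, src[, 1] / voxel[1] + 0.5,
                        src[, 2] / voxel[2] + 0.5,
                        src[, 3] / voxel[3] + 0.5)
  array(v, d)
}

#' Simulate a 4-D BOLD acquisition with a focal activation
#'
#' Gradient-echo EPI-like series on the default geometry of 80 x 40
#' in-plane voxels (250 x 250 um over a 20 x 10 mm field of view) x 11
#' slices of 0.7 mm at a 1 s repetition time. Voxels inside a cubic block
#' (default 0.6 mm side) around `activation_center` carry the
#' stimulus-locked fractional response of `activation_profile`; all voxels
#' carry baseline 100, optional linear drift, i.i.d. Gaussian noise and
#' optional per-volume rigid motion whose true parameters are recorded as
#' ground truth.
#'
#' @param paradigm A [make_paradigm()] object.
#' @param activation_center World coordinates (mm), inside the lattice.
#' @param activation_profile A [kinetic_profile()].
#' @param dim Lattice dimensions (x, y, z).
#' @param voxel Voxel sizes, mm.
#' @param tr Repetition time, seconds.
#' @param block_mm Side of the activated cube, mm.
#' @param noise_sd Noise SD in percent of baseline.
#' @param drift Linear drift, fraction of baseline per second.
#' @param motion_amplitude Max |translation| (mm) and |rotation| (deg) of
#'   the per-volume motion (0 = still).
#' @param seed Integer seed.
#' @return A [volume4d()] with attributes `motion_true` (n_volumes x 6),
#'   `activation_mask` (logical 3-D array) and `response` (percent time
#'   course).
#' @export
synth_bold_volume <- function(paradigm, activation_center = c(5, 2.5, 1.05),
                              activation_profile = group_profiles()$BOLD,
                              dim = c(80, 40, 11),
                              voxel = c(0.25, 0.25, 0.7), tr = 1,
                              block_mm = 0.6, noise_sd = 0.5, drift = 0,
                              motion_amplitude = 0, seed = NULL) {
  stopifnot(inherits(paradigm, "stim_paradigm"))
  ext <- dim * voxel
  stop_if(any(activation_center < 0) || any(activation_center > ext),
          "activation centre outside the lattice")
  n_t <- round(paradigm$total_duration / tr)
  t <- (seq_len(n_t) - 1L) * tr
  resp <- numeric(n_t)
  if (activation_profile$amplitude > 0) {
    f <- waveform_fun(activation_profile)
    for (o in paradigm$onsets) resp <- resp + f(t - o - activation_profile$lag)
  }
  cx <- lapply(1:3, function(k) (seq_len(dim[k]) - 0.5) * voxel[k])
  inb <- function(k) cx[[k]] >= activation_center[k] - block_mm / 2 &
    cx[[k]] < activation_center[k] + block_mm / 2
  mask <- array(outer(outer(inb(1), inb(2), "&"), inb(3), "&"), dim)
  with_seed(seed, {
    motion <- matrix(0, n_t, 6)
    if (motion_amplitude > 0 && n_t > 1)
      motion[-1, ] <- stats::runif(6 * (n_t - 1), -motion_amplitude,
                                   motion_amplitude)
    vols <- array(0, c(dim, n_t))
    ## structured baseline: brain-like ellipsoidal profile plus a smooth
    ## random texture, so that realignment has intensity features to lock on
    nrmc <- lapply(1:3, function(k) (cx[[k]] - ext[k] / 2) / (0.45 * ext[k]))
    el <- outer(outer(nrmc[[1]]^2, nrmc[[2]]^2, "+"), nrmc[[3]]^2, "+")
    tex <- array(stats::rnorm(prod(dim)), dim)
    for (ax in 1:3) tex <- conv_axis(tex, 1.2, ax)
    tex <- tex / max(abs(tex))
    base <- 100 * (0.55 + 0.45 * exp(-el)) + 15 * tex
    for (i in seq_len(n_t)) {
      v3 <- base * (1 + mask * resp[i] / 100 + drift * t[i])
      if (any(motion[i, ] != 0)) v3 <- apply_rigid3d(v3, motion[i, ], voxel)
      vols[, , , i] <- v3 + stats::rnorm(prod(dim), 0, noise_sd)
    }
    out <- volume4d(vols, voxel, tr)
    attr(out, "motion_true") <- motion
    attr(out, "activation_mask") <- mask
    attr(out, "response") <- resp
    out
  })
}
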