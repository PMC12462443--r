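#' 2-D image stack container
#'
#' Frame stack from a widefield fluorescence camera: `frames` is a 3-D
#' array (y, x, t), `pixel_pitch` the pixel size in micrometres and
#' `frame_rate` the acquisition rate in Hz.
#'
#' @param frames 3-D numeric array (y, x, t); a matrix is promoted to one
#'   frame.
#' @param pixel_pitch Pixel size, um.
#' @param frame_rate Frame rate, Hz (default 40).
#' @param channel Channel label.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_pitch, frame_rate = 40,
                        channel = "FL") {
  if (length(dim(frames)) == 2) dim(frames) <- c(dim(frames), 1L)
  stop_if(length(dim(frames)) != 3, "`frames` must be a 2-D or 3-D array")
  stop_if(!is_number(pixel_pitch) || pixel_pitch <= 0,
          "`pixel_pitch` must be > 0")
  stop_if(!is_number(frame_rate) || frame_rate <= 0,
          "`frame_rate` must be > 0")
  structure(list(frames = frames, pixel_pitch = pixel_pitch,
                 frame_rate = frame_rate, channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %s: %dx%d px (%g um) x %d frames at %g Hz\n",
              x$channel, d[1], d[2], x$pixel_pitch, d[3], x$frame_rate))
  invisible(x)
}

## separable 2-D Gaussian blur of a matrix, sigma in pixels, replicate edges
blur2d <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- dnorm(seq(-r, r), sd = sigma_px); k <- k / sum(k)
  pad_filter <- function(m) {
    n <- nrow(m)
    mp <- rbind(m[rep(1, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
    out <- apply(mp, 2, function(col)
      as.numeric(stats::filter(col, k, sides = 2))[(r + 1):(r + n)])
    matrix(out, nrow = n)
  }
  t(pad_filter(t(pad_filter(img))))
}

#' Simulate a widefield fluorescence frame stack
#'
#' Frames are the static phantom modulated by the stimulus-locked response,
#' `phantom * (1 + response(t) * response_map)`, blurred by the optical
#' point-spread function (Gaussian, `psf_fwhm` um) with additive Gaussian
#' noise. `response(t)` is the fractional single-cycle waveform train of
#' the profile, so a pixel with `response_map = 1` follows the calibrated
#' waveform exactly.
#'
#' @param paradigm A [make_paradigm()] object.
#' @param phantom 2-D matrix of baseline fluorescence.
#' @param response_map 2-D matrix (same size) scaling the local response
#'   amplitude (0 = no response, 1 = full profile amplitude).
#' @param profile A [kinetic_profile()] driving the response.
#' @param psf_fwhm Optical PSF full width at half maximum, um (>= 0).
#' @param pixel_pitch Pixel size, um.
#' @param frame_rate Frame rate, Hz.
#' @param noise_sd Additive noise SD in units of the phantom intensity.
#' @param channel Channel label.
#' @param seed Integer seed.
#' @return An [image_stack()]; attribute `response` holds the fractional
#'   response time course.
#' @export
synth_fl_frames <- function(paradigm, phantom, response_map,
                            profile = group_profiles()$RCaMP,
                            psf_fwhm = 70, pixel_pitch = 50,
                            frame_rate = 40, noise_sd = 0,
                            channel = "RCaMP", seed = NULL) {
  stopifnot(inherits(paradigm, "stim_paradigm"))
  stop_if(!is_number(psf_fwhm) || psf_fwhm < 0, "`psf_fwhm` must be >= 0")
  stop_if(!all(dim(phantom) == dim(response_map)),
          "`phantom` and `response_map` sizes differ")
  n_t <- round(paradigm$total_duration * frame_rate)
  t <- (seq_len(n_t) - 1L) / frame_rate
  resp <- numeric(n_t)
  if (profile$amplitude > 0) {
    f <- waveform_fun(profile)
    for (o in paradigm$onsets) resp <- resp + f(t - o - profile$lag)
  }
  resp <- resp / 100
  sig <- psf_fwhm / (2 * sqrt(2 * log(2))) / pixel_pitch
  base <- blur2d(phantom, sig)
  mod <- blur2d(phantom * response_map, sig)
  with_seed(seed, {
    frames <- array(0, c(dim(phantom), n_t))
    for (i in seq_len(n_t))
      frames[, , i] <- base + resp[i] * mod +
        if (noise_sd > 0) stats::rnorm(length(base), 0, noise_sd) else 0
    out <- image_stack(frames, pixel_pitch, frame_rate, channel)
    attr(out, "response") <- resp
    out
  })
}

#' Miniature layered cortical atlas
#'
#' Synthetic stand-in for a 3-D labelled mouse brain atlas: a cortical slab
#' occupying the upper part of the lattice, divided along x into
#' `n_regions` contiguous labelled regions (region 1 is always `S1FL`, the
#' primary somatosensory forelimb area), with cortical layer indices 1-6
#' assigned by depth. Voxels below the cortex carry layer 0 and label 0.
#'
#' @param n_regions Number of cortical regions (>= 1).
#' @param shape Lattice dimensions (x, y, z); z is depth from the surface.
#' @param cortex_depth Number of z-slices forming the cortex.
#' @return Object of class `atlas_volume`: `labels`, `layer` (3-D integer
#'   arrays) and `region_names` (id -> name).
#' @export
make_mini_atlas <- function(n_regions = 4, shape = c(48, 32, 12),
                            cortex_depth = 6) {
  stop_if(!is_number(n_regions) || n_regions < 1, "`n_regions` must be >= 1")
  stop_if(length(shape) != 3 || any(shape < 1), "invalid `shape`")
  stop_if(shape[1] < n_regions,
          "shape too small to host the requested regions")
  stop_if(cortex_depth > shape[3], "cortex deeper than the lattice")
  labels <- array(0L, shape)
  layer <- array(0L, shape)
  bounds <- round(seq(0, shape[1], length.out = n_regions + 1))
  for (r in seq_len(n_regions)) {
    xs <- (bounds[r] + 1):bounds[r + 1]
    labels[xs, , seq_len(cortex_depth)] <- r
  }
  for (z in seq_len(cortex_depth))
    layer[, , z] <- as.integer(ceiling(z * 6 / cortex_depth))
  pool <- c("S1FL", "S1HL", "S1BF", "M1", "M2", "V1", "A1", "RSP")
  nm <- if (n_regions <= length(pool)) pool[seq_len(n_regions)]
        else c(pool, paste0("CTX", seq_len(n_regions - length(pool))))
  structure(list(labels = labels, layer = layer,
                 region_names = stats::setNames(nm, seq_len(n_regions))),
            class = "atlas_volume")
}
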