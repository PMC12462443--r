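#' Read and write 4-D volumes as NIfTI-1
#'
#' Round-trips the lattice, voxel sizes (mm) and repetition time (s)
#' through NIfTI-1 files.
#'
#' @param vol A [volume4d()].
#' @param path Output file (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns
#'   a [volume4d()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume4d"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- c(vol$voxel, vol$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  stop_if(!file.exists(path), paste0("no such file: ", path))
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  volume4d(arr, voxel = pd[1:3], tr = if (length(pd) >= 4) pd[4] else 1)
}

#' Read and write fluorescence stacks as multi-page TIFF
#'
#' Frames are stored as 32-bit float TIFF pages scaled to `[0, 1]`; the
#' scaling and acquisition metadata (frame rate, pixel pitch, channel) go
#' to a JSON sidecar `<path>.json`, and the round trip restores the
#' original values.
#'
#' @param stack An [image_stack()].
#' @param path Output `.tif` file.
#' @return `write_stack` returns `path` invisibly; `read_stack` an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  vmin <- min(stack$frames); vmax <- max(stack$frames)
  scale <- if (vmax > vmin) vmax - vmin else 1
  pages <- lapply(seq_len(dim(stack$frames)[3]), function(i)
    (stack$frames[, , i] - vmin) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  sidecar <- list(frame_rate = stack$frame_rate,
                  pixel_pitch_um = stack$pixel_pitch,
                  channel = stack$channel, vmin = vmin, vmax = vmax)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  stop_if(!file.exists(path), paste0("no such file: ", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  side_path <- paste0(path, ".json")
  stop_if(!file.exists(side_path),
          paste0("missing metadata sidecar: ", side_path))
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  scale <- if (side$vmax > side$vmin) side$vmax - side$vmin else 1
  frames <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages))
    frames[, , i] <- pages[[i]] * scale + side$vmin
  image_stack(frames, pixel_pitch = side$pixel_pitch_um,
              frame_rate = side$frame_rate, channel = side$channel)
}

#' Serialize a rigid 2-D transform to JSON
#' @param tf A [rigid2d()].
#' @param path Output `.json` file.
#' @return `write_transform` returns `path` invisibly; `read_transform` a
#'   [rigid2d()].
#' @export
write_transform <- function(tf, path) {
  stopifnot(inherits(tf, "rigid2d"))
  jsonlite::write_json(unclass(tf), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid2d(x$rotation, x$translation, x$center)
}

#' Default pipeline configuration
#'
#' Nested list describing one end-to-end run: stimulation paradigm,
#' per-channel kinetic profiles, HRF parameters, GLM settings (FWE alpha,
#' high-pass cut-off, smoothing FWHM, initial scans dropped), ROI size,
#' analysis settings and the seed. The default configuration reproduces
#' the packaged group-level simulation at a reduced spatial size.
#'
#' @param seed Integer seed recorded in the config.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    paradigm = list(pulse_width = 5e-4, pulse_amplitude = 0.5,
                    pulse_rate = 4, onset_duration = 8, cycle_period = 90,
                    n_cycles = 9, baseline_lead = 82),
    profiles = lapply(group_profiles(), unclass),
    hrf = unclass(hrf_params()),
    glm = list(alpha = 0.05, cutoff_period = 200, smooth_fwhm_mm = 0.6,
               drop_seconds = 5, run_volume_glm = TRUE,
               volume_dim = c(24, 16, 4), voxel_mm = c(0.25, 0.25, 0.7),
               volume_noise_sd = 0.5),
    roi = list(size_mm = 0.6),
    kinetics = list(smooth_sigma = 0.25),
    latency = list(max_lag = 5, smooth_sigma = 0.5, window = c(2, 20))
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and fills unspecified fields from [default_config()].
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  stop_if(!file.exists(path), paste0("no such file: ", path))
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

#' Stable hash of a configuration
#'
#' MD5 digest of the canonical JSON serialization, recorded in every
#' pipeline output for provenance.
#'
#' @param config Configuration list.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = 12,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
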