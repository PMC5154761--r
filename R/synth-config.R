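#' Configuration for the synthetic two-channel movie generator
#'
#' Builds and validates the parameter set describing the simulated imaging
#' regime: a single motile cell whose membrane carries intense reporter
#' patches (patch channel, e.g. a PIP3 or active-Ras probe) and narrow
#' high-intensity segments flanking each patch boundary (ring channel, e.g. a
#' SCAR/WAVE reporter), over a cytosolic pool, with shot and read noise.
#'
#' Geometry is star-convex: the cell is described by a radius function
#' r(theta) around a drifting centroid, with angles measured
#' counter-clockwise from the +x axis. Patches are angular intervals of the
#' membrane band; they are born (de novo, or by splitting off a live parent),
#' grow from sub-resolution width to a sampled target width, and close after
#' a geometrically distributed lifetime.
#'
#' @param image_size_px integer length-2, image size in pixels (rows, cols).
#' @param pixel_size_um pixel size in micrometres.
#' @param n_frames number of frames.
#' @param frame_interval_s frame interval in seconds.
#' @param cell_radius_um base cell radius.
#' @param membrane_band_um thickness of the bright membrane rim (rendered
#'   just inside the cell radius). Must be at least two pixels.
#' @param cyto_mean cytosolic mean intensity, one value per channel or a
#'   scalar shared by all channels.
#' @param patch_fold patch-channel membrane intensity inside patches, as a
#'   multiple of the baseline membrane intensity. Must exceed 1.
#' @param ring_fold ring-channel membrane intensity inside ring segments,
#'   as a multiple of baseline. Must exceed 1.
#' @param ring_width_um angular extent of each ring segment, expressed as an
#'   arc length at the local cell radius.
#' @param ring_placement `"exterior"` places ring segments just outside each
#'   patch boundary (the biological arrangement); `"interior"` places them
#'   just inside (a control that flips the patch/ring anti-correlation).
#' @param baseline_membrane_fold membrane intensity outside patches, both
#'   channels, as a multiple of `cyto_mean`. The default (2.82) is calibrated
#'   so that the membrane band-mean read by [sample_membrane()] with default
#'   settings equals the cytosol mean for a non-recruited reporter, matching
#'   the appearance of real uniformly distributed membrane probes.
#' @param patch_birth_rate expected patch births per frame (Poisson).
#' @param patch_width_deg_mean,patch_width_deg_sd target patch angular width
#'   distribution (degrees, normal, truncated at 10 degrees).
#' @param patch_lifetime_frames_mean mean patch lifetime in frames
#'   (geometric).
#' @param split_probability probability that a birth splits off a live
#'   parent patch rather than appearing de novo (given a parent exists).
#' @param drift_speed_um_s cell centroid drift speed.
#' @param drift_direction_rad drift direction.
#' @param protrusion_amp_um amplitude of radial protrusions.
#' @param protrusion_freq angular frequency of protrusions (lobes per turn)
#'   when `protrusion_mode = "independent"`.
#' @param protrusion_mode `"independent"` superimposes a rotating cosine
#'   deformation; `"at_patches"` raises smooth radial bumps under each
#'   patch (so membrane expansion co-localises with patches/rings).
#' @param radius_growth_um_s uniform radial expansion speed (for speed
#'   oracle movies).
#' @param psf_sigma_um Gaussian point-spread blur applied to the noise-free
#'   image before noise; 0 (default) keeps edges pixel-sharp so the
#'   noise-free render is an exact piecewise-constant function of the truth
#'   geometry. Use a positive value (e.g. 0.25, a realistic confocal PSF)
#'   when measured edge widths should reflect optical blur rather than
#'   sampling resolution.
#' @param noise_poisson_scale photons per intensity unit for shot noise;
#'   0 disables Poisson noise.
#' @param noise_gauss_sd additive Gaussian read-noise SD; 0 disables.
#' @param channels character vector of channel types to render, from
#'   `"patch"`, `"ring"`, `"copatch"` (a second independent render of the
#'   patch geometry, for coincidence controls).
#' @param seed integer master seed; all generator randomness derives from it.
#'
#' @return An object of class `synth_config` (a validated list).
#' @examples
#' cfg <- synth_config(n_frames = 5, image_size_px = c(128, 128))
#' cfg$patch_fold
#' @export
synth_config <- function(image_size_px = c(256L, 256L),
                         pixel_size_um = 0.1,
                         n_frames = 50L,
                         frame_interval_s = 2,
                         cell_radius_um = 5,
                         membrane_band_um = 0.5,
                         cyto_mean = 100,
                         patch_fold = 3,
                         ring_fold = 4,
                         ring_width_um = 1.4,
                         ring_placement = c("exterior", "interior"),
                         baseline_membrane_fold = 2.82,
                         patch_birth_rate = 0.25,
                         patch_width_deg_mean = 80,
                         patch_width_deg_sd = 15,
                         patch_lifetime_frames_mean = 30,
                         split_probability = 0.62,
                         drift_speed_um_s = 0.02,
                         drift_direction_rad = pi / 4,
                         protrusion_amp_um = 0.3,
                         protrusion_freq = 2,
                         protrusion_mode = c("independent", "at_patches"),
                         radius_growth_um_s = 0,
                         psf_sigma_um = 0,
                         noise_poisson_scale = 1,
                         noise_gauss_sd = 2,
                         channels = c("patch", "ring"),
                         seed = 1L) {
  cfg <- list(
    image_size_px = as.integer(image_size_px),
    pixel_size_um = pixel_size_um,
    n_frames = as.integer(n_frames),
    frame_interval_s = frame_interval_s,
    cell_radius_um = cell_radius_um,
    membrane_band_um = membrane_band_um,
    cyto_mean = cyto_mean,
    patch_fold = patch_fold,
    ring_fold = ring_fold,
    ring_width_um = ring_width_um,
    ring_placement = match.arg(ring_placement),
    baseline_membrane_fold = baseline_membrane_fold,
    patch_birth_rate = patch_birth_rate,
    patch_width_deg_mean = patch_width_deg_mean,
    patch_width_deg_sd = patch_width_deg_sd,
    patch_lifetime_frames_mean = patch_lifetime_frames_mean,
    split_probability = split_probability,
    drift_speed_um_s = drift_speed_um_s,
    drift_direction_rad = drift_direction_rad,
    protrusion_amp_um = protrusion_amp_um,
    protrusion_freq = protrusion_freq,
    protrusion_mode = match.arg(protrusion_mode),
    radius_growth_um_s = radius_growth_um_s,
    psf_sigma_um = psf_sigma_um,
    noise_poisson_scale = noise_poisson_scale,
    noise_gauss_sd = noise_gauss_sd,
    channels = channels,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

#' @rdname synth_config
#' @param cfg a `synth_config` candidate to validate.
#' @export
validate_synth_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) mp_stop(msg, "invalid_config")
  chk(length(cfg$image_size_px) == 2 && all(cfg$image_size_px >= 32),
      "image_size_px must be two integers >= 32")
  chk(cfg$pixel_size_um > 0, "pixel_size_um must be > 0")
  chk(cfg$n_frames >= 1, "n_frames must be >= 1")
  chk(cfg$frame_interval_s > 0, "frame_interval_s must be > 0")
  chk(cfg$cell_radius_um > 0, "cell_radius_um must be > 0")
  chk(cfg$membrane_band_um >= 2 * cfg$pixel_size_um,
      "membrane_band_um must be at least two pixels")
  chk(all(cfg$cyto_mean > 0), "cyto_mean must be > 0")
  chk(cfg$patch_fold > 1, "patch_fold must exceed 1")
  chk(cfg$ring_fold > 1, "ring_fold must exceed 1")
  chk(cfg$ring_width_um > 0, "ring_width_um must be > 0")
  chk(cfg$baseline_membrane_fold > 0, "baseline_membrane_fold must be > 0")
  chk(cfg$patch_birth_rate >= 0, "patch_birth_rate must be >= 0")
  chk(cfg$patch_width_deg_mean > 0 && cfg$patch_width_deg_sd >= 0,
      "patch width distribution must be positive")
  chk(cfg$patch_lifetime_frames_mean >= 1,
      "patch_lifetime_frames_mean must be >= 1")
  chk(cfg$split_probability >= 0 && cfg$split_probability <= 1,
      "split_probability must lie in [0, 1]")
  chk(cfg$drift_speed_um_s >= 0 && cfg$protrusion_amp_um >= 0,
      "motion parameters must be >= 0")
  chk(cfg$noise_poisson_scale >= 0 && cfg$noise_gauss_sd >= 0,
      "noise parameters must be >= 0")
  chk(is.null(cfg$psf_sigma_um) || cfg$psf_sigma_um >= 0,
      "psf_sigma_um must be >= 0")
  chk(length(cfg$channels) >= 1 &&
        all(cfg$channels %in% c("patch", "ring", "copatch")),
      "channels must be drawn from patch/ring/copatch")
  # per-channel cytosol means
  if (length(cfg$cyto_mean) == 1) {
    cfg$cyto_mean <- rep(cfg$cyto_mean, length(cfg$channels))
  }
  chk(length(cfg$cyto_mean) == length(cfg$channels),
      "cyto_mean must be scalar or one value per channel")
  names(cfg$cyto_mean) <- cfg$channels
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  %d frames of %dx%d px (%.3g um/px, %.3g s/frame)\n",
              x$n_frames, x$image_size_px[1], x$image_size_px[2],
              x$pixel_size_um, x$frame_interval_s))
  cat(sprintf("  cell r=%.3g um, membrane band %.3g um, channels: %s\n",
              x$cell_radius_um, x$membrane_band_um,
              paste(x$channels, collapse = ", ")))
  cat(sprintf("  patches: fold %.3g, birth rate %.3g/frame, width %.3g+-%.3g deg, split p=%.3g\n",
              x$patch_fold, x$patch_birth_rate, x$patch_width_deg_mean,
              x$patch_width_deg_sd, x$split_probability))
  invisible(x)
}

#' Read / write a generator configuration as YAML
#'
#' @param cfg a `synth_config`.
#' @param path file path.
#' @return `read_synth_config()` returns a validated `synth_config`;
#'   `write_synth_config()` returns `path` invisibly.
#' @export
write_synth_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "synth_config"))
  x <- unclass(cfg)
  x$cyto_mean <- unname(x$cyto_mean)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(synth_config, x)
}
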