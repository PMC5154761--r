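# Noise-free geometry rendering plus shot/read noise. One frame at a time.

#' Render one frame of a synthetic movie
#'
#' Produces the per-channel images for one frame of the ground truth:
#' cytosol filled at the cytosolic mean, a membrane band of thickness
#' `membrane_band_um` just inside the radius function at
#' `baseline_membrane_fold * cyto_mean`, multiplied by `patch_fold` inside
#' truth patch intervals (patch and copatch channels) or by `ring_fold`
#' inside the ring segments flanking each patch boundary (ring channel).
#' Pixels are classified by their centre; the noise-free image is an exact
#' piecewise-constant function of the truth geometry. Noise, when enabled,
#' is applied last: Poisson shot noise at `noise_poisson_scale` photons per
#' intensity unit, then additive Gaussian read noise, then clamping at zero.
#'
#' @param truth a [make_patch_schedule()] result.
#' @param frame_index frame to render (1-based).
#' @param cfg the generator configuration (defaults to `truth$config`).
#' @param noise apply the configured noise model (zero noise settings give
#'   a deterministic image). Noise draws come from the current RNG stream.
#' @return A named list of image matrices (`[row, col]`), one per channel.
#' @export
render_frame <- function(truth, frame_index, cfg = truth$config,
                         noise = TRUE) {
  if (frame_index < 1 || frame_index > length(truth$frames)) {
    mp_stop("frame_index out of range", "invalid_config")
  }
  fr <- truth$frames[[frame_index]]
  px <- cfg$pixel_size_um
  nr <- cfg$image_size_px[1]
  nc <- cfg$image_size_px[2]

  xs <- (seq_len(nc)) * px
  ys <- (seq_len(nr)) * px
  dx <- matrix(xs, nr, nc, byrow = TRUE) - fr$centroid_um[1]
  dy <- matrix(ys, nr, nc) - fr$centroid_um[2]
  rho <- sqrt(dx^2 + dy^2)
  theta <- wrap_angle(atan2(dy, dx))
  r_theta <- matrix(truth_radius(truth, frame_index, as.vector(theta)), nr, nc)

  r_max <- max(r_theta)
  if (fr$centroid_um[1] - r_max < px ||
      fr$centroid_um[1] + r_max > nc * px ||
      fr$centroid_um[2] - r_max < px ||
      fr$centroid_um[2] + r_max > nr * px) {
    mp_stop("cell (radius + protrusion + drift) exceeds image bounds",
            "geometry")
  }

  band <- rho <= r_theta & rho > (r_theta - cfg$membrane_band_um)
  inside <- rho <= (r_theta - cfg$membrane_band_um)
  pat <- fr$patches

  render_channel <- function(type, cmean) {
    img <- matrix(0, nr, nc)
    img[inside] <- cmean
    base <- cfg$baseline_membrane_fold * cmean
    img[band] <- base
    if (nrow(pat) > 0) {
      if (type %in% c("patch", "copatch")) {
        for (i in seq_len(nrow(pat))) {
          sel <- band & angle_in_arc(theta, pat$theta_start[i], pat$width[i])
          img[sel] <- base * cfg$patch_fold
        }
      } else if (type == "ring") {
        # ring accumulations live on free membrane flanking each patch;
        # they never trespass on a patch interior (own or a neighbour's)
        in_any_patch <- matrix(FALSE, nr, nc)
        for (i in seq_len(nrow(pat))) {
          in_any_patch <- in_any_patch |
            angle_in_arc(theta, pat$theta_start[i], pat$width[i])
        }
        for (i in seq_len(nrow(pat))) {
          r_b <- truth_radius(truth, frame_index,
                              c(pat$theta_start[i], pat$theta_end[i]))
          ring_ang <- cfg$ring_width_um / r_b
          if (cfg$ring_placement == "exterior") {
            zones <- rbind(
              c(wrap_angle(pat$theta_start[i] - ring_ang[1]), ring_ang[1]),
              c(pat$theta_end[i], ring_ang[2]))
          } else {
            zones <- rbind(
              c(pat$theta_start[i], min(ring_ang[1], pat$width[i] / 2)),
              c(wrap_angle(pat$theta_end[i] -
                             min(ring_ang[2], pat$width[i] / 2)),
                min(ring_ang[2], pat$width[i] / 2)))
          }
          for (z in seq_len(nrow(zones))) {
            sel <- band & angle_in_arc(theta, zones[z, 1], zones[z, 2])
            if (cfg$ring_placement == "exterior") sel <- sel & !in_any_patch
            img[sel] <- base * cfg$ring_fold
          }
        }
      }
    }
    if (!is.null(cfg$psf_sigma_um) && cfg$psf_sigma_um > 0) {
      img <- pmax(EBImage::gblur(img, sigma = cfg$psf_sigma_um / px), 0)
    }
    if (noise) {
      if (cfg$noise_poisson_scale > 0) {
        img <- matrix(stats::rpois(length(img),
                                   img * cfg$noise_poisson_scale) /
                        cfg$noise_poisson_scale, nr, nc)
      }
      if (cfg$noise_gauss_sd > 0) {
        img <- img + matrix(stats::rnorm(length(img), 0, cfg$noise_gauss_sd),
                            nr, nc)
      }
      img <- pmax(img, 0)
    }
    img
  }

  cmeans <- cfg$cyto_mean
  if (length(cmeans) == 1) cmeans <- rep(cmeans, length(cfg$channels))
  out <- lapply(seq_along(cfg$channels), function(k)
    render_channel(cfg$channels[k], cmeans[k]))
  names(out) <- cfg$channels
  out
}

#' Generate a complete synthetic movie with ground truth
#'
#' Composes the patch schedule, per-frame rendering and noise into a movie.
#' Identical configurations (including the seed) give bit-identical output.
#'
#' @param cfg a [synth_config()].
#' @return A list with elements `stack` (a `frame_stack`: numeric array
#'   `[row, col, channel, frame]` with calibration attributes) and `truth`
#'   (the [make_patch_schedule()] ground truth).
#' @examples
#' mv <- make_cell_movie(synth_config(n_frames = 3, image_size_px = c(128, 128)))
#' dim(mv$stack)
#' @export
make_cell_movie <- function(cfg) {
  truth <- make_patch_schedule(cfg)
  nr <- cfg$image_size_px[1]
  nc <- cfg$image_size_px[2]
  nch <- length(cfg$channels)
  arr <- array(0, dim = c(nr, nc, nch, cfg$n_frames))
  with_seed(mp_substream(cfg$seed, "render"), {
    for (f in seq_len(cfg$n_frames)) {
      imgs <- render_frame(truth, f, cfg, noise = TRUE)
      for (k in seq_len(nch)) arr[, , k, f] <- imgs[[k]]
    }
  })
  stack <- structure(arr,
                     class = c("frame_stack", "array"),
                     pixel_size_um = cfg$pixel_size_um,
                     frame_interval_s = cfg$frame_interval_s,
                     channel_names = cfg$channels)
  list(stack = stack, truth = truth)
}

#' Extract one channel image of one frame from a frame stack
#'
#' @param stack a `frame_stack`.
#' @param frame frame index.
#' @param channel channel name or index.
#' @return Image matrix `[row, col]`.
#' @export
stack_frame <- function(stack, frame, channel = 1) {
  if (is.character(channel)) {
    channel <- match(channel, attr(stack, "channel_names"))
    if (is.na(channel)) mp_stop("unknown channel name", "invalid_config")
  }
  stack[, , channel, frame]
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<frame_stack> %dx%d px, %d channel(s) [%s], %d frame(s), %.3g um/px, %.3g s/frame\n",
              d[1], d[2], d[3],
              paste(attr(x, "channel_names"), collapse = ", "), d[4],
              attr(x, "pixel_size_um"), attr(x, "frame_interval_s")))
  invisible(x)
}
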