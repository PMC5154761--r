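# Shared fixtures: small, fast generator configurations and hand-built
# geometric images. Everything is generated in code at test time.

# small noisy two-channel movie (fast default-like conditions)
small_config <- function(seed = 1, n_frames = 6, ...) {
  synth_config(image_size_px = c(160L, 160L), cell_radius_um = 5,
               n_frames = n_frames, seed = seed, ...)
}

# a clean rasterized disk image (value inside, 0 outside)
disk_image <- function(size = 96, cx = size / 2, cy = size / 2, r = 20,
                       value = 100) {
  img <- matrix(0, size, size)
  for (row in seq_len(size)) {
    for (col in seq_len(size)) {
      if ((row - cy)^2 + (col - cx)^2 < r^2) img[row, col] <- value
    }
  }
  img
}

# membrane profile object built directly from a value vector
fake_profile <- function(values, radius_um = 5, cyto_mean = NULL) {
  n <- length(values)
  spacing <- 2 * pi * radius_um / n
  structure(list(raw = values,
                 normalized = if (!is.null(cyto_mean)) values / cyto_mean,
                 cyto_mean = cyto_mean,
                 arc_um = (seq_len(n) - 1) * spacing,
                 band_width_um = 1, clipped = FALSE, n_points = n,
                 arc_spacing_um = spacing),
            class = "membrane_profile")
}

fake_cyto <- function(mean = 100, sd = 10) {
  structure(list(mean = mean, sd = sd, n_pixels = 1000L,
                 erosion_margin_um = 1),
            class = "cytosol_stats")
}

# circular contour built analytically (bypasses segmentation)
circle_contour <- function(r = 5, n = 100, center = c(8, 8),
                           pixel_size_um = 0.1) {
  th <- (seq_len(n) - 1) * 2 * pi / n
  pts <- cbind(center[1] + r * cos(th), center[2] + r * sin(th))
  membranepatch:::orient_contour(pts, pixel_size_um)
}

# segment + contour + cytosol + profiles for one frame of a movie
measure_frame <- function(stack, truth, f, n_points = 100,
                          band_width_um = 1.6) {
  px <- attr(stack, "pixel_size_um")
  img_p <- stack_frame(stack, f, "patch")
  has_ring <- "ring" %in% attr(stack, "channel_names")
  mask <- segment_cell(img_p, px, min_area_px = 500)
  ct <- extract_contour(mask, n_points)
  cs_p <- cytosol_stats(img_p, mask, 1.0)
  out <- list(mask = mask, contour = ct, cyto_patch = cs_p,
              profile_patch = sample_membrane(img_p, ct, band_width_um,
                                              cyto_mean = cs_p$mean))
  if (has_ring) {
    img_r <- stack_frame(stack, f, "ring")
    cs_r <- cytosol_stats(img_r, mask, 1.0)
    out$cyto_ring <- cs_r
    out$profile_ring <- sample_membrane(img_r, ct, band_width_um,
                                        cyto_mean = cs_r$mean)
  }
  out
}
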